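Package: condukt
Title: Discrete-Event Simulation and Analysis of Automated Conditioning
    Experiments in Free-Swimming Fish
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A software-only re-creation of an automated classical/operant
    conditioning rig for free-swimming zebrafish: a declarative multi-day
    schedule model (trials, runs, reps; delay-based stimulus triggers), a
    discrete-event engine that executes schedules against a virtual circular
    tank (sensor-gated operant reward, fixed-delay classical reward, robotic
    feeder arm), an agent-based fish simulator with Rescorla-Wagner reward
    association, trajectory/event-log I/O including idTracker-style exports,
    per-rep behavioral metrics (distance to target, zones, darts, turning,
    success scoring), and trial-level learning statistics (kernel-smoothed
    learning curves, pre/post window ANOVA, repeated-measures learning test,
    learning-model parameter recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
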