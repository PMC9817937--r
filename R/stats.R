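# Trial-level learning analyses: kernel-smoothed learning curves over binary
# outcomes, pre/post window ANOVA, a repeated-measures learning test across
# subjects, and maximum-likelihood fitting of the association-learning model.
#
# The ANOVAs are computed from sums of squares directly so the engine's core
# contract has no statistics-package dependency; p-values come from the
# F-distribution CDF.  Tests cross-check them against stats::aov.

#' Kernel-smoothed learning curve for binary outcomes
#'
#' Nadaraya-Watson estimator: a Gaussian-kernel weighted mean of the 0/1
#' success scores evaluated on an even time grid, with a pointwise spread
#' band equal to the kernel-weighted standard deviation of the scores around
#' the curve.  The curve is invariant to shifting all times by a constant.
#'
#' @param times cumulative training time of each rep (hours), at least 2.
#' @param scores 0/1 success scores, same length.
#' @param bandwidth Gaussian kernel bandwidth in hours (> 0).
#' @param grid_n number of grid points (default 101).
#' @param grid optional explicit grid (overrides `grid_n`).
#' @return data.frame `time`, `p` (smoothed success probability in `[0, 1]`),
#'   `sd` (spread band).
#' @export
learning_curve <- function(times, scores, bandwidth = 4, grid_n = 101,
                           grid = NULL) {
  if (length(times) != length(scores)) stopf("times and scores must align")
  if (length(times) < 2) stopf("at least 2 scores are required")
  if (!is.numeric(bandwidth) || bandwidth <= 0) stopf("'bandwidth' must be > 0")
  if (!all(scores %in% c(0, 1))) stopf("scores must be 0 or 1")
  if (is.null(grid)) grid <- seq(min(times), max(times), length.out = grid_n)
  p <- numeric(length(grid)); s <- numeric(length(grid))
  for (i in seq_along(grid)) {
    w <- dnorm((times - grid[i]) / bandwidth)
    sw <- sum(w)
    p[i] <- sum(w * scores) / sw
    s[i] <- sqrt(sum(w * (scores - p[i])^2) / sw)
  }
  data.frame(time = grid, p = p, sd = s)
}

#' One-way ANOVA across analysis windows
#'
#' Tests whether per-individual window means (PRE vs POST windows) differ,
#' from sums of squares computed from scratch.  With zero within-group
#' variance: equal group means give `F = 0, p = 1` by convention; unequal
#' means give an infinite F and `p = 0`.
#'
#' @param window_means data.frame with columns `window` (group) and `mean`
#'   (one value per individual per window), e.g. from [window_stats()];
#'   alternatively a list/data.frame of numeric vectors, one per window.
#' @return list with `F`, `df`, `p`, and `summary` (per-window n/mean/sd).
#' @export
pre_post_test <- function(window_means) {
  if (is.data.frame(window_means) && all(c("window", "mean") %in% names(window_means))) {
    groups <- split(window_means$mean, window_means$window)
  } else {
    groups <- as.list(window_means)
  }
  groups <- lapply(groups, function(v) v[!is.na(v)])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stopf("at least 2 windows are required")
  if (any(lengths(groups) < 2)) stopf("at least 2 individuals per window are required")
  y <- unlist(groups)
  g_mean <- vapply(groups, mean, numeric(1))
  grand <- mean(y)
  ss_between <- sum(lengths(groups) * (g_mean - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  if (ss_within <= .Machine$double.eps * sum(y^2 + 1)) {
    if (ss_between <= .Machine$double.eps * sum(y^2 + 1)) {
      Fstat <- 0; p <- 1
    } else {
      Fstat <- Inf; p <- 0
    }
  } else {
    Fstat <- (ss_between / df1) / (ss_within / df2)
    p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  list(F = Fstat, df = c(df1, df2), p = p,
       summary = data.frame(window = names(groups), n = lengths(groups),
                            mean = g_mean,
                            sd = vapply(groups, sd, numeric(1)),
                            row.names = NULL))
}

#' Repeated-measures learning test across subjects
#'
#' Two-way within-subject decomposition of per-subject, per-block success
#' rates: main effects of subject (fish) and block (cumulative training
#' time), each tested against the subject-by-block residual.  The design must
#' be balanced: every subject observed in every block.
#'
#' @param scores data.frame with columns `subject`, `time_h`, `score`
#'   (a score series, e.g. from [score_series()]).
#' @param blocks either an integer vector assigning each row to a block, or
#'   the number of consecutive runs/reps grouped per block via `block_size`
#'   applied to each subject's rep order.  Default: consecutive reps grouped
#'   in threes.
#' @param block_size reps per block when `blocks` is not given (default 3).
#' @return a `learning_test_result`: F and p for the subject and time
#'   effects, degrees of freedom, and the per-subject success-rate profile
#'   over blocks.
#' @export
rm_learning_test <- function(scores, blocks = NULL, block_size = 3) {
  need <- c("subject", "time_h", "score")
  if (!all(need %in% names(scores)))
    stopf("scores needs columns: %s", paste(need, collapse = ", "))
  if (!is.null(blocks)) scores$block <- blocks   # aligned to input row order
  scores <- scores[order(scores$subject, scores$time_h), ]
  if (is.null(blocks))
    scores$block <- ave(seq_len(nrow(scores)), scores$subject,
                        FUN = function(ix) (seq_along(ix) - 1L) %/% block_size + 1L)
  profile <- aggregate(score ~ subject + block, data = scores, FUN = mean)
  tab <- table(profile$subject, profile$block)
  if (any(tab != 1)) {
    missing <- which(tab == 0, arr.ind = TRUE)
    stopf("unbalanced design: missing cell(s) %s",
          paste(sprintf("(subject %s, block %s)", rownames(tab)[missing[, 1]],
                        colnames(tab)[missing[, 2]]), collapse = ", "))
  }
  if (ncol(tab) < 2) stopf("at least 2 blocks are required")
  Y <- matrix(NA_real_, nrow(tab), ncol(tab), dimnames = dimnames(tab))
  for (i in seq_len(nrow(profile)))
    Y[as.character(profile$subject[i]), as.character(profile$block[i])] <-
      profile$score[i]
  s <- nrow(Y); b <- ncol(Y)
  grand <- mean(Y)
  rm_ <- rowMeans(Y); cm <- colMeans(Y)
  ss_subj <- b * sum((rm_ - grand)^2)
  ss_block <- s * sum((cm - grand)^2)
  resid <- Y - outer(rm_, rep(1, b)) - outer(rep(1, s), cm) + grand
  ss_err <- sum(resid^2)
  df_s <- s - 1L; df_b <- b - 1L; df_e <- df_s * df_b
  f_of <- function(ss, df) {
    if (ss_err <= .Machine$double.eps * (sum(Y^2) + 1)) {
      if (ss <= .Machine$double.eps * (sum(Y^2) + 1)) c(0, 1) else c(Inf, 0)
    } else {
      Fv <- (ss / df) / (ss_err / df_e)
      c(Fv, pf(Fv, df, df_e, lower.tail = FALSE))
    }
  }
  fs <- f_of(ss_subj, df_s); fb <- f_of(ss_block, df_b)
  structure(list(
    F_subject = fs[1], p_subject = fs[2], df_subject = c(df_s, df_e),
    F_time = fb[1], p_time = fb[2], df_time = c(df_b, df_e),
    profile = data.frame(subject = rep(rownames(Y), b),
                         block = rep(colnames(Y), each = s),
                         success_rate = as.vector(Y))),
    class = "learning_test_result")
}

#' @export
print.learning_test_result <- function(x, ...) {
  cat(sprintf("Repeated-measures learning test\n  subject: F(%d,%d) = %.3f, p = %.4g\n  time:    F(%d,%d) = %.3f, p = %.4g\n",
              x$df_subject[1], x$df_subject[2], x$F_subject, x$p_subject,
              x$df_time[1], x$df_time[2], x$F_time, x$p_time))
  invisible(x)
}

#' Extract a per-subject score series from trial results
#'
#' @param results list of `rep_result`s (one subject) or a named list of such
#'   lists (multiple subjects), as returned by [run_trial()].
#' @param stimulus optional stimulus label attached to every row.
#' @return data.frame `subject`, `time_h`, `score`, `stimulus` with operant
#'   reps only, times strictly increasing per subject.
#' @export
score_series <- function(results, stimulus = NA_character_) {
  one <- function(res, subject) {
    ss <- attr(res, "score_series")
    if (is.null(ss))
      ss <- data.frame(rep = seq_along(res),
                       time_h = vapply(res, `[[`, numeric(1), "time_h"),
                       score = vapply(res, `[[`, integer(1), "success"),
                       paradigm = vapply(res, `[[`, character(1), "paradigm"))
    ss <- ss[ss$paradigm == "operant" & !is.na(ss$score), ]
    data.frame(subject = subject, time_h = ss$time_h, score = ss$score,
               stimulus = stimulus)
  }
  if (length(results) > 0 && inherits(results[[1]], "rep_result"))
    return(one(results, subject = 1L))
  out <- do.call(rbind, lapply(seq_along(results), function(i)
    one(results[[i]], subject = names(results)[i] %||% i)))
  rownames(out) <- NULL
  out
}

# ---- learning-model fitting ----------------------------------------------

fit_nll <- function(scores, alpha, v0, guess, lam = 1) {
  v <- assoc_path_cpp(as.integer(scores), alpha, v0, lam)
  p <- guess + (1 - guess) * v
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(ifelse(scores == 1, log(p), log(1 - p)))
}

#' Fit the association-learning model to a score series by maximum likelihood
#'
#' The observation model maps association strength to success probability as
#' `p = guess + (1 - guess) * V`, where `V` follows the rewarded-update rule
#' (reward after success, mild extinction after failure; see
#' [update_association()]) and `guess` is the baseline probability of
#' triggering the sensor by chance.  `alpha`, `V0`, and `guess` are estimated
#' by a deterministic bounded quasi-Newton search from a fixed set of
#' documented start points; the confidence interval for `alpha` is a profile
#' likelihood interval, which remains valid at the `alpha = 0` boundary.
#'
#' @param scores 0/1 vector in rep order (>= 10 reps), or a score-series
#'   data.frame with a `score` column.
#' @param level confidence level for the `alpha` interval (default 0.95).
#' @param profile_grid grid of `alpha` values for the profile (default
#'   `seq(0, 1, by = 0.02)`).
#' @return list with `alpha`, `V0`, `guess`, `logLik`, `alpha_ci`, and
#'   `boundary` (TRUE when the data are all-0/all-1 or the estimate sits on
#'   the parameter boundary).
#' @export
fit_learning_model <- function(scores, level = 0.95,
                               profile_grid = seq(0, 1, by = 0.02)) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) < 10) stopf("at least 10 reps are required")
  if (!all(scores %in% c(0, 1))) stopf("scores must be 0 or 1")
  degenerate <- all(scores == 0) || all(scores == 1)

  starts <- expand.grid(alpha = c(0.02, 0.1, 0.3), v0 = c(0.05, 0.3),
                        guess = c(0.1, 0.3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(optim(
      par = as.numeric(starts[i, ]),
      fn = function(p) fit_nll(scores, p[1], p[2], p[3]),
      method = "L-BFGS-B",
      lower = c(0, 0, 1e-6), upper = c(1, 1, 0.9)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stopf("optimization failed")
  alpha_hat <- best$par[1]

  # profile likelihood over alpha
  thresh <- best$value + qchisq(level, 1) / 2
  prof <- vapply(profile_grid, function(a) {
    fit <- optim(par = c(best$par[2], best$par[3]),
                 fn = function(p) fit_nll(scores, a, p[1], p[2]),
                 method = "L-BFGS-B", lower = c(0, 1e-6), upper = c(1, 0.9))
    fit$value
  }, numeric(1))
  inside <- profile_grid[prof <= thresh + 1e-9]
  alpha_ci <- if (length(inside) > 0) range(inside) else c(alpha_hat, alpha_hat)

  list(alpha = alpha_hat, V0 = best$par[2], guess = best$par[3],
       logLik = -best$value, alpha_ci = alpha_ci,
       boundary = degenerate || alpha_hat <= 1e-3 || alpha_hat >= 1 - 1e-3)
}

#' Simulate scores from the association-learning observation model
#'
#' Sequentially draws 0/1 outcomes with `p = guess + (1 - guess) * V`,
#' updating `V` by the rewarded-update rule after each draw.  This is the
#' direct generative counterpart of [fit_learning_model()] and is used for
#' parameter-recovery simulations.
#'
#' @param n_reps number of reps.
#' @param alpha,V0,guess model parameters.
#' @param seed integer.
#' @return integer 0/1 vector.
#' @export
simulate_model_scores <- function(n_reps, alpha = 0.3, V0 = 0.05, guess = 0.1,
                                  seed = 1) {
  with_seed(seed, {
    V <- V0
    out <- integer(n_reps)
    for (i in seq_len(n_reps)) {
      p <- guess + (1 - guess) * V
      out[i] <- as.integer(runif(1) < p)
      V <- update_association(V, out[i] == 1L, alpha)
    }
    out
  })
}

# ---- fast operant score generator ----------------------------------------

#' Simulate operant score series for a cohort of independently trained fish
#'
#' Score-only fast path over the same kinematics core and derived seeds as
#' [run_rep()] (their success outcomes agree exactly), skipping event-log and
#' trajectory assembly so calibration-scale simulations (hundreds of
#' simulated subjects) stay cheap.  Each subject is a single fish trained
#' alone, the standard operant arrangement; reps are spaced `rep_interval_h`
#' hours apart on the virtual clock, with satiation recovering between reps.
#'
#' @param n_subjects number of fish, each trained independently.
#' @param n_reps operant reps per fish.
#' @param params shared [agent_params()] (per-subject jitter applied).
#' @param template operant [rep_template()]; default: the bundled
#'   audiovisual preset's template.
#' @param tank a [tank_geometry()].
#' @param config an [engine_config()].
#' @param seed integer master seed.
#' @param rep_interval_h virtual hours between rep starts (default 0.5, i.e.
#'   12 reps span 6 h of training time).
#' @param jitter per-subject parameter jitter (see [make_cohort()]).
#' @return score-series data.frame `subject`, `time_h`, `score`, `stimulus`.
#' @export
simulate_operant_series <- function(n_subjects, n_reps,
                                    params = agent_params(),
                                    template = NULL,
                                    tank = tank_geometry(),
                                    config = engine_config(),
                                    seed = 1, rep_interval_h = 0.5,
                                    jitter = 0.1) {
  if (is.null(template)) template <- preset_template("audiovisual-4day")
  stopifnot(template$paradigm == "operant")
  out <- list()
  for (subj in seq_len(n_subjects)) {
    cohort <- make_cohort(1, params, seed = derive_seed(seed, "subject", subj),
                          tank = tank, jitter = jitter)
    for (r in seq_len(n_reps)) {
      rep_seed <- derive_seed(seed, "subject", subj, "rep", r)
      core <- rep_core(template, tank, cohort, config, rep_seed)
      out[[length(out) + 1L]] <- data.frame(
        subject = subj, time_h = (r - 1) * rep_interval_h,
        score = as.integer(core$fed), stimulus = NA_character_)
      cohort <- apply_rep_outcome(cohort, template, core$fed, core$grains)
      cohort <- recover_satiation(cohort, rep_interval_h)
    }
  }
  do.call(rbind, out)
}

#' Plot a learning curve (requires ggplot2)
#'
#' @param curve output of [learning_curve()].
#' @param scores optional data.frame with `time_h` and `score` to overlay the
#'   raw 0/1 outcomes.
#' @return a ggplot object.
#' @export
plot_learning_curve <- function(curve, scores = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_learning_curve requires the ggplot2 package")
  g <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$p)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$p - .data$sd, 0),
                                      ymax = pmin(.data$p + .data$sd, 1)),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "cumulative training time (h)",
                  y = "success probability")
  if (!is.null(scores))
    g <- g + ggplot2::geom_point(
      data = scores, ggplot2::aes(x = .data$time_h, y = .data$score),
      alpha = 0.4, shape = 16)
  g
}
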