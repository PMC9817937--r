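# Trajectory and event-log I/O: the package's delimited-text trajectory
# format, idTracker-style tracker exports, line-delimited event logs, and
# session manifests.

#' Construct a trajectory table
#'
#' The unit of analysis: per-frame `(x, y)` positions (cm) per individual at
#' a fixed frame rate.  Missing positions (occlusion, untracked frames) are
#' allowed and must be jointly missing in x and y.
#'
#' @param df data.frame with columns `frame` (0-based, consecutive per
#'   individual), `time` (seconds, `frame / frame_rate`), `id`, `x`, `y`.
#' @param frame_rate frames/second.
#' @return a `trajectory_table` (a data.frame with a `frame_rate` attribute).
#' @export
trajectory_table <- function(df, frame_rate = 30) {
  need <- c("frame", "time", "id", "x", "y")
  if (!all(need %in% names(df)))
    stopf("trajectory table needs columns: %s", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (nrow(df) > 0) {
    bad <- xor(is.na(df$x), is.na(df$y))
    if (any(bad)) stopf("x and y must be jointly missing (row %d)", which(bad)[1])
    for (ind in unique(df$id)) {
      f <- sort(df$frame[df$id == ind])
      if (length(f) > 1 && any(diff(f) != 1))
        stopf("frame indices must be consecutive per individual (id %s)", ind)
    }
    if (max(abs(df$time - df$frame / frame_rate)) > 1e-6)
      stopf("time must equal frame / frame_rate")
  }
  rownames(df) <- NULL
  structure(df, frame_rate = as.numeric(frame_rate),
            class = c("trajectory_table", "data.frame"))
}

#' Write / read a trajectory file
#'
#' Plain comma-delimited text with a header and a `# frame_rate:` comment
#' line; missing positions are empty fields (never sentinel zeros).  The
#' write/read round trip is lossless, including missing values.
#'
#' @param traj a [trajectory_table()].
#' @param path file path.
#' @return `read_trajectory` returns a `trajectory_table`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate: %g", attr(traj, "frame_rate")), con)
  writeLines("frame,time,id,x,y", con)
  if (nrow(traj) > 0) {
    num <- function(v) ifelse(is.na(v), "", sprintf("%.6g", v))
    writeLines(paste(traj$frame, sprintf("%.6g", traj$time), traj$id,
                     num(traj$x), num(traj$y), sep = ","), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !grepl("^# frame_rate:", lines[1]))
    stopf("'%s' is not a trajectory file (missing frame_rate header)", path)
  fr <- as.numeric(sub("^# frame_rate:\\s*", "", lines[1]))
  header <- strsplit(lines[2], ",")[[1]]
  if (!identical(header, c("frame", "time", "id", "x", "y")))
    stopf("'%s': unexpected column header at line 2", path)
  body <- lines[-(1:2)]
  if (length(body) == 0) {
    return(trajectory_table(data.frame(frame = integer(0), time = numeric(0),
                                       id = integer(0), x = numeric(0),
                                       y = numeric(0)), fr))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  # empty trailing fields are dropped by strsplit; pad rows like "0,0,1,,"
  if (any(nf < 3 | nf > 5))
    stopf("'%s': malformed row at line %d", path, which(nf < 3 | nf > 5)[1] + 2L)
  get <- function(i) vapply(parts, function(p) if (length(p) >= i && nzchar(p[i]))
    p[i] else NA_character_, character(1))
  df <- data.frame(frame = as.integer(get(1)), time = as.numeric(get(2)),
                   id = type.convert(get(3), as.is = TRUE),
                   x = as.numeric(get(4)), y = as.numeric(get(5)))
  if (anyNA(df$frame) || anyNA(df$time))
    stopf("'%s': malformed row at line %d", path,
          which(is.na(df$frame) | is.na(df$time))[1] + 2L)
  # time is derived from the frame index; recompute it exactly rather than
  # trusting the file's rounded representation
  df$time <- df$frame / fr
  trajectory_table(df, fr)
}

#' Read an idTracker-style tracker export
#'
#' Consumes the de-facto `trajectories.txt` layout: a delimited numeric
#' matrix with three columns per individual (`X1 Y1 ProbId1 X2 Y2 ProbId2
#' ...`) in pixel units, one row per frame.  The probability column is
#' dropped, coordinates are converted to cm via the explicit `scale` factor
#' (no auto-calibration), and both `NaN` and exact-zero coordinate pairs are
#' mapped to missing (tracker versions use the two inconsistently for
#' untracked frames).
#'
#' @param path tracker export file.
#' @param frame_rate frames/second of the source video.
#' @param scale cm per pixel.
#' @param delim field delimiter; default whitespace (`""`), set `","` for
#'   comma-dialect exports.
#' @return a [trajectory_table()].
#' @export
read_idtracker <- function(path, frame_rate = 30, scale = 1, delim = "") {
  mat <- as.matrix(read.table(path, header = FALSE, sep = delim,
                              na.strings = c("NA", "NaN", "nan")))
  if (ncol(mat) %% 3 != 0)
    stopf("'%s': column count (%d) is not divisible by 3 (X, Y, ProbId per individual)",
          path, ncol(mat))
  n_ind <- ncol(mat) / 3
  out <- do.call(rbind, lapply(seq_len(n_ind), function(i) {
    x <- mat[, 3 * i - 2]; y <- mat[, 3 * i - 1]
    untracked <- is.na(x) | is.na(y) | (x == 0 & y == 0)
    x[untracked] <- NA; y[untracked] <- NA
    data.frame(frame = seq_len(nrow(mat)) - 1L,
               time = (seq_len(nrow(mat)) - 1L) / frame_rate,
               id = i, x = x * scale, y = y * scale)
  }))
  trajectory_table(out, frame_rate)
}

# ---- event logs ----------------------------------------------------------

#' Write / read a line-delimited event log
#'
#' One record per line with fixed field order `t`, `wall_time`, `kind`,
#' `payload` (comma-joined `key=value` pairs), tab-separated, with a header
#' line.  This is the canonical per-rep log the engine emits.
#'
#' @param events event data.frame from a `rep_result`.
#' @param path file path.
#' @return `read_event_log` returns the event data.frame.
#' @export
write_event_log <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t\twall_time\tkind\tpayload", con)
  writeLines(paste(sprintf("%.6f", events$t), events$wall_time, events$kind,
                   events$payload, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = c("numeric", "character", "character", "character"),
                   na.strings = NULL)
  if (!identical(names(df), c("t", "wall_time", "kind", "payload")))
    stopf("'%s' is not an event log", path)
  df
}

payload_field <- function(payload, key) {
  m <- regmatches(payload, regexec(paste0("(^|,)", key, "=([^,]*)"), payload))
  vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, character(1))
}

# ---- session manifest ----------------------------------------------------

#' Write / read a session manifest
#'
#' Maps rep ids to their event-log and trajectory files plus the schedule
#' hash and rep seed that produced them.  `read_manifest` checks that every
#' referenced file exists.
#'
#' @param manifest data.frame with columns `rep_id`, `event_log`,
#'   `trajectory`, `schedule_hash`, `seed`.
#' @param path manifest file (tab-separated; referenced paths are relative to
#'   its directory).
#' @return `read_manifest` returns the manifest with absolute paths.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("character", "character", "character",
                                 "character", "integer"))
  base <- dirname(path)
  m$event_log <- file.path(base, m$event_log)
  m$trajectory <- file.path(base, m$trajectory)
  missing <- c(m$event_log[!file.exists(m$event_log)],
               m$trajectory[!file.exists(m$trajectory)])
  if (length(missing) > 0)
    stopf("manifest references missing file(s): %s", paste(missing, collapse = ", "))
  m
}
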