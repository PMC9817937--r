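# Internal helpers: seed derivation, RNG hygiene, clock-time parsing.

#' Derive a reproducible sub-seed from a base seed and a sequence of tags
#'
#' Deterministic 31-bit mixing of the base seed with integer/character tags,
#' used to split one user seed into independent streams (per rep, per agent,
#' per feed draw) so cohort size or rep order never perturbs another
#' stream's draws.
#'
#' @param seed integer base seed.
#' @param ... integer or character tags identifying the stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(list(seed), list(...))   # keep tag types: no character coercion
  h <- 0
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    h <- (h * 69069 + as.numeric(p) + 1) %% 2147483647
    # non-linear scramble after each tag: a purely affine combiner leaves
    # arithmetic structure that causes systematic stream collisions across
    # tag sequences (distinct tag paths mapping to identical seeds)
    h <- scramble32(h)
  }
  as.integer(h)
}

scramble32 <- function(h) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(h))
  v <- sample.int(2147483646L, 1L)
  if (has_old) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  v
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls stay referentially transparent.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# "HH:MM" or "HH:MM:SS" -> seconds since midnight; NA if not a clock time.
parse_clock <- function(x) {
  if (!is.character(x) || length(x) != 1) return(NA_real_)
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})(:([0-9]{2}))?$", x))[[1]]
  if (length(m) == 0) return(NA_real_)
  h <- as.numeric(m[2]); mi <- as.numeric(m[3])
  s <- if (m[5] == "") 0 else as.numeric(m[5])
  if (h > 23 || mi > 59 || s > 59) return(NA_real_)
  h * 3600 + mi * 60 + s
}

# "YYYY-MM-DD HH:MM[:SS]" -> POSIXct (tz fixed to UTC: a timezone-free local
# clock; no DST handling); NA if not a dated time.
parse_dated <- function(x) {
  if (!is.character(x) || length(x) != 1) return(as.POSIXct(NA))
  if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}[ T][0-9]{1,2}:[0-9]{2}(:[0-9]{2})?$", x))
    return(as.POSIXct(NA))
  fmt <- if (grepl(":[0-9]{2}:[0-9]{2}$", x)) "%Y-%m-%d %H:%M:%S" else "%Y-%m-%d %H:%M"
  as.POSIXct(sub("T", " ", x), format = fmt, tz = "UTC")
}

is_clock_time <- function(x) !is.na(parse_clock(x))

fmt_wall <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")

# md5 of a file (used for schedule hashes in manifests).
file_md5 <- function(path) unname(tools::md5sum(path))

text_md5 <- function(text) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(text, tf)
  file_md5(tf)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
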