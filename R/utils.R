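#' Convert "HH:MM" (or "HH:MM:SS") clock strings to seconds of day
#'
#' Numeric input is returned unchanged (already seconds of day).
#'
#' @param x character clock times or numeric seconds of day.
#' @return numeric vector of seconds since midnight.
#' @export
clock_to_seconds <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) < 2L || length(p) > 3L || anyNA(p))
      stop("clock time must be 'HH:MM' or 'HH:MM:SS'", call. = FALSE)
    if (length(p) == 2L) p <- c(p, 0)
    p[1L] * 3600 + p[2L] * 60 + p[3L]
  }, numeric(1))
}

#' Format seconds of day as "HH:MM:SS"
#' @param x numeric seconds of day.
#' @return character vector.
#' @export
seconds_to_clock <- function(x) {
  x <- round(x)
  sprintf("%02d:%02d:%02d", x %/% 3600L, (x %% 3600L) %/% 60L, x %% 60L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

# Local RNG scope: runs `expr` under a seed derived from `seed` without
# touching the caller's RNG state. All generator functions use this so a
# pipeline run is reproducible piecewise and as a whole.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-entity sub-seed below 2^31, so per-subject streams are
# independent of cohort ordering.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}
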