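# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs code with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoidal integral of y over x (same length, x increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("trapz() needs at least two samples")
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Centered moving average, window w samples (odd); edges use shrunken windows.
moving_mean <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  pad <- (w - 1L) %/% 2L
  xe <- c(rep(x[1L], pad), x, rep(x[length(x)], w - 1L - pad))
  as.numeric(stats::filter(xe, k, sides = 2L))[(pad + 1L):(pad + length(x))]
}

stop_missing <- function(value, name) {
  if (is.null(value) || (is.atomic(value) && length(value) == 1L && is.na(value))) {
    stop(sprintf("required field '%s' is missing", name), call. = FALSE)
  }
  invisible(value)
}
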