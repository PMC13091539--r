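# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; if `seed` is
# NULL the expression runs against the caller's RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (seed >= 2^31 || seed < -2^31) {
    abort("`seed` must be a 32-bit integer (|seed| < 2^31).",
          class = "endokin_invalid_config")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Centred rolling mean with shrinking windows at the edges; width is forced
# odd. Used to denoise spot channels before threshold comparisons.
roll_mean <- function(x, width = 5L) {
  n <- length(x)
  if (n == 0L || width <= 1L) return(x)
  half <- (as.integer(width) - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Ordinary least-squares slope of y on x via the closed form; NA-safe.
ls_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(NA_real_)
  sum(xc * (y - mean(y))) / denom
}

# First time at which `x` (sampled at `time`) crosses below `level`,
# linearly interpolated between the bracketing samples; NA if never.
cross_below <- function(time, x, level) {
  below <- which(x < level)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(time[1L])
  t0 <- time[i - 1L]; t1 <- time[i]
  x0 <- x[i - 1L]; x1 <- x[i]
  if (!is.finite(x0) || x1 == x0) return(t1)
  t0 + (x0 - level) / (x0 - x1) * (t1 - t0)
}

stop_invalid <- function(msg) abort(msg, class = "endokin_invalid_config")
stop_insufficient <- function(msg) abort(msg, class = "endokin_insufficient_data")
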