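# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + as.numeric(stream) * 12289L) %% 2147483587
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  invisible(x)
}

# Linear-interpolation resample of y (regular grid) to n points spanning the
# full extent, endpoints preserved.
lin_resample <- function(y, n) {
  m <- length(y)
  if (m == n) return(y)
  stats::approx(x = seq(0, 1, length.out = m), y = y,
                xout = seq(0, 1, length.out = n))$y
}

# Centered moving average with window of k samples (k odd enforced).
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  cs <- cumsum(c(0, x))
  h <- (k - 1L) %/% 2L
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Run-length onsets: positions (1-based) where value changes, including 1.
run_onsets <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  c(1L, which(x[-1L] != x[-n]) + 1L)
}
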