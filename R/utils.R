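# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

hammingWindow <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Centered rolling percentile with edge truncation; linear-interpolated
# empirical percentile (quantile type 7).
rollingPercentile <- function(x, width, prob) {
  n <- length(x)
  stopifnot(width >= 1, width <= n)
  half_lo <- floor((width - 1) / 2)
  half_hi <- width - 1 - half_lo
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_lo)
    hi <- min(n, i + half_hi)
    stats::quantile(x[lo:hi], probs = prob, names = FALSE, type = 7)
  }, numeric(1))
}

# Bilinear interpolation of image `img` (matrix, rows = y, cols = x) at
# continuous pixel coordinates (x, y), 1-based. Returns NA outside the frame.
bilinearSample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= w & y >= 1 & y <= h
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  out[ok] <- img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
  out
}

# Gaussian white noise spectrally shaped to a pink (power ~ 1/f) profile,
# scaled to standard deviation `sd`. The DC bin is zeroed.
pinkNoise <- function(n, sd) {
  if (sd == 0 || n < 2) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  k <- seq_len(n) - 1                      # 0 .. n-1
  f <- pmin(k, n - k)                      # symmetric frequency index
  amp <- ifelse(f == 0, 0, 1 / sqrt(f))    # amplitude ~ f^-1/2 => power ~ 1/f
  shaped <- Re(stats::fft(spec * amp, inverse = TRUE)) / n
  s <- stats::sd(shaped)
  if (s == 0) return(numeric(n))
  shaped * (sd / s)
}

# First linear-interpolated crossing of `level` between consecutive samples,
# scanning indices `idx` in order; returns fractional index or NA.
firstCrossing <- function(y, level, idx) {
  for (j in seq_along(idx)[-1]) {
    a <- idx[j - 1]; b <- idx[j]
    if ((y[a] < level) != (y[b] < level) || y[b] == level) {
      if (y[b] == y[a]) return(b)
      return(a + (level - y[a]) / (y[b] - y[a]) * (b - a))
    }
  }
  NA_real_
}
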