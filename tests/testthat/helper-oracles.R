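# Independent brute-force oracles, deliberately literal: each quantity is
# computed by direct scanning / direct formula evaluation, not by the
# package's algorithms.

# Topographic prominence by exhaustive per-peak scan: for each plateau-aware
# local maximum, walk sample by sample to the nearest strictly higher sample
# (or the edge) on each side, record the minimum passed on each side, and
# subtract the higher of the two minima.
oracle_prominences <- function(y) {
  n <- length(y)
  starts <- 1L
  for (i in 2:n) if (y[i] != y[i - 1L]) starts <- c(starts, i)
  ends <- c(starts[-1L] - 1L, n)
  vals <- y[starts]
  out <- data.frame(index = integer(), prominence = numeric())
  if (length(starts) < 3L) return(out)
  for (k in 2:(length(starts) - 1L)) {
    if (!(vals[k] > vals[k - 1L] && vals[k] > vals[k + 1L])) next
    i <- (starts[k] + ends[k]) %/% 2L
    h <- y[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L) {
      if (y[j] > h) break
      if (y[j] < lmin) lmin <- y[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n) {
      if (y[j] > h) break
      if (y[j] < rmin) rmin <- y[j]
      j <- j + 1L
    }
    out <- rbind(out, data.frame(index = i, prominence = h - max(lmin, rmin)))
  }
  out
}

# Direct formula: 100 * sample SD / mean.
oracle_cov <- function(d) {
  m <- sum(d) / length(d)
  100 * sqrt(sum((d - m)^2) / (length(d) - 1)) / m
}

# Product-moment correlation and two-sided p by direct formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# Rank (average ties) then product-moment.
oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))$r
}

# Raised-cosine lobe used to hand-build series.
hann_lobe <- function(t, center, amp, half_width) {
  u <- (t - center) / half_width
  ifelse(abs(u) < 1, amp * cos(pi * u / 2)^2, 0)
}

# A clean (noise-free, dropout-free) spec; onsets on the sample grid.
clean_spec <- function(...) {
  wave_spec(residual_sd = 0, sensor_noise_sd = 0,
            dropout_trial_fraction = 0, ...)
}

# Strip the generator's ground-truth attribute for object comparisons.
strip_truth <- function(trial) {
  attr(trial, "truth") <- NULL
  trial
}
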