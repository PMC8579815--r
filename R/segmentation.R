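#' @title Wave segmentation by peak prominence
#' @description The wave is segmented from the successive peaks of the chain
#'   markers' vertical displacements. Each segment's amplitude is the
#'   topographic prominence of its primary peak: the height of the local
#'   maximum above the higher of the two minima separating it from higher
#'   terrain (or from the window edge). The most prominent peak of a marker
#'   is its sub-movement; everything else is residual movement.
#' @name segmentation
NULL

# Local maxima of a series, plateau-aware: runs of equal values that are
# strictly above both neighbouring runs peak at the run's middle sample.
local_maxima <- function(y) {
  r <- rle(y)
  v <- r$values
  k <- length(v)
  if (k < 3L) return(integer())
  is_peak <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k], FALSE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- (starts + ends) %/% 2L
  mid[is_peak]
}

# Topographic prominence of each peak index: walk outwards until a strictly
# higher sample (higher terrain) or the series edge, track the minimum on
# each side, and subtract the higher of the two minima.
peak_prominences <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(i) {
    h <- y[i]
    left_min <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) {
      if (y[j] < left_min) left_min <- y[j]
      j <- j - 1L
    }
    right_min <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) {
      if (y[j] < right_min) right_min <- y[j]
      j <- j + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect peaks and their topographic prominences
#'
#' Operates sample-exactly on the series as given (no smoothing). Peaks are
#' returned sorted by prominence, largest first, ties broken by earlier time.
#'
#' @param y Numeric series (vertical positions within the analysis window).
#' @param t Optional time stamps (defaults to sample indices).
#' @return A tibble with columns `time`, `index`, `height`, `prominence`.
#' @examples
#' y <- sin(seq(0, 4 * pi, length.out = 200))
#' detect_peaks(y)
#' @export
detect_peaks <- function(y, t = seq_along(y)) {
  pk <- detect_peaks_core(y, t)
  tibble::new_tibble(pk, nrow = length(pk$time))
}

detect_peaks_core <- function(y, t = seq_along(y)) {
  if (length(y) < 3L) stop("need at least 3 samples to detect peaks")
  if (any(!is.finite(y))) stop("series must be finite")
  if (diff(range(y)) == 0) {
    stop("all-equal series has no peaks")
  }
  peaks <- local_maxima(y)
  prom <- peak_prominences(y, peaks)
  ord <- order(-prom, t[peaks])
  list(
    time = t[peaks][ord],
    index = peaks[ord],
    height = y[peaks][ord],
    prominence = prom[ord]
  )
}

# Robust estimate of the i.i.d. sample-to-sample jitter of a series from the
# median absolute first difference (slopes of a smooth signal barely move the
# median when most of the record is near baseline).
estimate_jitter <- function(y) {
  d <- diff(y)
  median(abs(d - median(d))) / (0.6745 * sqrt(2))
}

.sg_cache <- new.env(parent = emptyenv())

sg_coefficients <- function(n_filt) {
  key <- as.character(n_filt)
  if (is.null(.sg_cache[[key]])) {
    .sg_cache[[key]] <- signal::sgolay(p = 2, n = n_filt)
  }
  .sg_cache[[key]]
}

# Noise-aware conditioning: when the jitter estimate exceeds `floor_mm`, the
# series is Savitzky-Golay filtered (local quadratic) so that the sample-level
# extrema feeding the prominence computation are not dominated by
# extreme-value noise bias. Clean series pass through untouched.
condition_series <- function(y, fs, floor_mm = 0.5) {
  sigma <- estimate_jitter(y)
  if (!is.finite(sigma) || sigma <= floor_mm) {
    return(list(y = y, conditioned = FALSE, sigma = sigma))
  }
  n_filt <- min(21L, length(y) - (1L - length(y) %% 2L))
  if (n_filt %% 2L == 0L) n_filt <- n_filt - 1L
  if (n_filt < 5L) return(list(y = y, conditioned = FALSE, sigma = sigma))
  list(
    y = as.numeric(signal::sgolayfilt(y, sg_coefficients(n_filt))),
    conditioned = TRUE, sigma = sigma
  )
}

# Sub-sample refinement of a peak: vertex of a least-squares quadratic over
# +/- `half` samples around the discrete argmax.
refine_peak <- function(t, y, i, half = 10L) {
  lo <- max(1L, i - half)
  hi <- min(length(y), i + half)
  idx <- lo:hi
  tt <- t[idx] - t[i]
  X <- cbind(1, tt, tt^2)
  cf <- tryCatch(qr.solve(X, y[idx]), error = function(e) NULL)
  if (is.null(cf) || !is.finite(cf[3L]) || cf[3L] >= 0) {
    return(list(time = t[i], height = y[i]))
  }
  tv <- -cf[2L] / (2 * cf[3L])
  if (abs(tv) > max(abs(tt))) {
    return(list(time = t[i], height = y[i]))
  }
  list(time = t[i] + tv, height = cf[1L] - cf[2L]^2 / (4 * cf[3L]))
}

#' Segment a trial into its eight sub-movements
#'
#' Within the analysis window, each chain marker's primary peak is its
#' maximum-prominence peak (the "most visible upward peak"); the remaining
#' peaks above the prominence floor are kept as secondary (residual) peaks.
#' Sub-movement durations are the seven successive primary-peak intervals in
#' wave traversal order (chain order, reversed for right-to-left trials).
#' Out-of-order peaks are flagged via `valid_order`, not discarded.
#'
#' When a marker's series carries measurable sensor jitter (robust estimate
#' above `noise_floor`), the series is conditioned with a Savitzky-Golay
#' filter and the primary peak's time and height are refined by a local
#' quadratic vertex fit, keeping peak estimates near-unbiased under noise;
#' clean series are used untouched, so noise-free trials segment exactly.
#'
#' @param trial A preprocessed `wave_trial`.
#' @param window `c(t_start, t_end)` from [select_analysis_window()];
#'   defaults to the full record.
#' @param min_prominence Prominence floor in mm below which peaks are treated
#'   as noise.
#' @param noise_floor Jitter estimate (mm) above which conditioning engages.
#' @return A `wave_segmentation`: tibble `sub_movements` (traversal order,
#'   chain index, peak time/height, prominence, secondary-peak summary),
#'   `sub_durations` (7 intervals, s), `valid_order`, and the window used.
#' @export
segment_wave <- function(trial, window = NULL, min_prominence = 5,
                         noise_floor = 0.5) {
  validate_wave_trial(trial)
  if (is.null(window)) window <- range(trial$t)
  in_win <- trial$t >= window[1L] & trial$t <= window[2L]
  if (sum(in_win) < 3L) stop("analysis window contains fewer than 3 samples")
  h <- trial_height(trial, chain_only = TRUE)
  # column order of `h` is chain index 1..8; traversal visits:
  trav_chain <- if (trial$direction == "left-to-right") 1:8 else 8:1

  t_win <- trial$t[in_win]
  peak_time <- peak_height <- prominence <- numeric(8L)
  n_secondary <- integer(8L)
  max_secondary <- numeric(8L)
  sec_chain <- integer(0); sec_time <- sec_prom <- numeric(0)
  conditioned_any <- FALSE
  for (p in 1:8) {
    ci <- trav_chain[p]
    yj <- h[in_win, ci]
    if (any(!is.finite(yj))) {
      # unresolved gaps: fall back to linear bridging for detection only
      ok <- is.finite(yj)
      if (sum(ok) < 3L) stop("chain marker ", ci, " has too few valid samples")
      yj <- stats::approx(t_win[ok], yj[ok], xout = t_win, rule = 2)$y
    }
    cs <- condition_series(yj, trial$sampling_rate, noise_floor)
    conditioned_any <- conditioned_any || cs$conditioned
    pk <- tryCatch(detect_peaks_core(cs$y, t_win), error = function(e) NULL)
    if (is.null(pk) || !length(pk$time) || max(pk$prominence) < min_prominence) {
      stop(
        "no peak with prominence >= ", min_prominence,
        " mm for chain marker ", ci, "; incomplete wave"
      )
    }
    peak_time[p] <- pk$time[1L]
    peak_height[p] <- pk$height[1L]
    prominence[p] <- pk$prominence[1L]
    if (cs$conditioned) {
      ref <- refine_peak(t_win, cs$y, pk$index[1L])
      prominence[p] <- prominence[p] + (ref$height - peak_height[p])
      peak_time[p] <- ref$time
      peak_height[p] <- ref$height
    }
    keep <- which(pk$prominence[-1L] >= min_prominence) + 1L
    n_secondary[p] <- length(keep)
    max_secondary[p] <- if (length(keep)) max(pk$prominence[keep]) else 0
    if (length(keep)) {
      sec_chain <- c(sec_chain, rep(ci, length(keep)))
      sec_time <- c(sec_time, pk$time[keep])
      sec_prom <- c(sec_prom, pk$prominence[keep])
    }
  }
  sub <- tibble::new_tibble(
    list(
      order = 1:8, chain_index = trav_chain,
      marker_id = colnames(h)[trav_chain],
      peak_time = peak_time, peak_height = peak_height,
      prominence = prominence, n_secondary = n_secondary,
      max_secondary_prominence = max_secondary
    ),
    nrow = 8L
  )
  durations <- diff(sub$peak_time)
  structure(
    list(
      direction = trial$direction,
      sub_movements = sub,
      secondary_peaks = tibble::new_tibble(
        list(chain_index = sec_chain, time = sec_time, prominence = sec_prom),
        nrow = length(sec_chain)
      ),
      sub_durations = durations,
      valid_order = all(durations > 0),
      window = window,
      conditioned = conditioned_any
    ),
    class = "wave_segmentation"
  )
}

#' @export
print.wave_segmentation <- function(x, ...) {
  cat(sprintf(
    "<wave_segmentation> %s, %d sub-movements, order %s\n",
    x$direction, nrow(x$sub_movements),
    if (x$valid_order) "valid" else "OUT OF ORDER"
  ))
  cat(sprintf(
    "  peak times (s): %s\n",
    paste(sprintf("%.2f", x$sub_movements$peak_time), collapse = " ")
  ))
  cat(sprintf(
    "  prominences (mm): %s\n",
    paste(sprintf("%.0f", x$sub_movements$prominence), collapse = " ")
  ))
  invisible(x)
}
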