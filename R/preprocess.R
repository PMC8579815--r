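#' @title Dropout repair and analysis-window selection
#' @description Optical trackers lose markers when they rotate out of camera
#'   view; interior gaps are repaired by cubic-spline interpolation, longer or
#'   boundary gaps stay missing and count toward a per-trial exclusion rule.
#' @name preprocess
NULL

# Run-length encode the TRUE runs of a logical vector.
missing_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

#' Repair marker dropout by cubic-spline interpolation
#'
#' Interior gaps of at most `max_gap_samples` are filled, per coordinate, by
#' a cubic spline (`stats::splinefun`, method `"fmm"`, which reproduces cubic
#' polynomials exactly) fit to the marker's valid samples. Longer gaps, and
#' gaps touching the record boundary (where a spline would extrapolate), are
#' left missing and counted as unresolved. Valid samples are never altered,
#' and the operation is idempotent.
#'
#' @param trial A `wave_trial`.
#' @param max_gap_samples Longest gap (in samples) the spline may bridge.
#'   The default, 30 samples (0.3 s at 100 Hz), keeps the spline from
#'   hallucinating across long occlusions.
#' @return A list with elements `trial` (repaired) and `report` (a
#'   `gap_report`: per-marker gap runs, pre-interpolation missing fraction,
#'   post-interpolation unresolved fraction over samples and over markers
#'   with unresolved data, and an exclusion flag left `FALSE` until
#'   [apply_exclusion_rule()] is applied).
#' @export
interpolate_gaps <- function(trial, max_gap_samples = 30) {
  validate_wave_trial(trial)
  n <- length(trial$t)
  m <- length(trial$marker_id)
  runs_all <- list()
  for (j in seq_len(m)) {
    mask <- trial$missing[, j]
    if (sum(!mask) < 4L) {
      stop("marker ", trial$marker_id[j],
           " has fewer than 4 valid samples; spline is underdetermined")
    }
    runs <- missing_runs(mask)
    if (nrow(runs)) {
      runs$marker_id <- trial$marker_id[j]
      runs_all[[length(runs_all) + 1L]] <- runs
    }
    if (!any(mask)) next
    valid <- which(!mask)
    for (k in seq_len(nrow(runs))) {
      s <- runs$start[k]; len <- runs$length[k]; e <- s + len - 1L
      interior <- s > 1L && e < n
      if (!interior || len > max_gap_samples) next
      idx <- s:e
      for (ax in c("x", "y", "z")) {
        f <- splinefun(trial$t[valid], trial[[ax]][valid, j], method = "fmm")
        trial[[ax]][idx, j] <- f(trial$t[idx])
      }
      trial$missing[idx, j] <- FALSE
    }
  }
  pre_frac <- sum(vapply(runs_all, function(r) sum(r$length), numeric(1))) /
    (n * m)
  unresolved <- sum(trial$missing) / (n * m)
  report <- structure(
    list(
      gap_runs = if (length(runs_all)) {
        do.call(rbind, runs_all)[, c("marker_id", "start", "length")]
      } else {
        data.frame(marker_id = character(), start = integer(),
                   length = integer())
      },
      pre_missing_fraction = pre_frac,
      unresolved_fraction = unresolved,
      any_unresolved = unresolved > 0,
      max_gap_samples = max_gap_samples,
      trial_excluded = FALSE
    ),
    class = "gap_report"
  )
  list(trial = trial, report = report)
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf(
    "<gap_report> %d gap run(s); missing %.2f%% -> unresolved %.2f%%%s\n",
    nrow(x$gap_runs), 100 * x$pre_missing_fraction,
    100 * x$unresolved_fraction,
    if (x$trial_excluded) " [excluded]" else ""
  ))
  invisible(x)
}

#' Exclude trials with too much unresolved missing data
#'
#' A trial is excluded when its post-interpolation unresolved missing-data
#' fraction reaches `threshold` (default 3% of samples, the conventional
#' residual-dropout tolerance after spline repair).
#'
#' @param report A `gap_report` from [interpolate_gaps()].
#' @param threshold Unresolved fraction at or above which the trial is
#'   excluded.
#' @return The report with `trial_excluded` set.
#' @export
apply_exclusion_rule <- function(report, threshold = 0.03) {
  stopifnot(inherits(report, "gap_report"))
  report$trial_excluded <- report$unresolved_fraction >= threshold
  report
}

#' Select the analysis window containing the whole wave
#'
#' Automates the usual manual cropping of wave recordings: for each chain
#' marker, height is referenced to a per-marker baseline (median of the
#' pre-activity segment), and the marker counts as active wherever its
#' excursion exceeds `threshold_frac` of its own peak excursion. The window
#' spans the earliest to the latest activity of any chain marker, padded by
#' `pad` seconds and clipped to the record. A manual override stored in
#' `trial$window_override` (e.g. from a manifest's `t_start`/`t_end`) is
#' honored as-is.
#'
#' @param trial A preprocessed `wave_trial`.
#' @param threshold_frac Activity threshold as a fraction of each marker's
#'   peak excursion.
#' @param pad Padding in seconds on both sides.
#' @param min_excursion Minimum peak excursion in mm for a marker to count as
#'   moving at all; below it the trial is unsegmentable.
#' @return Numeric `c(t_start, t_end)`.
#' @export
select_analysis_window <- function(trial, threshold_frac = 0.10, pad = 0.25,
                                   min_excursion = 5) {
  validate_wave_trial(trial)
  if (!is.null(trial$window_override)) {
    w <- as.numeric(trial$window_override)
    if (length(w) != 2L || w[1L] >= w[2L]) {
      stop("window override must be c(t_start, t_end) with t_start < t_end")
    }
    return(w)
  }
  h <- trial_height(trial, chain_only = TRUE)
  first_active <- rep(NA_real_, ncol(h))
  last_active <- rep(NA_real_, ncol(h))
  for (j in seq_len(ncol(h))) {
    yj <- h[, j]
    base <- median(yj, na.rm = TRUE)
    exc <- yj - base
    peak <- max(exc, na.rm = TRUE)
    if (!is.finite(peak) || peak < min_excursion) {
      stop("chain marker ", colnames(h)[j] %||% j,
           " shows no supra-threshold activity; trial is unsegmentable")
    }
    act <- which(exc > threshold_frac * peak)
    # refine the baseline to the pre-activity segment when one exists
    if (act[1L] > 5L) {
      base <- median(yj[seq_len(act[1L] - 1L)], na.rm = TRUE)
      exc <- yj - base
      peak <- max(exc, na.rm = TRUE)
      act <- which(exc > threshold_frac * peak)
    }
    first_active[j] <- trial$t[act[1L]]
    last_active[j] <- trial$t[act[length(act)]]
  }
  c(
    max(min(trial$t), min(first_active) - pad),
    min(max(trial$t), max(last_active) + pad)
  )
}
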