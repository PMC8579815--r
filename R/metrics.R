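#' @title Per-trial wave-quality metrics
#' @description The per-trial metric vector: mean wave amplitude,
#'   wrist-minus-shoulder amplitude differentiation, residual (unwanted)
#'   movement amplitude and the wave/residual signal-to-noise ratio, wave and
#'   sub-movement durations, the coefficient of variation of propagation
#'   speed, and the shoulder-to-shoulder interval.
#' @name metrics
NULL

#' Coefficient of variation of propagation speed
#'
#' `100 * SD(durations) / mean(durations)`, the within-trial variability of
#' the sub-movement durations expressed as a percentage. A wave travelling at
#' constant speed along the chain has equal inter-peak intervals and hence a
#' COV of 0; the statistic is invariant to rescaling all durations.
#'
#' @param sub_durations At least two inter-peak intervals in seconds.
#' @return COV in percent.
#' @examples
#' cov_propagation_speed(rep(0.25, 7)) # 0
#' @export
cov_propagation_speed <- function(sub_durations) {
  if (length(sub_durations) < 2L) {
    stop("need at least two sub-movement durations")
  }
  mu <- mean(sub_durations)
  if (!is.finite(mu) || mu == 0) {
    stop("mean sub-movement duration is zero; COV undefined")
  }
  100 * sd(sub_durations) / mu
}

#' Residual (unwanted) movement amplitude
#'
#' Movement in segments that should be stationary. Two readings are
#' supported: `"secondary-peak"` (default) averages, over the eight chain
#' markers, the largest non-primary peak prominence within the window (zero
#' for markers that moved exactly once) -- each segment's motion outside its
#' own sub-movement is the noise. `"stationary-markers"` instead averages the
#' primary-peak prominence of designated non-chain markers.
#'
#' @param segmentation A `wave_segmentation`.
#' @param trial The trial the segmentation came from (needed for
#'   `"stationary-markers"` mode).
#' @param mode Residual definition, see above.
#' @return Residual amplitude in mm with the mode recorded as an attribute.
#' @export
residual_amplitude <- function(segmentation, trial = NULL,
                               mode = c("secondary-peak", "stationary-markers")) {
  mode <- match.arg(mode)
  stopifnot(inherits(segmentation, "wave_segmentation"))
  if (mode == "secondary-peak") {
    value <- mean(segmentation$sub_movements$max_secondary_prominence)
  } else {
    if (is.null(trial)) stop("stationary-markers mode needs the trial")
    extra <- which(is.na(trial$chain_index))
    if (!length(extra)) {
      stop("no stationary (non-chain) markers configured in this trial")
    }
    win <- segmentation$window
    in_win <- trial$t >= win[1L] & trial$t <= win[2L]
    proms <- vapply(extra, function(j) {
      yj <- trial[[trial$height_axis]][in_win, j]
      yj <- yj[is.finite(yj)]
      pk <- tryCatch(detect_peaks(yj), error = function(e) NULL)
      if (is.null(pk) || nrow(pk) == 0L) 0 else pk$prominence[1L]
    }, numeric(1))
    value <- mean(proms)
  }
  structure(value, mode = mode)
}

#' Wave over residual amplitude ratio
#'
#' The signal-to-noise ratio of the trial: intended wave amplitude over the
#' amplitude of unwanted movement. A zero residual yields an infinite
#' sentinel (flagged, not an error).
#'
#' @param wave_amplitude Mean primary prominence in mm.
#' @param residual_amplitude Residual amplitude in mm.
#' @return The ratio, `Inf` when the residual is zero.
#' @export
wave_residual_ratio <- function(wave_amplitude, residual_amplitude) {
  if (residual_amplitude == 0) return(Inf)
  wave_amplitude / residual_amplitude
}

#' Shoulder-to-shoulder interval
#'
#' Time between the two shoulder markers' primary peaks (traversal positions
#' 4 and 5), in seconds and as a percentage of the wave duration. A long
#' relative interval marks a chunking strategy: one arm's wave, a pause, then
#' the other arm's.
#'
#' @param segmentation A `wave_segmentation`.
#' @return Named numeric `c(interval, percent)`.
#' @export
shoulder_to_shoulder <- function(segmentation) {
  stopifnot(inherits(segmentation, "wave_segmentation"))
  tt <- segmentation$sub_movements$peak_time
  interval <- tt[5L] - tt[4L]
  duration <- tt[8L] - tt[1L]
  c(
    interval = interval,
    percent = if (duration > 0) 100 * interval / duration else NA_real_
  )
}

#' Compute the full per-trial metric vector
#'
#' @param segmentation A `wave_segmentation` from [segment_wave()].
#' @param trial The corresponding `wave_trial` (for metadata and the
#'   stationary-markers residual mode).
#' @param residual_mode Passed to [residual_amplitude()].
#' @return One-row tibble: trial key, the seven quality metrics
#'   (`wave_amplitude`, `wrist_minus_shoulder`, `residual_amplitude`,
#'   `wave_residual_ratio`, `shoulder_interval`, `wave_duration`,
#'   `cov_propagation`) plus `mean_sub_duration`, `shoulder_interval_pct`,
#'   `valid_order`, and bookkeeping flags.
#' @export
compute_trial_metrics <- function(segmentation, trial,
                                  residual_mode = c("secondary-peak",
                                                    "stationary-markers")) {
  residual_mode <- match.arg(residual_mode)
  stopifnot(inherits(segmentation, "wave_segmentation"))
  sub <- segmentation$sub_movements
  prom <- sub$prominence
  wave_amplitude <- mean(prom)
  wrists <- prom[sub$chain_index %in% c(2L, 7L)]
  shoulders <- prom[sub$chain_index %in% c(4L, 5L)]
  wrist_minus_shoulder <- mean(wrists) - mean(shoulders)
  resid <- residual_amplitude(segmentation, trial, residual_mode)
  ratio <- wave_residual_ratio(wave_amplitude, as.numeric(resid))
  durations <- segmentation$sub_durations
  wave_duration <- sum(durations)
  s2s <- shoulder_to_shoulder(segmentation)
  tibble::new_tibble(list(
    participant_id = trial$participant_id,
    block = trial$block,
    focus = trial$focus,
    direction = trial$direction,
    trial_index = trial$trial_index,
    wave_amplitude = wave_amplitude,
    wrist_minus_shoulder = wrist_minus_shoulder,
    residual_amplitude = as.numeric(resid),
    residual_mode = attr(resid, "mode"),
    wave_residual_ratio = ratio,
    ratio_flagged = !is.finite(ratio),
    wave_duration = wave_duration,
    mean_sub_duration = mean(durations),
    cov_propagation = cov_propagation_speed(durations),
    shoulder_interval = unname(s2s["interval"]),
    shoulder_interval_pct = unname(s2s["percent"]),
    valid_order = segmentation$valid_order,
    excluded = FALSE,
    note = NA_character_
  ), nrow = 1L)
}

# An all-NA metrics row for trials that could not be analyzed; fields are
# explicitly missing, never silent zeros.
empty_metrics_row <- function(trial, excluded, note) {
  tibble::new_tibble(list(
    participant_id = trial$participant_id,
    block = trial$block,
    focus = trial$focus,
    direction = trial$direction,
    trial_index = trial$trial_index,
    wave_amplitude = NA_real_,
    wrist_minus_shoulder = NA_real_,
    residual_amplitude = NA_real_,
    residual_mode = NA_character_,
    wave_residual_ratio = NA_real_,
    ratio_flagged = NA,
    wave_duration = NA_real_,
    mean_sub_duration = NA_real_,
    cov_propagation = NA_real_,
    shoulder_interval = NA_real_,
    shoulder_interval_pct = NA_real_,
    valid_order = NA,
    excluded = excluded,
    note = note
  ), nrow = 1L)
}
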