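#' Analysis parameters for the trial pipeline
#'
#' Bundles the tunable thresholds of the preprocessing and segmentation
#' stages with their defaults.
#'
#' @param max_gap_samples Longest dropout gap the spline may bridge.
#' @param exclusion_threshold Unresolved missing-data fraction at or above
#'   which a trial is excluded.
#' @param window_threshold_frac Activity threshold for window selection, as a
#'   fraction of per-marker peak excursion.
#' @param window_pad Window padding in seconds.
#' @param min_excursion Minimum per-marker peak excursion in mm.
#' @param min_prominence Prominence floor in mm for peak detection.
#' @param noise_floor Jitter level (mm) above which noise-aware peak
#'   conditioning engages.
#' @param residual_mode Residual-amplitude definition, see
#'   [residual_amplitude()].
#' @return A list of class `wave_params`.
#' @export
wave_params <- function(max_gap_samples = 30,
                        exclusion_threshold = 0.03,
                        window_threshold_frac = 0.10,
                        window_pad = 0.25,
                        min_excursion = 5,
                        min_prominence = 5,
                        noise_floor = 0.5,
                        residual_mode = "secondary-peak") {
  structure(
    list(
      max_gap_samples = max_gap_samples,
      exclusion_threshold = exclusion_threshold,
      window_threshold_frac = window_threshold_frac,
      window_pad = window_pad,
      min_excursion = min_excursion,
      min_prominence = min_prominence,
      noise_floor = noise_floor,
      residual_mode = residual_mode
    ),
    class = "wave_params"
  )
}

#' Run the full per-trial pipeline
#'
#' Gap repair, exclusion rule, window selection, segmentation, metrics. A
#' trial that fails the exclusion rule or cannot be segmented yields a row
#' with explicitly missing metric fields and a note, never silent zeros.
#'
#' @param trial A `wave_trial`.
#' @param params A [wave_params()].
#' @return One-row metrics tibble (see [compute_trial_metrics()]).
#' @export
analyze_trial <- function(trial, params = wave_params()) {
  repaired <- interpolate_gaps(trial, params$max_gap_samples)
  report <- apply_exclusion_rule(repaired$report, params$exclusion_threshold)
  if (report$trial_excluded) {
    return(empty_metrics_row(
      trial, excluded = TRUE,
      note = sprintf("excluded: %.1f%% unresolved missing data",
                     100 * report$unresolved_fraction)
    ))
  }
  tryCatch({
    window <- select_analysis_window(
      repaired$trial,
      threshold_frac = params$window_threshold_frac,
      pad = params$window_pad,
      min_excursion = params$min_excursion
    )
    seg <- segment_wave(
      repaired$trial, window,
      min_prominence = params$min_prominence,
      noise_floor = params$noise_floor
    )
    compute_trial_metrics(seg, repaired$trial, params$residual_mode)
  }, error = function(e) {
    empty_metrics_row(trial, excluded = FALSE, note = conditionMessage(e))
  })
}

#' Analyze a whole cohort
#'
#' Either analyzes an existing collection of trials, or -- when given a
#' [cohort_design()] -- generates and analyzes the cohort trial-by-trial
#' without materializing all trajectories at once, which keeps memory flat
#' for large simulation studies.
#'
#' @param cohort A `wave_cohort` from [generate_cohort()], a list of
#'   `wave_trial`s, or a [cohort_design()].
#' @param base_spec Base [wave_spec()] when `cohort` is a design.
#' @param params A [wave_params()].
#' @return A metrics tibble with one row per trial. When the cohort was
#'   generated here, the per-participant ground-truth table is attached as
#'   attribute `"truth"`.
#' @export
analyze_cohort <- function(cohort, base_spec = wave_spec(),
                           params = wave_params()) {
  if (inherits(cohort, "cohort_design")) {
    walked <- cohort_walk(cohort, base_spec, function(tr) {
      analyze_trial(tr, params)
    })
    out <- dplyr::bind_rows(walked$results)
    truth <- walked$participants
    truth$shape <- vapply(
      truth$shape, function(s) paste(signif(s, 6), collapse = ";"),
      character(1)
    )
    attr(out, "truth") <- truth
    return(out)
  }
  trials <- if (inherits(cohort, "wave_cohort")) cohort$trials else cohort
  out <- dplyr::bind_rows(lapply(trials, analyze_trial, params = params))
  if (inherits(cohort, "wave_cohort")) attr(out, "truth") <- cohort$truth
  out
}
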