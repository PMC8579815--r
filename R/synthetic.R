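#' Generative specification for a synthetic wave trial
#'
#' Describes the ground truth of one simulated wave attempt: a vertical
#' displacement pulse per chain marker, riding on a shoulder-level baseline,
#' contaminated by smooth residual motion outside each marker's own pulse,
#' i.i.d. sensor jitter, and occasional marker-dropout gaps.
#'
#' Defaults represent a competent novice trial under typical optical
#' motion-capture conditions: hand amplitudes larger than shoulder amplitudes,
#' a wave lasting about 1.9 s inside a 3 s record sampled at 100 Hz, sensor
#' jitter at the 0.2 mm accuracy of research-grade trackers, residual
#' (unwanted) motion an order of magnitude below the wave, and dropout in 5%
#' of trials.
#'
#' @param chain_amplitudes Eight pulse amplitudes in mm, in wave traversal
#'   order (first-moving segment first).
#' @param chain_onsets Eight pulse-peak times in s, strictly increasing, in
#'   traversal order.
#' @param pulse_width Temporal half-width of each pulse in s; the pulse has
#'   compact support `[onset - pulse_width, onset + pulse_width]`.
#' @param baseline_height Resting (shoulder-level) height in mm.
#' @param residual_sd Amplitude scale (mm) of smooth unwanted motion injected
#'   outside a marker's own pulse support.
#' @param sensor_noise_sd I.i.d. Gaussian measurement jitter in mm.
#' @param dropout_trial_fraction Probability that a trial contains one
#'   contiguous missing-data gap.
#' @param dropout_gap_length Gap length in samples when dropout occurs.
#' @param sampling_rate Samples per second.
#' @param trial_duration Record length in s.
#' @param direction `"left-to-right"` or `"right-to-left"`.
#' @param pulse_shape `"hann"` (raised-cosine lobe, default) or `"gaussian"`
#'   (truncated to the same support).
#' @param emit_head_marker Also emit the stationary head-reference marker
#'   (ignored by the analysis chain)?
#' @param seed Optional integer; when given, trial generation is reproducible
#'   in isolation. When `NULL` the current RNG stream is used (so a cohort
#'   generator can drive many trials from one seed).
#'
#' @return An object of class `wave_spec`.
#' @examples
#' spec <- wave_spec(residual_sd = 0, sensor_noise_sd = 0, seed = 1)
#' trial <- generate_trial(spec)
#' @export
wave_spec <- function(chain_amplitudes = c(150, 130, 105, 85, 85, 105, 130, 150),
                      chain_onsets = seq(0.55, by = 0.27, length.out = 8),
                      pulse_width = 0.4,
                      baseline_height = 1100,
                      residual_sd = 10,
                      sensor_noise_sd = 0.2,
                      dropout_trial_fraction = 0.05,
                      dropout_gap_length = 15,
                      sampling_rate = 100,
                      trial_duration = 3,
                      direction = c("left-to-right", "right-to-left"),
                      pulse_shape = c("hann", "gaussian"),
                      emit_head_marker = FALSE,
                      seed = NULL) {
  direction <- match.arg(direction)
  pulse_shape <- match.arg(pulse_shape)
  if (length(chain_amplitudes) != 8L || any(!is.finite(chain_amplitudes)) ||
      any(chain_amplitudes < 0)) {
    stop("`chain_amplitudes` must be 8 finite non-negative values (mm)")
  }
  if (length(chain_onsets) != 8L || any(!is.finite(chain_onsets)) ||
      any(diff(chain_onsets) <= 0)) {
    stop("`chain_onsets` must be 8 strictly increasing times (s)")
  }
  if (pulse_width <= 0) stop("`pulse_width` must be positive")
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive")
  if (trial_duration <= 0) stop("`trial_duration` must be positive")
  if (residual_sd < 0 || sensor_noise_sd < 0) {
    stop("noise standard deviations must be non-negative")
  }
  if (dropout_trial_fraction < 0 || dropout_trial_fraction > 1) {
    stop("`dropout_trial_fraction` must lie in [0, 1]")
  }
  if (dropout_gap_length < 1) stop("`dropout_gap_length` must be >= 1 sample")
  if (chain_onsets[1L] - pulse_width < 0 ||
      chain_onsets[8L] + pulse_width > trial_duration) {
    stop(
      "pulse support extends beyond the trial record: ",
      "onsets must satisfy onset - pulse_width >= 0 and ",
      "onset + pulse_width <= trial_duration"
    )
  }
  structure(
    list(
      chain_amplitudes = as.numeric(chain_amplitudes),
      chain_onsets = as.numeric(chain_onsets),
      pulse_width = pulse_width,
      baseline_height = baseline_height,
      residual_sd = residual_sd,
      sensor_noise_sd = sensor_noise_sd,
      dropout_trial_fraction = dropout_trial_fraction,
      dropout_gap_length = as.integer(dropout_gap_length),
      sampling_rate = sampling_rate,
      trial_duration = trial_duration,
      direction = direction,
      pulse_shape = pulse_shape,
      emit_head_marker = isTRUE(emit_head_marker),
      seed = seed
    ),
    class = "wave_spec"
  )
}

#' @export
print.wave_spec <- function(x, ...) {
  cat("<wave_spec>\n")
  cat(sprintf(
    "  amplitudes (mm): %s\n", paste(signif(x$chain_amplitudes, 4), collapse = " ")
  ))
  cat(sprintf(
    "  onsets (s): %s\n", paste(signif(x$chain_onsets, 4), collapse = " ")
  ))
  cat(sprintf(
    "  pulse half-width %.3g s, %s pulse, %s\n",
    x$pulse_width, x$pulse_shape, x$direction
  ))
  cat(sprintf(
    "  residual sd %.3g mm, sensor sd %.3g mm, dropout %.3g of trials\n",
    x$residual_sd, x$sensor_noise_sd, x$dropout_trial_fraction
  ))
  cat(sprintf(
    "  %.3g s at %.5g Hz\n", x$trial_duration, x$sampling_rate
  ))
  invisible(x)
}

# Unimodal pulse with g(0) = 1 and compact support |u| <= 1.
pulse_kernel <- function(u, shape = "hann") {
  g <- numeric(length(u))
  inside <- abs(u) < 1
  if (shape == "hann") {
    g[inside] <- cos(pi * u[inside] / 2)^2
  } else {
    g[inside] <- exp(-0.5 * (2.5 * u[inside])^2)
  }
  g
}

# Smooth band-limited noise: natural cubic spline through Gaussian knots.
smooth_noise <- function(t, sd, knot_spacing = 0.25) {
  if (sd <= 0) return(numeric(length(t)))
  knots <- seq(min(t) - knot_spacing, max(t) + knot_spacing, by = knot_spacing)
  vals <- rnorm(length(knots), sd = sd)
  splinefun(knots, vals, method = "natural")(t)
}

#' Generate one synthetic wave trial
#'
#' Builds a trial whose vertical coordinate for chain marker *i* is
#' `baseline + A_i * g((t - t_i) / w) + residual(t) + noise(t)`, where `g` is a
#' unimodal pulse with unit peak and compact support, the residual term is
#' smooth low-amplitude motion active only outside marker *i*'s own pulse
#' support, and the noise term is i.i.d. sensor jitter. With probability
#' `dropout_trial_fraction` one contiguous run of samples in one randomly
#' chosen marker is masked missing.
#'
#' @param spec A [wave_spec()].
#' @param participant_id,block,focus,trial_index Trial metadata.
#' @return A `wave_trial` with a `"truth"` attribute holding the per-marker
#'   ground-truth amplitudes and onset times used.
#' @export
generate_trial <- function(spec, participant_id = "P01", block = 1L,
                           focus = c("external", "internal"),
                           trial_index = 1L) {
  stopifnot(inherits(spec, "wave_spec"))
  focus <- match.arg(focus)
  if (!is.null(spec$seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
      add = TRUE
    )
    set.seed(spec$seed)
  }

  fs <- spec$sampling_rate
  n <- round(spec$trial_duration * fs) + 1L
  t <- seq(0, by = 1 / fs, length.out = n)
  m <- 8L + spec$emit_head_marker

  marker_id <- .chain_marker_ids
  chain_index <- 1:8
  if (spec$emit_head_marker) {
    marker_id <- c(marker_id, "head_ref")
    chain_index <- c(chain_index, NA_integer_)
  }

  # traversal position of each physical marker
  pos <- if (spec$direction == "left-to-right") 1:8 else 8:1
  onset <- amp <- rep(NA_real_, m)
  onset[1:8] <- spec$chain_onsets[pos]
  amp[1:8] <- spec$chain_amplitudes[pos]

  z <- matrix(spec$baseline_height, n, m)
  x <- matrix(rep((c(1:8, if (spec$emit_head_marker) 4.5) - 4.5) * 170,
                  each = n), n, m)
  y <- matrix(0, n, m)
  if (spec$emit_head_marker) z[, m] <- spec$baseline_height + 350

  for (j in 1:8) {
    u <- (t - onset[j]) / spec$pulse_width
    z[, j] <- z[, j] + amp[j] * pulse_kernel(u, spec$pulse_shape)
    if (spec$residual_sd > 0) {
      # taper the residual to zero inside the marker's own pulse support
      mask <- pmin(1, pmax(0, (abs(t - onset[j]) - spec$pulse_width) / 0.1))
      z[, j] <- z[, j] + mask * smooth_noise(t, spec$residual_sd)
    }
  }
  if (spec$sensor_noise_sd > 0) {
    x <- x + rnorm(n * m, sd = spec$sensor_noise_sd)
    y <- y + rnorm(n * m, sd = spec$sensor_noise_sd)
    z <- z + rnorm(n * m, sd = spec$sensor_noise_sd)
  }

  missing <- matrix(FALSE, n, m)
  if (runif(1) < spec$dropout_trial_fraction) {
    gap <- min(spec$dropout_gap_length, n - 4L)
    marker <- sample.int(8L, 1L)
    start <- sample(seq(2L, n - gap), 1L)
    missing[start:(start + gap - 1L), marker] <- TRUE
  }

  # positions at masked samples are undefined
  x[missing] <- y[missing] <- z[missing] <- NA_real_
  colnames(x) <- colnames(y) <- colnames(z) <- colnames(missing) <- marker_id
  trial <- new_wave_trial(
    participant_id = participant_id, block = as.integer(block), focus = focus,
    direction = spec$direction, trial_index = as.integer(trial_index),
    t = t, sampling_rate = fs, marker_id = marker_id,
    chain_index = as.integer(chain_index),
    x = x, y = y, z = z, missing = missing
  )
  attr(trial, "truth") <- list(
    amplitudes = amp[1:8], onsets = onset[1:8],
    traversal_amplitudes = spec$chain_amplitudes,
    traversal_onsets = spec$chain_onsets,
    lag_cov = 100 * sd(diff(spec$chain_onsets)) / mean(diff(spec$chain_onsets))
  )
  trial
}

#' Cohort design for synthetic wave studies
#'
#' Describes a practice cohort: how many participants, the block structure and
#' attentional-focus counterbalancing, and the between-participant statistical
#' structure (amplitude spread, timing-constancy spread, and the induced
#' coupling between a participant's mean amplitude and onset-lag variability).
#'
#' The default design mirrors a 12-participant single-session study: 120
#' trials per participant in 4 blocks of 30, half the participants on an ABBA
#' and half on a BAAB condition order.
#'
#' @param n_participants Number of participants.
#' @param trials_per_block Trials per block.
#' @param n_blocks Number of blocks.
#' @param between_participant_amplitude_sd SD (mm) of participants' mean wave
#'   amplitude around the base spec's mean amplitude.
#' @param between_participant_timing_sd SD (s) across participants of the
#'   within-trial onset-lag jitter SD.
#' @param mean_timing_sd Cohort-mean within-trial onset-lag jitter SD (s).
#' @param amplitude_timing_coupling Coupling magnitude `c` in `[0, 1]`:
#'   participants' mean amplitude and onset-lag SD are drawn from a bivariate
#'   normal with correlation `-|c|`, so larger waves go with less constant
#'   propagation timing.
#' @param segment_shape_sd Relative SD of per-participant per-segment
#'   amplitude multipliers (articulation idiosyncrasy); 0 disables.
#' @param trial_amplitude_cv Relative SD of the per-trial amplitude scale
#'   within a participant.
#' @param residual_sd_cv Relative SD across participants of the residual-motion
#'   scale.
#' @param focus_amplitude_effect Mean amplitude difference (mm), external
#'   minus internal focus, applied additively to every segment amplitude.
#' @param focus_effect_sd Between-participant SD (mm) of that focus effect;
#'   individuals respond to attentional instructions to very different
#'   degrees, which is what keeps cohort-level focus effects marginal.
#' @param focus_A Which focus condition the letter "A" denotes in the
#'   ABBA/BAAB sequences.
#' @param seed Integer seed driving all cohort-level randomness.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_participants = 12,
                          trials_per_block = 30,
                          n_blocks = 4,
                          between_participant_amplitude_sd = 25,
                          between_participant_timing_sd = 0.012,
                          mean_timing_sd = 0.03,
                          amplitude_timing_coupling = 0.8,
                          segment_shape_sd = 0.12,
                          trial_amplitude_cv = 0.08,
                          residual_sd_cv = 0.4,
                          focus_amplitude_effect = 6,
                          focus_effect_sd = 12,
                          focus_A = c("external", "internal"),
                          seed = 1L) {
  focus_A <- match.arg(focus_A)
  if (n_participants < 1) stop("`n_participants` must be >= 1")
  if (trials_per_block < 1 || n_blocks < 1) {
    stop("block structure must have at least one trial and one block")
  }
  if (abs(amplitude_timing_coupling) > 1) {
    stop("`amplitude_timing_coupling` magnitude must not exceed 1")
  }
  if (between_participant_amplitude_sd < 0 ||
      between_participant_timing_sd < 0 || mean_timing_sd < 0) {
    stop("between-participant SDs must be non-negative")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      trials_per_block = as.integer(trials_per_block),
      n_blocks = as.integer(n_blocks),
      between_participant_amplitude_sd = between_participant_amplitude_sd,
      between_participant_timing_sd = between_participant_timing_sd,
      mean_timing_sd = mean_timing_sd,
      amplitude_timing_coupling = amplitude_timing_coupling,
      segment_shape_sd = segment_shape_sd,
      trial_amplitude_cv = trial_amplitude_cv,
      residual_sd_cv = residual_sd_cv,
      focus_amplitude_effect = focus_amplitude_effect,
      focus_effect_sd = focus_effect_sd,
      focus_A = focus_A,
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>\n")
  cat(sprintf(
    "  %d participants, %d blocks x %d trials (%d trials each)\n",
    x$n_participants, x$n_blocks, x$trials_per_block,
    x$n_blocks * x$trials_per_block
  ))
  cat(sprintf(
    "  amplitude sd %.3g mm, timing sd %.3g +/- %.3g s, coupling %.2f\n",
    x$between_participant_amplitude_sd, x$mean_timing_sd,
    x$between_participant_timing_sd, x$amplitude_timing_coupling
  ))
  invisible(x)
}

# Block focus sequence for one participant ("ABBA" or "BAAB").
focus_sequence <- function(sequence, n_blocks, focus_A) {
  focus_B <- setdiff(.focus_levels, focus_A)
  letters4 <- if (sequence == "ABBA") c("A", "B", "B", "A") else c("B", "A", "A", "B")
  rep(ifelse(letters4 == "A", focus_A, focus_B), length.out = n_blocks)
}

# Draw per-participant generative parameters for a cohort.
draw_participants <- function(design, base_spec) {
  np <- design$n_participants
  rho <- -abs(design$amplitude_timing_coupling)
  z1 <- rnorm(np)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(np)
  base_mean_amp <- mean(base_spec$chain_amplitudes)
  mean_amp <- pmax(
    0.1 * base_mean_amp,
    base_mean_amp + design$between_participant_amplitude_sd * z1
  )
  timing_sd <- pmax(
    0.002,
    design$mean_timing_sd + design$between_participant_timing_sd * z2
  )
  shapes <- matrix(1, np, 8)
  if (design$segment_shape_sd > 0) {
    shapes <- matrix(
      pmax(0.2, rnorm(np * 8, 1, design$segment_shape_sd)), np, 8
    )
  }
  residual_sd <- pmax(
    0.5, rnorm(np, base_spec$residual_sd,
               base_spec$residual_sd * design$residual_sd_cv)
  )
  focus_effect <- rnorm(np, design$focus_amplitude_effect,
                        design$focus_effect_sd)
  sequence <- rep(c("ABBA", "BAAB"), length.out = np)
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(np)),
    sequence = sequence,
    mean_amplitude = mean_amp,
    timing_sd = timing_sd,
    residual_sd = residual_sd,
    focus_effect = focus_effect,
    shape = lapply(seq_len(np), function(i) shapes[i, ])
  )
}

# Per-trial spec for one participant draw; jitters onset lags, rescaling the
# schedule (rarely) when the jittered wave would overrun the record.
participant_trial_spec <- function(base_spec, prt, design, focus, direction) {
  base_lags <- diff(base_spec$chain_onsets)
  lags <- pmax(0.02, base_lags + rnorm(7, sd = prt$timing_sd))
  span_max <- base_spec$trial_duration - 2 * base_spec$pulse_width - 0.05
  if (sum(lags) > span_max) lags <- lags * span_max / sum(lags)
  onsets <- cumsum(c(0, lags))
  onsets <- onsets - mean(onsets) + mean(base_spec$chain_onsets)

  amp_scale <- prt$mean_amplitude / mean(base_spec$chain_amplitudes)
  amps <- base_spec$chain_amplitudes * amp_scale * prt$shape[[1]]
  amps <- amps * max(0.1, rnorm(1, 1, design$trial_amplitude_cv))
  amps <- amps + if (focus == "external") prt$focus_effect / 2 else
    -prt$focus_effect / 2
  amps <- pmax(1, amps)

  spec <- base_spec
  spec$chain_amplitudes <- amps
  spec$chain_onsets <- onsets
  spec$residual_sd <- prt$residual_sd
  spec$direction <- direction
  spec$seed <- NULL
  spec
}

# Iterate a cohort trial-by-trial under the design's seed, applying `fn` to
# each generated trial. Keeps memory flat for large cohorts.
cohort_walk <- function(design, base_spec, fn) {
  stopifnot(inherits(design, "cohort_design"), inherits(base_spec, "wave_spec"))
  set.seed(design$seed)
  participants <- draw_participants(design, base_spec)
  out <- vector("list", design$n_participants *
                  design$n_blocks * design$trials_per_block)
  k <- 0L
  for (i in seq_len(design$n_participants)) {
    prt <- participants[i, ]
    foci <- focus_sequence(prt$sequence, design$n_blocks, design$focus_A)
    trial_counter <- 0L
    for (b in seq_len(design$n_blocks)) {
      for (tr in seq_len(design$trials_per_block)) {
        trial_counter <- trial_counter + 1L
        direction <- .wave_directions[2L - trial_counter %% 2L]
        spec_t <- participant_trial_spec(base_spec, prt, design,
                                         foci[b], direction)
        trial <- generate_trial(spec_t,
          participant_id = prt$participant_id, block = b,
          focus = foci[b], trial_index = trial_counter
        )
        k <- k + 1L
        out[[k]] <- fn(trial)
      }
    }
  }
  list(participants = participants, results = out)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-participant generative parameters around `base_spec` (mean
#' amplitude and onset-lag variability from a bivariate normal with
#' correlation `-|amplitude_timing_coupling|`, so large movers propagate less
#' constantly), then generates every trial of the block design with
#' alternating wave direction and counterbalanced ABBA/BAAB focus sequences.
#'
#' @param design A [cohort_design()].
#' @param base_spec A [wave_spec()] giving the cohort-mean trial; its `seed`
#'   is ignored (the design seed drives everything).
#' @return A list of class `wave_cohort` with elements `trials` (list of
#'   `wave_trial`), `truth` (per-participant generative parameter table) and
#'   `manifest` (per-trial metadata table).
#' @export
generate_cohort <- function(design, base_spec = wave_spec()) {
  walked <- cohort_walk(design, base_spec, identity)
  trials <- walked$results
  manifest <- dplyr::bind_rows(lapply(trials, function(tr) {
    tibble::tibble(
      participant_id = tr$participant_id, block_index = tr$block,
      focus = tr$focus, direction = tr$direction, trial_index = tr$trial_index
    )
  }))
  truth <- walked$participants
  truth$shape <- vapply(
    truth$shape, function(s) paste(signif(s, 6), collapse = ";"), character(1)
  )
  structure(
    list(trials = trials, truth = truth, manifest = manifest,
         design = design, base_spec = base_spec),
    class = "wave_cohort"
  )
}

#' @export
print.wave_cohort <- function(x, ...) {
  cat(sprintf(
    "<wave_cohort> %d trials, %d participants\n",
    length(x$trials), x$design$n_participants
  ))
  invisible(x)
}
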