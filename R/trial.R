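#' @title Wave trial objects
#' @description A `wave_trial` bundles one participant's single wave attempt:
#'   a common time base, per-marker 3D positions (columns of the `x`, `y`, `z`
#'   matrices), a missing-sample mask, the chain-role of each marker, and the
#'   trial metadata (participant, block, attentional focus, wave direction).
#' @name wave_trial
NULL

new_wave_trial <- function(participant_id, block, focus, direction,
                           trial_index, t, sampling_rate, marker_id,
                           chain_index, x, y, z, missing,
                           height_axis = "z", window_override = NULL) {
  trial <- structure(
    list(
      participant_id = participant_id, block = block, focus = focus,
      direction = direction, trial_index = trial_index,
      t = t, sampling_rate = sampling_rate,
      marker_id = marker_id, chain_index = chain_index,
      x = x, y = y, z = z, missing = missing,
      height_axis = height_axis, window_override = window_override
    ),
    class = "wave_trial"
  )
  validate_wave_trial(trial)
  trial
}

validate_wave_trial <- function(trial) {
  n <- length(trial$t)
  m <- length(trial$marker_id)
  if (n < 2L) stop("a trial needs at least two samples")
  if (any(diff(trial$t) <= 0)) stop("timestamps must be strictly increasing")
  for (ax in c("x", "y", "z", "missing")) {
    if (!is.matrix(trial[[ax]]) || nrow(trial[[ax]]) != n ||
        ncol(trial[[ax]]) != m) {
      stop(sprintf("`%s` must be a %d x %d matrix", ax, n, m))
    }
  }
  chain <- trial$chain_index[!is.na(trial$chain_index)]
  if (!setequal(chain, 1:8) || length(chain) != 8L) {
    missing_idx <- setdiff(1:8, chain)
    stop(
      "trial must cover chain indices 1..8 exactly once",
      if (length(missing_idx)) {
        paste0("; absent: ", paste(missing_idx, collapse = ", "))
      }
    )
  }
  if (!trial$focus %in% .focus_levels) {
    stop("`focus` must be \"internal\" or \"external\"")
  }
  if (!trial$direction %in% .wave_directions) {
    stop("`direction` must be \"left-to-right\" or \"right-to-left\"")
  }
  if (!trial$height_axis %in% c("x", "y", "z")) {
    stop("`height_axis` must be one of \"x\", \"y\", \"z\"")
  }
  invisible(trial)
}

#' Height (vertical) coordinates of a trial
#'
#' @param trial A `wave_trial`.
#' @param chain_only Return only the eight chain markers, ordered by chain
#'   index?
#' @return Numeric matrix, samples x markers; missing samples are `NA`.
#' @export
trial_height <- function(trial, chain_only = FALSE) {
  h <- trial[[trial$height_axis]]
  h[trial$missing] <- NA_real_
  if (chain_only) {
    ord <- order(trial$chain_index, na.last = NA)
    h <- h[, ord, drop = FALSE]
  }
  h
}

# physical chain columns in wave traversal order for this trial's direction
traversal_order <- function(trial) {
  chain_cols <- order(trial$chain_index, na.last = NA)
  if (trial$direction == "left-to-right") chain_cols else rev(chain_cols)
}

#' @export
print.wave_trial <- function(x, ...) {
  cat(sprintf(
    "<wave_trial> %s block %d trial %d (%s focus, %s)\n",
    x$participant_id, x$block, x$trial_index, x$focus, x$direction
  ))
  cat(sprintf(
    "  %d markers x %d samples at %.5g Hz (%.3g s); %d missing samples\n",
    length(x$marker_id), length(x$t), x$sampling_rate,
    diff(range(x$t)), sum(x$missing)
  ))
  invisible(x)
}

#' Quick diagnostic plot of a trial's vertical trajectories
#'
#' Stacks the eight chain markers' height traces (traversal order, bottom to
#' top) the way wave recordings are conventionally displayed.
#'
#' @param x A `wave_trial`.
#' @param offset Vertical stacking offset in mm between traces.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.wave_trial <- function(x, offset = 60, ...) {
  h <- trial_height(x)[, traversal_order(x), drop = FALSE]
  h <- sweep(h, 2, apply(h, 2, median, na.rm = TRUE))
  h <- sweep(h, 2, offset * (seq_len(ncol(h)) - 1), "+")
  graphics::matplot(
    x$t, h, type = "l", lty = 1, xlab = "time (s)",
    ylab = "height (mm, stacked)", ...
  )
  invisible(x)
}
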