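#' @title Cohort-level statistics
#' @description Aggregates trial metrics per participant and condition and
#'   provides the cohort statistical machinery: participant ranking on the
#'   wave-amplitude dimension, Pearson and Spearman correlation matrices over
#'   the seven quality metrics, a repeated-measures one-way ANOVA for the
#'   attentional-focus factor with eta squared, and quadrant reports for
#'   metric-pair scatters.
#' @name cohort_stats
NULL

# valid = not excluded, successfully segmented, and peaks in chain order
# (out-of-order trials keep their flagged metrics row but stay out of means)
metric_is_valid <- function(metrics) {
  !metrics$excluded & !is.na(metrics$wave_amplitude) &
    !is.na(metrics$valid_order) & metrics$valid_order
}

#' Summarize trial metrics per participant
#'
#' Means are computed over non-excluded, successfully segmented trials only;
#' non-finite ratio sentinels are dropped from the ratio mean. Participants
#' with zero valid trials are reported with missing summaries, not silently
#' dropped. `amplitude_rank` ranks overall mean wave amplitude, 1 = largest,
#' ties broken by participant id.
#'
#' @param metrics Metrics tibble from [analyze_cohort()].
#' @param by_focus Also compute per-focus means (columns suffixed
#'   `_internal` / `_external`)?
#' @return One row per participant.
#' @export
summarize_participants <- function(metrics, by_focus = TRUE) {
  vars <- c(wave_metric_variables(), "mean_sub_duration",
            "shoulder_interval_pct")
  valid <- metrics[metric_is_valid(metrics), ]
  all_ids <- sort(unique(metrics$participant_id))

  mean_clean <- function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }
  summarize_chunk <- function(chunk, suffix = "") {
    out <- lapply(vars, function(v) mean_clean(chunk[[v]]))
    names(out) <- paste0(vars, suffix)
    tibble::as_tibble(out)
  }

  rows <- lapply(all_ids, function(id) {
    chunk <- valid[valid$participant_id == id, ]
    row <- tibble::tibble(
      participant_id = id,
      n_valid_trials = nrow(chunk),
      n_excluded_trials = sum(
        metrics$participant_id == id & metrics$excluded, na.rm = TRUE
      )
    )
    row <- dplyr::bind_cols(row, summarize_chunk(chunk))
    if (by_focus) {
      for (f in .focus_levels) {
        row <- dplyr::bind_cols(
          row, summarize_chunk(chunk[chunk$focus == f, ], paste0("_", f))
        )
      }
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  ord <- order(-out$wave_amplitude, out$participant_id, na.last = TRUE)
  out$amplitude_rank <- integer(nrow(out))
  out$amplitude_rank[ord] <- seq_len(nrow(out))
  out
}

# r and two-sided p (t transform) for one pair, NA-safe.
cor_cell <- function(x, y, method) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) return(c(r = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(c(r = NA_real_, p = NA_real_, n = n))
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y) # average ranks for ties
  }
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  c(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Correlation matrix over the cohort quality metrics
#'
#' Pairwise product-moment correlations (or rank-order correlations after
#' rank transformation with average ranks for ties) across participants on
#' per-participant means, with two-sided p values from the t transform.
#' Zero-variance variables yield flagged undefined cells rather than errors.
#'
#' @param summaries Participant summaries from [summarize_participants()]
#'   (or any data frame holding the variables).
#' @param variables Columns to correlate; defaults to the seven canonical
#'   quality metrics.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `wave_cormat`: list with matrices `r`, `p`, `n`.
#' @export
correlation_matrix <- function(summaries,
                               variables = wave_metric_variables(),
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  absent <- setdiff(variables, names(summaries))
  if (length(absent)) {
    stop("variables not present: ", paste(absent, collapse = ", "))
  }
  k <- length(variables)
  r <- p <- nm <- matrix(
    NA_real_, k, k, dimnames = list(variables, variables)
  )
  for (i in seq_len(k)) {
    r[i, i] <- 1
    nm[i, i] <- sum(is.finite(summaries[[variables[i]]]))
    for (j in seq_len(k)[-seq_len(i)]) {
      cell <- cor_cell(summaries[[variables[i]]], summaries[[variables[j]]],
                       method)
      r[i, j] <- r[j, i] <- cell["r"]
      p[i, j] <- p[j, i] <- cell["p"]
      nm[i, j] <- nm[j, i] <- cell["n"]
    }
  }
  structure(
    list(r = r, p = p, n = nm, method = method, variables = variables),
    class = "wave_cormat"
  )
}

#' @rdname correlation_matrix
#' @export
pearson_matrix <- function(summaries, variables = wave_metric_variables()) {
  correlation_matrix(summaries, variables, "pearson")
}

#' @rdname correlation_matrix
#' @export
spearman_matrix <- function(summaries, variables = wave_metric_variables()) {
  correlation_matrix(summaries, variables, "spearman")
}

#' @export
print.wave_cormat <- function(x, digits = 3, ...) {
  cat(sprintf("<wave_cormat> %s, n = %s\n", x$method,
              paste(range(x$n, na.rm = TRUE), collapse = "-")))
  print(round(x$r, digits))
  invisible(x)
}

#' One-way ANOVA for the attentional-focus factor
#'
#' Collapses trials to per-participant condition means and, by default, runs
#' the repeated-measures (within-participant) one-way ANOVA: the focus effect
#' is tested against the focus-by-participant interaction, giving df
#' `(k - 1, (k - 1)(n - 1))` -- `(1, 11)` for 12 participants and two focus
#' conditions. Eta squared is `SS_focus / (SS_focus + SS_error)`, the
#' variance share of the focus effect once stable participant differences
#' are removed. `type = "between"` instead treats the condition means as
#' independent groups.
#'
#' @param metrics Metrics tibble from [analyze_cohort()].
#' @param metric Which metric to test.
#' @param type `"within"` (repeated measures, default) or `"between"`.
#' @return A `wave_anova`: list with `F`, `df1`, `df2`, `p`, `eta_squared`,
#'   the condition means, and the sums of squares.
#' @export
focus_anova <- function(metrics, metric = "wave_amplitude",
                        type = c("within", "between")) {
  type <- match.arg(type)
  valid <- metrics[metric_is_valid(metrics) & is.finite(metrics[[metric]]), ]
  cells <- aggregate(
    valid[[metric]],
    by = list(participant_id = valid$participant_id, focus = valid$focus),
    FUN = mean
  )
  names(cells)[3L] <- "y"
  lvls <- unique(cells$focus)
  if (length(lvls) < 2L) {
    stop("focus factor needs two levels with data; found ",
         length(lvls))
  }
  if (min(table(cells$focus)) < 2L) {
    stop("each focus level needs at least two participant-level observations")
  }
  group_means <- tapply(cells$y, cells$focus, mean)
  if (type == "within") {
    # complete pairs only
    wide <- stats::reshape(
      cells, idvar = "participant_id", timevar = "focus", direction = "wide"
    )
    wide <- wide[stats::complete.cases(wide), ]
    n <- nrow(wide)
    if (n < 2L) stop("need at least two participants with both conditions")
    ymat <- as.matrix(wide[, -1L, drop = FALSE])
    k <- ncol(ymat)
    grand <- mean(ymat)
    ss_focus <- n * sum((colMeans(ymat) - grand)^2)
    ss_subject <- k * sum((rowMeans(ymat) - grand)^2)
    ss_total <- sum((ymat - grand)^2)
    ss_error <- ss_total - ss_focus - ss_subject
    df1 <- k - 1L
    df2 <- (k - 1L) * (n - 1L)
  } else {
    y <- cells$y
    grand <- mean(y)
    ss_focus <- sum(tapply(y, cells$focus, function(v) {
      length(v) * (mean(v) - grand)^2
    }))
    ss_error <- sum((y - tapply(y, cells$focus, mean)[cells$focus])^2)
    df1 <- length(lvls) - 1L
    df2 <- length(y) - length(lvls)
  }
  if (ss_focus == 0) {
    # no effect at all: define F = 0, eta^2 = 0 even when the error stratum
    # is also empty (identical condition means everywhere)
    fstat <- 0
    eta2 <- 0
  } else {
    fstat <- (ss_focus / df1) / (ss_error / df2)
    eta2 <- ss_focus / (ss_focus + ss_error)
  }
  structure(
    list(
      F = fstat, df1 = df1, df2 = df2,
      p = pf(fstat, df1, df2, lower.tail = FALSE),
      eta_squared = eta2,
      ss_focus = ss_focus, ss_error = ss_error,
      group_means = group_means, metric = metric, type = type
    ),
    class = "wave_anova"
  )
}

#' @export
print.wave_anova <- function(x, ...) {
  cat(sprintf(
    "<wave_anova> %s (%s): F(%d, %d) = %.3g, p = %.3g, eta^2 = %.3g\n",
    x$metric, x$type, x$df1, x$df2, x$F, x$p, x$eta_squared
  ))
  means <- paste(sprintf("%s %.4g", names(x$group_means), x$group_means),
                 collapse = ", ")
  cat("  condition means:", means, "\n")
  invisible(x)
}

#' Quadrant report for a metric-pair scatter
#'
#' Labels each participant by quadrant relative to the cohort medians of two
#' metrics and fits the least-squares regression line, the usual reading of
#' participant scatter plots (top-right of amplitude vs differentiation =
#' well-articulated wave, and so on).
#'
#' @param summaries Participant summaries.
#' @param x_metric,y_metric Metric column names.
#' @return A list with the labeled per-participant table (`table`), the
#'   medians, and the regression `intercept`/`slope`.
#' @export
quadrant_report <- function(summaries, x_metric, y_metric) {
  x <- summaries[[x_metric]]
  y <- summaries[[y_metric]]
  if (is.null(x) || is.null(y)) stop("metric columns not found")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need at least three participants with both metrics")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    stop("degenerate (constant) metric: ",
         if (sd(x[ok]) == 0) x_metric else y_metric)
  }
  mx <- median(x[ok]); my <- median(y[ok])
  quadrant <- ifelse(
    y >= my,
    ifelse(x >= mx, "top-right", "top-left"),
    ifelse(x >= mx, "bottom-right", "bottom-left")
  )
  quadrant[!ok] <- NA_character_
  fit <- stats::lm.fit(cbind(1, x[ok]), y[ok])
  list(
    table = tibble::tibble(
      participant_id = summaries$participant_id,
      x = x, y = y, quadrant = quadrant
    ),
    x_metric = x_metric, y_metric = y_metric,
    x_median = mx, y_median = my,
    intercept = unname(fit$coefficients[1L]),
    slope = unname(fit$coefficients[2L])
  )
}
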