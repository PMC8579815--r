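# Hand-built metrics tables keep these tests independent of the generator.
fake_metrics_row <- function(id, focus, trial_index, amp,
                             cov = 10, excluded = FALSE, valid = TRUE) {
  tibble::tibble(
    participant_id = id, block = 1L, focus = focus,
    direction = "left-to-right", trial_index = trial_index,
    wave_amplitude = amp, wrist_minus_shoulder = amp / 3,
    residual_amplitude = amp / 10, residual_mode = "secondary-peak",
    wave_residual_ratio = 10, ratio_flagged = FALSE,
    wave_duration = 1.9, mean_sub_duration = 1.9 / 7,
    cov_propagation = cov, shoulder_interval = 0.27,
    shoulder_interval_pct = 100 / 7, valid_order = valid,
    excluded = excluded, note = NA_character_
  )
}

test_that("a participant with identical trials summarizes to the trial metrics", {
  met <- dplyr::bind_rows(lapply(1:4, function(i) {
    fake_metrics_row("P01", if (i %% 2) "internal" else "external", i, 100)
  }))
  s <- summarize_participants(met)
  expect_identical(nrow(s), 1L)
  expect_identical(s$n_valid_trials, 4L)
  expect_equal(s$wave_amplitude, 100)
  expect_equal(s$cov_propagation, 10)
  expect_equal(s$wave_amplitude_internal, 100)
  expect_equal(s$wave_amplitude_external, 100)
})

test_that("amplitude ranking orders participants large to small", {
  met <- dplyr::bind_rows(
    fake_metrics_row("A", "internal", 1, 50),
    fake_metrics_row("B", "internal", 1, 100),
    fake_metrics_row("C", "internal", 1, 75)
  )
  s <- summarize_participants(met, by_focus = FALSE)
  expect_identical(s$amplitude_rank[match(c("A", "B", "C"), s$participant_id)],
                   c(3L, 1L, 2L))
})

test_that("excluded and flagged trials stay out of the means; empty participants are reported", {
  met <- dplyr::bind_rows(
    fake_metrics_row("P01", "internal", 1, 100),
    fake_metrics_row("P01", "internal", 2, 999, excluded = TRUE),
    fake_metrics_row("P01", "internal", 3, 999, valid = FALSE),
    fake_metrics_row("P02", "internal", 1, 80, excluded = TRUE)
  )
  s <- summarize_participants(met, by_focus = FALSE)
  expect_equal(s$wave_amplitude[s$participant_id == "P01"], 100)
  expect_identical(s$n_valid_trials[s$participant_id == "P02"], 0L)
  expect_true(is.na(s$wave_amplitude[s$participant_id == "P02"]))
  expect_identical(sort(s$amplitude_rank), 1:2)
})

test_that("pearson matrix matches the direct formula on a hand-built table", {
  df <- tibble::tibble(a = c(1, 2, 4, 7), b = c(3, 1, 5, 9))
  cm <- correlation_matrix(df, c("a", "b"))
  orc <- oracle_pearson(df$a, df$b)
  expect_equal(cm$r["a", "b"], orc$r, tolerance = 1e-12)
  expect_equal(cm$p["a", "b"], orc$p, tolerance = 1e-12)
  expect_identical(cm$n["a", "b"], 4)
  expect_identical(diag(cm$r), c(a = 1, b = 1))

  # exact linear dependence
  df2 <- tibble::tibble(x = 1:5 * 1.0, y = 2 * (1:5))
  expect_equal(correlation_matrix(df2, c("x", "y"))$r["x", "y"], 1)

  # zero variance flagged, not an error
  df3 <- tibble::tibble(x = c(1, 1, 1, 1), y = c(1, 2, 3, 4))
  expect_true(is.na(correlation_matrix(df3, c("x", "y"))$r["x", "y"]))
})

test_that("spearman matrix is a rank transform with average ranks for ties", {
  df <- tibble::tibble(x = c(1, 2, 2, 5, 7), y = c(2, 4, 4, 4, 11))
  cm <- spearman_matrix(df, c("x", "y"))
  expect_equal(cm$r["x", "y"], oracle_spearman(df$x, df$y), tolerance = 1e-12)

  # invariant under strictly increasing maps; reversal gives -1
  df2 <- tibble::tibble(x = c(0.3, 1.2, 2.9, 4.4), y = exp(c(0.3, 1.2, 2.9, 4.4)))
  expect_equal(spearman_matrix(df2, c("x", "y"))$r["x", "y"], 1)
  df3 <- tibble::tibble(x = 1:6 * 1.0, y = rev(1:6) * 1.0)
  expect_equal(spearman_matrix(df3, c("x", "y"))$r["x", "y"], -1)
})

test_that("pearson is invariant under positive affine maps", {
  set.seed(1)
  x <- rnorm(10); y <- rnorm(10)
  df <- tibble::tibble(x = x, y = y)
  df2 <- tibble::tibble(x = 3 * x + 7, y = 0.2 * y - 4)
  expect_equal(correlation_matrix(df, c("x", "y"))$r["x", "y"],
               correlation_matrix(df2, c("x", "y"))$r["x", "y"],
               tolerance = 1e-12)
})

test_that("focus ANOVA matches direct sums of squares and aov", {
  # 3 participants x 2 conditions, hand-built
  met <- dplyr::bind_rows(
    fake_metrics_row("P01", "internal", 1, 100),
    fake_metrics_row("P01", "external", 2, 110),
    fake_metrics_row("P02", "internal", 3, 90),
    fake_metrics_row("P02", "external", 4, 105),
    fake_metrics_row("P03", "internal", 5, 120),
    fake_metrics_row("P03", "external", 6, 118)
  )
  a <- focus_anova(met)
  # direct evaluation: paired design, focus vs focus-by-participant error
  y <- matrix(c(110, 100, 105, 90, 118, 120), 3, 2, byrow = TRUE)
  grand <- mean(y)
  ssf <- 3 * sum((colMeans(y) - grand)^2)
  sss <- 2 * sum((rowMeans(y) - grand)^2)
  sse <- sum((y - grand)^2) - ssf - sss
  expect_equal(a$F, (ssf / 1) / (sse / 2), tolerance = 1e-12)
  expect_equal(a$eta_squared, ssf / (ssf + sse), tolerance = 1e-12)
  expect_identical(c(a$df1, a$df2), c(1L, 2L))
  # repeated-measures F equals the squared paired t statistic
  tt <- stats::t.test(y[, 1], y[, 2], paired = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  # and the aov Error-stratum fit agrees
  cells <- data.frame(
    y = as.vector(t(y)),
    focus = rep(c("external", "internal"), 3),
    id = rep(c("P01", "P02", "P03"), each = 2)
  )
  fit <- summary(stats::aov(y ~ focus + Error(id), data = cells))
  ftab <- fit[["Error: Within"]][[1]]
  expect_equal(a$F, ftab["focus", "F value"], tolerance = 1e-9)

  # between-participant variant: one-way ANOVA on the 6 condition means
  ab <- focus_anova(met, type = "between")
  gm <- tapply(cells$y, cells$focus, mean)
  ssb <- sum(3 * (gm - mean(cells$y))^2)
  ssw <- sum((cells$y - gm[cells$focus])^2)
  expect_equal(ab$F, (ssb / 1) / (ssw / 4), tolerance = 1e-12)
  expect_identical(c(ab$df1, ab$df2), c(1L, 4L))
})

test_that("identical condition means give F = 0 and eta^2 = 0", {
  met <- dplyr::bind_rows(
    fake_metrics_row("P01", "internal", 1, 90),
    fake_metrics_row("P01", "external", 2, 90),
    fake_metrics_row("P02", "internal", 3, 130),
    fake_metrics_row("P02", "external", 4, 130)
  )
  a <- focus_anova(met)
  expect_equal(a$F, 0)
  expect_equal(a$eta_squared, 0)
})

test_that("single-level focus input errors; eta^2 stays in [0, 1]", {
  met <- dplyr::bind_rows(
    fake_metrics_row("P01", "internal", 1, 90),
    fake_metrics_row("P02", "internal", 2, 95)
  )
  expect_error(focus_anova(met), "two levels")
  set.seed(2)
  for (i in 1:10) {
    met2 <- dplyr::bind_rows(lapply(1:6, function(p) {
      dplyr::bind_rows(
        fake_metrics_row(sprintf("P%02d", p), "internal", 2 * p - 1, rnorm(1, 100, 20)),
        fake_metrics_row(sprintf("P%02d", p), "external", 2 * p, rnorm(1, 100, 20))
      )
    }))
    a <- focus_anova(met2)
    expect_gte(a$eta_squared, 0)
    expect_lte(a$eta_squared, 1)
  }
})

test_that("quadrant labels split on the cohort medians", {
  s <- tibble::tibble(
    participant_id = c("a", "b", "c", "d"),
    wave_amplitude = c(1, -1, -1, 1),
    cov_propagation = c(1, 1, -1, -1)
  )
  q <- quadrant_report(s, "wave_amplitude", "cov_propagation")
  expect_identical(q$table$quadrant,
                   c("top-right", "top-left", "bottom-left", "bottom-right"))

  s2 <- tibble::tibble(
    participant_id = sprintf("p%d", 1:6),
    x = c(1, 2, 3, 4, 5, 6),
    y = c(-2.1, -3.9, -6.2, -7.8, -10.1, -11.9)
  )
  q2 <- quadrant_report(s2, "x", "y")
  expect_lt(q2$slope, 0)
  expect_equal(q2$slope, -2, tolerance = 0.05)

  s3 <- tibble::tibble(participant_id = c("a", "b", "c"),
                       x = c(1, 1, 1), y = c(1, 2, 3))
  expect_error(quadrant_report(s3, "x", "y"), "degenerate")
})
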