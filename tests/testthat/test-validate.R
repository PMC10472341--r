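test_that("ICC equals the one-way ANOVA oracle and hits its boundary cases", {
  set.seed(101)
  # identical methods with between-area variation: perfect concordance
  x <- runif(12, 0.1, 0.6)
  r <- icc(x, x)
  expect_equal(r$icc, 1)
  expect_equal(r$WMS, 0)

  # constant area means with within-pair disagreement: negative ICC
  x2 <- rep(0.4, 10) + 0.05
  y2 <- rep(0.4, 10) - 0.05
  expect_lt(icc(x2, y2)$icc, 0)

  # random tables match the independent aov-based computation exactly
  for (i in 1:20) {
    D <- sample(5:30, 1)
    a <- runif(D, 0.05, 0.9)
    b <- pmin(0.99, pmax(0.01, a + rnorm(D, 0, 0.05)))
    expect_equal(icc(a, b)$icc, icc_oracle_aov(a, b), tolerance = 1e-12)
  }

  expect_error(icc(runif(2), runif(2)), "at least 3")
  expect_error(icc(c(0.2, 0.3, 1.4), c(0.2, 0.3, 0.4)), "0, 1")
})

test_that("ICC is invariant under a common affine rescaling of both methods", {
  set.seed(11)
  a <- runif(15, 0.2, 0.8)
  b <- pmin(0.95, pmax(0.05, a + rnorm(15, 0, 0.04)))
  base <- icc(a, b)$icc
  shifted <- icc(0.05 + 0.5 * a, 0.05 + 0.5 * b)$icc
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("ICC confidence interval brackets the estimate and matches the textbook formula", {
  set.seed(202)
  for (i in 1:10) {
    D <- sample(5:20, 1)
    a <- runif(D, 0.1, 0.9)
    b <- pmin(0.99, pmax(0.01, a + rnorm(D, 0, 0.06)))
    r <- icc_ci(icc(a, b))
    expect_lte(r$ci_lower, r$icc)
    expect_lte(r$icc, r$ci_upper)
  }

  # worked 5-area table against an independent re-derivation: mean squares
  # from aov(), then the exact one-way interval written out longhand
  a <- c(0.12, 0.25, 0.31, 0.48, 0.55)
  b <- c(0.15, 0.22, 0.35, 0.44, 0.60)
  r <- icc_ci(icc(a, b))
  long <- data.frame(v = c(a, b), id = factor(rep(1:5, 2)))
  ms <- summary(stats::aov(v ~ id, data = long))[[1]][["Mean Sq"]]
  Fobs_l <- (ms[1] / ms[2]) / qf(0.975, 4, 5)
  Fobs_u <- (ms[1] / ms[2]) * qf(0.975, 5, 4)
  expect_equal(r$ci_lower, (Fobs_l - 1) / (Fobs_l + 1), tolerance = 1e-10)
  expect_equal(r$ci_upper, (Fobs_u - 1) / (Fobs_u + 1), tolerance = 1e-10)

  # exact agreement degenerates with a flag
  rd <- icc_ci(icc(a, a))
  expect_true(rd$degenerate)
  expect_equal(c(rd$ci_lower, rd$ci_upper), c(-1, 1))
})

test_that("difference CIs follow the Wald construction", {
  d <- difference_ci(0.30, 0.30, 0.02, 0.02)
  expect_equal(d$difference, 0)
  expect_equal(d$ci_lower, -1.96 * sqrt(2) * 0.02, tolerance = 1e-12)
  expect_equal(d$ci_upper, +1.96 * sqrt(2) * 0.02, tolerance = 1e-12)
  expect_true(d$includes_zero)

  d2 <- difference_ci(0.30, 0.35, 0, 0)
  expect_equal(d2$ci_lower, 0.05)
  expect_equal(d2$ci_upper, 0.05)
  expect_false(d2$includes_zero)
})

test_that("zero-inclusion summary conserves counts and truncates the percentage", {
  diffs <- data.frame(
    category = rep(rep(c("S", "ExS", "NS"), each = 10), 2),
    group = rep(c("A", "B"), each = 30),
    includes_zero = c(rep(TRUE, 10),                      # A: S 10/10
                      rep(c(TRUE, FALSE), c(8, 2)),       # A: ExS 8/10
                      rep(c(TRUE, FALSE), c(5, 5)),       # A: NS 5/10
                      rep(c(TRUE, FALSE), c(8, 2)),       # B: S 8/10
                      rep(TRUE, 10),                      # B: ExS 10/10
                      rep(c(TRUE, FALSE), c(8, 2))))      # B: NS 8/10
  zi <- zero_inclusion_summary(diffs)
  expect_equal(zi$n_zero, 49)
  expect_equal(zi$n_total, 60)
  expect_equal(sum(zi$by_category$n_zero), zi$n_zero)
  expect_equal(zi$overall_pct, 81.6)
  expect_equal(zero_inclusion_summary(data.frame(category = "S", includes_zero = TRUE))$overall_pct, 100)
  expect_equal(zero_inclusion_summary(data.frame(category = "S", includes_zero = FALSE))$overall_pct, 0)
})

test_that("CV screening applies the strict 30% rule and logs exclusions", {
  tab <- function(cv, method) {
    data.frame(area_id = seq_along(cv), category = "S", prevalence = 0.3,
               se = 0.01, cv = cv, no_sample = FALSE)
  }
  scr <- cv_screen(tab(c(29.9, 30.0, 10)), tab(c(20, 40, 5)))
  f <- scr$flags
  expect_true(f$acceptable[f$method == "direct" & f$cv == 29.9])
  expect_false(f$acceptable[f$method == "direct" & f$cv == 30.0])

  scr2 <- cv_screen(tab(c(10, 20, 40)), tab(c(10, 20, 40)),
                    exclude = data.frame(method = "direct", area_id = 3, category = "S"))
  s_direct <- scr2$summary[scr2$summary$method == "direct", ]
  expect_equal(s_direct$cv_median, 15)  # outlier removed from summary
  expect_equal(nrow(scr2$excluded), 1)
  s_sae <- scr2$summary[scr2$summary$method == "sae", ]
  expect_equal(s_sae$cv_median, 20)
  expect_equal(c(s_sae$cv_min, s_sae$cv_max), c(10, 40))
  expect_equal(s_sae$n_acceptable, 2)
})

test_that("self-comparison report is perfectly concordant and logs missing cells", {
  cfg <- small_cfg(seed = 43)
  cfg$national_sample_per_area <- c(0, rep(100, 19))
  frame <- generate_area_frame(cfg)
  micro <- generate_survey(frame, cfg, "national")
  de <- direct_estimates(micro, frame)
  fake_sae <- de
  fake_sae$mse <- de$se^2
  class(fake_sae) <- "data.frame"
  rep_ <- concordance_report(de, fake_sae)
  for (k in c("S", "ExS", "NS")) expect_equal(rep_$icc[[k]]$icc, 1)
  expect_true(all(rep_$differences$difference == 0))
  expect_true(all(rep_$differences$includes_zero))
  expect_equal(rep_$zero_inclusion$overall_pct, 100)
  # the zero-sample area was excluded pairwise and logged
  expect_true(all(rep_$excluded$area_id == 1))
  expect_equal(nrow(rep_$excluded), 3)
  expect_true(rep_$all_icc_acceptable)
})
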