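test_that("aggregation counts statuses per area and conserves totals", {
  cfg <- small_cfg(seed = 9)
  frame <- generate_area_frame(cfg)
  m <- one_area_micro(c("S", "S", "ExS", "NS"))
  cnt <- aggregate_to_areas(m, frame)
  expect_equal(cnt$y[1, ], c(S = 2L, ExS = 1L, NS = 1L))
  expect_equal(cnt$n[1], 4L)
  expect_true(all(cnt$n[-1] == 0))

  micro <- generate_survey(frame, cfg, "national")
  cnt2 <- aggregate_to_areas(micro, frame)
  expect_equal(sum(cnt2$n), nrow(micro))

  bad <- one_area_micro("S", area_id = 999L)
  expect_error(aggregate_to_areas(bad, frame), "unknown area_id")
})

test_that("with phi = 0 and intercept-only design the model collapses to the pooled multinomial", {
  skip_if_not_installed("nnet")
  cfg <- sim_config(n_regions = 10, n_covariates = 0,
                    beta1 = -0.9, beta2 = -0.6, phi = c(0, 0),
                    national_sample_per_area = 2000,
                    pop_meanlog = log(5e5), seed = 13)
  frame <- generate_area_frame(cfg)
  micro <- generate_survey(frame, cfg, "national")
  cnt <- aggregate_to_areas(micro, frame)

  # independent fixed-effects multinomial oracle
  Y <- cbind(NS = cnt$y[, "NS"], S = cnt$y[, "S"], ExS = cnt$y[, "ExS"])
  fe <- nnet::multinom(Y ~ 1, trace = FALSE, reltol = 1e-14)
  b <- coef(fe)

  # free fit: variances collapse and the coefficients agree with the oracle
  fit <- fit_sae(cnt, rel_tol = 1e-9)
  expect_lt(max(fit$phi), 1e-2)
  expect_lt(abs(fit$beta1[[1]] - b["S", 1]), 1e-4)
  expect_lt(abs(fit$beta2[[1]] - b["ExS", 1]), 1e-4)

  # degenerate submodel (phi = 0): exactly the pooled multinomial
  fit0 <- fit_sae(cnt, random_effects = FALSE)
  pooled <- colSums(cnt$y) / sum(cnt$n)
  expect_lt(max(abs(fit0$prevalence[, 1] - pooled["S"])), 1e-3)
  expect_lt(max(abs(fit0$prevalence[, 2] - pooled["ExS"])), 1e-3)
  expect_lt(abs(fit0$beta1[[1]] - b["S", 1]), 1e-4)
  expect_lt(abs(fit0$beta2[[1]] - b["ExS", 1]), 1e-4)
  expect_true(all(fit0$u == 0))
})

test_that("relabeling areas permutes random effects and leaves parameters unchanged", {
  cfg <- sim_config(n_regions = 2, n_covariates = 1,
                    beta1 = c(-0.5, 0.4), beta2 = c(-0.8, 0.2),
                    national_sample_per_area = 150, seed = 19)
  frame <- generate_area_frame(cfg)
  micro <- generate_survey(frame, cfg, "national")
  cnt <- aggregate_to_areas(micro, frame)
  fit <- fit_sae(cnt)

  set.seed(1)
  perm <- sample(seq_len(nrow(frame)))
  cnt_p <- cnt
  cnt_p$y <- cnt$y[perm, , drop = FALSE]
  cnt_p$n <- cnt$n[perm]
  cnt_p$X1 <- cnt$X1[perm, , drop = FALSE]
  cnt_p$X2 <- cnt$X2[perm, , drop = FALSE]
  fit_p <- fit_sae(cnt_p)

  expect_equal(unname(fit_p$beta1), unname(fit$beta1), tolerance = 1e-5)
  expect_equal(unname(fit_p$beta2), unname(fit$beta2), tolerance = 1e-5)
  expect_equal(fit_p$phi, fit$phi, tolerance = 1e-5)
  expect_equal(fit_p$u, fit$u[perm, ], tolerance = 1e-5)
})

test_that("fitted prevalences are normalized and the objective path is monitored", {
  cfg <- small_cfg(seed = 23)
  frame <- generate_area_frame(cfg)
  cnt <- aggregate_to_areas(generate_survey(frame, cfg, "national"), frame)
  fit <- fit_sae(cnt)
  expect_equal(rowSums(fit$prevalence), rep(1, nrow(frame)), tolerance = 1e-10)
  expect_true(length(fit$objective_trace) > 1)
  # the best objective seen is the one reported at convergence
  expect_equal(min(fit$objective_trace), fit$convergence$objective,
               tolerance = 1e-8)
})

test_that("synthetic prediction serves zero-sample areas; full equals synthetic when u = 0", {
  cfg <- small_cfg(seed = 29)
  cfg$national_sample_per_area <- c(rep(120, 19), 0)
  frame <- generate_area_frame(cfg)
  micro <- generate_survey(frame, cfg, "national")
  cnt <- aggregate_to_areas(micro, frame)
  fit <- fit_sae(cnt)

  expect_equal(fit$u[20, ], c(0, 0))
  expect_equal(fit$mode[20], "synthetic")
  p_syn <- predict_prevalence(fit, 20, mode = "synthetic")
  p_auto <- predict_prevalence(fit, 20, mode = "auto")
  p_full <- predict_prevalence(fit, 20, mode = "full")
  expect_equal(p_syn, p_auto)
  expect_equal(p_syn, p_full)  # u = 0 for the empty area
  expect_equal(unname(rowSums(predict_prevalence(fit))), rep(1, 20),
               tolerance = 1e-10)
  expect_error(predict_prevalence(fit, 999), "unknown area")

  # a coefficient vector that zeroes both logits predicts uniform shares
  fit0 <- fit
  fit0$beta1[] <- 0
  fit0$beta2[] <- 0
  expect_equal(unname(predict_prevalence(fit0, 20, mode = "synthetic")[1, ]),
               rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("bootstrap MSEs are nonnegative, deterministic in the seed, and stable in B", {
  cfg <- small_cfg(seed = 37)
  frame <- generate_area_frame(cfg)
  cnt <- aggregate_to_areas(generate_survey(frame, cfg, "national"), frame)
  fit <- fit_sae(cnt)
  prec1 <- mse_bootstrap(fit, B = 60, seed = 5)
  prec2 <- mse_bootstrap(fit, B = 60, seed = 5)
  expect_identical(prec1, prec2)
  expect_true(all(prec1$mse >= 0))
  expect_true(all(is.finite(prec1$cv[prec1$prevalence > 0])))

  prec3 <- mse_bootstrap(fit, B = 120, seed = 5)
  # doubling B changes the estimates by no more than Monte-Carlo noise:
  # compare against ~3 bootstrap standard errors of an MSE (chi-square scale)
  rel_tol <- 3 * sqrt(2 / 60)
  ratio <- prec3$mse / prec1$mse
  expect_true(mean(abs(ratio - 1) < 3 * rel_tol) > 0.9)
})
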