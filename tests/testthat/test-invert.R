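test_that("global fit requires a reference-divided set with two traces", {
  set <- simulate_traceset(quick_sim(seed = 1))
  expect_error(global_fit(set), "reference-divided")
  div <- quick_divided(quick_sim(seed = 1))
  one <- trace_set(div$main[1], deconvolved = TRUE, ref_t_mix = div$ref_t_mix)
  expect_error(global_fit(one), "at least 2")
})

test_that("fitted density is non-negative with unit mass", {
  fit <- global_fit(quick_divided(quick_sim(seed = 2)), c_grid = quick_c_grid())
  expect_true(all(fit$density$p >= 0))
  expect_equal(sum(fit$density$p) * fit$density$dc, 1, tolerance = 1e-9)
  expect_true(all(is.finite(fit$residual_norms)))
  expect_gt(fit$lambda_reg, 0)
})

test_that("no-decay traces put the mass at the bottom of the grid", {
  t <- seq(0, 14, by = 0.25)
  ones <- lapply(c(120, 480, 1920), function(tm) trace(t, rep(1, length(t)), tm))
  set <- trace_set(ones, deconvolved = TRUE, ref_t_mix = 60)
  fit <- global_fit(set, c_grid = quick_c_grid(), lambda_reg = 1e-3)
  low <- fit$density$c_grid <= 2.5   # concentrations with no observable decay
  expect_gt(sum(fit$density$p[low]) * fit$density$dc, 0.9)
})

test_that("a noiseless point-like environment is recovered at its concentration", {
  spec <- simulation_spec(gaussian_mixture(7, 0.125, 1), noise_sigma = 0,
                          seed = 1)
  set <- simulate_traceset(spec)   # default fine grids
  div <- reference_deconvolve(set)
  fit <- global_fit(div, lambda_reg = 1e-6)
  near <- abs(fit$density$c_grid - 7) <= 0.5
  expect_gt(sum(fit$density$p[near]) * fit$density$dc, 0.95)
})

test_that("a noiseless three-component truth is recovered as a curve", {
  truth <- density_from_mixture(bbg1_mixture())
  div <- reference_deconvolve(simulate_traceset(
    simulation_spec(bbg1_mixture(), noise_sigma = 0, seed = 1)))
  fit <- global_fit(div, lambda_reg = 1e-2)
  expect_lt(max(abs(fit$density$p - truth$p)), 0.02 * max(truth$p))
})

test_that("lambda selection is deterministic and noise-ordered", {
  div <- quick_divided(quick_sim(seed = 5))
  l1 <- select_lambda(div, c_grid = quick_c_grid())
  l2 <- select_lambda(div, c_grid = quick_c_grid())
  expect_identical(l1, l2)
  # more noise never calls for less smoothing (on average over seeds)
  ratio_log <- vapply(1:4, function(s) {
    lo <- quick_divided(quick_sim(noise_sigma = 0.005, seed = s))
    hi <- quick_divided(quick_sim(noise_sigma = 0.03, seed = s))
    log10(select_lambda(hi, c_grid = quick_c_grid())) -
      log10(select_lambda(lo, c_grid = quick_c_grid()))
  }, numeric(1))
  expect_gte(mean(ratio_log), 0)
  # essentially noiseless data need essentially no smoothing
  nl <- quick_divided(quick_sim(noise_sigma = 0, seed = 1))
  expect_lt(select_lambda(nl, c_grid = quick_c_grid()), 10)
})

test_that("bootstrap envelopes are reproducible and noise-responsive", {
  div <- quick_divided(quick_sim(seed = 6))
  fit <- global_fit(div, c_grid = quick_c_grid())
  expect_error(uncertainty_band(div, fit, n_boot = 5), "at least 10")
  b1 <- uncertainty_band(div, fit, n_boot = 12, seed = 7)
  b2 <- uncertainty_band(div, fit, n_boot = 12, seed = 7)
  expect_identical(b1$uncertainty_band, b2$uncertainty_band)
  expect_true(all(b1$uncertainty_band$upper >= b1$uncertainty_band$lower))
  # noiseless data: envelopes collapse onto the point estimate
  nl <- quick_divided(quick_sim(noise_sigma = 0, seed = 1))
  fit_nl <- global_fit(nl, c_grid = quick_c_grid(), lambda_reg = 1e-4)
  b_nl <- uncertainty_band(nl, fit_nl, n_boot = 12, seed = 1)
  expect_lt(max(b_nl$uncertainty_band$upper - b_nl$uncertainty_band$lower),
            1e-2 * max(fit_nl$density$p))
  # envelope volume grows with injected noise (paired seeds)
  wid <- function(ns, s) {
    d <- quick_divided(quick_sim(noise_sigma = ns, seed = s))
    f <- global_fit(d, c_grid = quick_c_grid())
    b <- uncertainty_band(d, f, n_boot = 12, seed = 1)$uncertainty_band
    mean(b$upper - b$lower)
  }
  dw <- vapply(1:3, function(s) wid(0.03, s) - wid(0.005, s), numeric(1))
  expect_gt(mean(dw), 0)
})

test_that("the mixing-time ladder lifts the p-k3 degeneracy", {
  div5 <- quick_divided(quick_sim(seed = 11))
  div1 <- quick_divided(quick_sim(seed = 11, t_mix_list = 1920))
  d5 <- degeneracy_diagnostic(div5, c_grid = quick_c_grid())
  d1 <- degeneracy_diagnostic(div1, c_grid = quick_c_grid())
  expect_gt(d5$score, d1$score)
  expect_length(d5$objective, 11L)
  # near-duplicated mixing times carry no more k3 information than one trace
  tm_dup <- 1920 + 0.01 * (0:4)
  div_dup <- quick_divided(quick_sim(seed = 11, t_mix_list = tm_dup))
  d_dup <- degeneracy_diagnostic(div_dup, c_grid = quick_c_grid())
  expect_lt(d_dup$score, d5$score)
})

test_that("the rate normalization is recoverable from a full set", {
  div <- quick_divided(quick_sim(noise_sigma = 0.002, seed = 13))
  fit <- global_fit(div, c_grid = quick_c_grid(), fit_k3 = TRUE)
  expect_false(is.null(fit$k3_fitted))
  expect_equal(fit$k3_fitted, kernel_constants()$k3, tolerance = 0.15)
})
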