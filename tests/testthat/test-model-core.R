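kc <- kernel_constants()

test_that("sigma is linear in concentration with the calibrated slope", {
  expect_identical(sigma_from_concentration(0, kc), 0)
  expect_equal(sigma_from_concentration(14, kc), 0.2996, tolerance = 1e-12)
  expect_equal(sigma_from_concentration(7, kc), 0.1498, tolerance = 1e-12)
  expect_equal(sigma_from_concentration(c(1, 2), kc), c(0.0214, 0.0428))
  expect_error(sigma_from_concentration(-1, kc), "non-negative")
})

test_that("homogeneous Gaussian decay matches its closed form", {
  expect_identical(homogeneous_decay(0, 123, kc), 1)
  expect_equal(homogeneous_decay(8.4, 7, kc),
               exp(-4 * 7.23e-5 * 49 * 8.4^2), tolerance = 1e-12)
  # 8.4 us at 7 M is the 1/e point of the calibration
  expect_equal(homogeneous_decay(8.4, 7, kc), exp(-1), tolerance = 5e-4)
  expect_equal(homogeneous_decay(5, 10, kc), exp(-0.723), tolerance = 1e-12)
  expect_error(homogeneous_decay(-1, 7, kc), "non-negative")
})

test_that("LSD decay has exact no-evolution limits", {
  expect_identical(lsd_decay(0, 1920, 14, kc), 1)
  expect_identical(lsd_decay(5, 0, 14, kc), 1)
  expect_identical(lsd_decay(5, 1920, 0, kc), 1)
  # t_mix = Inf must equal the homogeneous factor without NaN traps
  expect_equal(lsd_decay(c(0, 3, 8), Inf, 7, kc),
               homogeneous_decay(c(0, 3, 8), 7, kc), tolerance = 1e-15)
})

test_that("LSD decay at half saturation matches the hand-built expression", {
  # choose T_mix so that k3 sigma^3 tau^2 T_mix = log 2, i.e. f = 1/2
  tau <- 6; c_h <- 9
  sg <- kc$gamma_sigma * c_h
  t_mix <- log(2) / (kc$k3 * sg^3 * tau^2)
  expect_equal(lsd_decay(tau, t_mix, c_h, kc),
               exp(-0.5 * 4 * kc$beta * c_h^2 * tau^2), tolerance = 1e-12)
})

test_that("LSD decay converges to the homogeneous limit once saturated", {
  set.seed(11)
  for (i in 1:200) {
    c_h <- runif(1, 2, 30)
    tau <- runif(1, 0.5, 14)
    sg <- kc$gamma_sigma * c_h
    # saturation argument just above 25
    t_mix <- 26 / (kc$k3 * sg^3 * tau^2)
    expect_lt(abs(lsd_decay(tau, t_mix, c_h, kc) -
                    homogeneous_decay(tau, c_h, kc)), 1e-9)
  }
})

test_that("LSD decay is monotonically non-increasing in tau, T_mix and C_H", {
  set.seed(7)
  for (i in 1:100) {
    c_h <- runif(1, 0.5, 35)
    t_mix <- runif(1, 10, 3000)
    tau <- sort(runif(20, 0, 14))
    expect_true(all(diff(lsd_decay(tau, t_mix, c_h, kc)) <= 1e-15))
    tm <- sort(runif(20, 0, 3000))
    v_tm <- vapply(tm, function(T) lsd_decay(5, T, c_h, kc), numeric(1))
    expect_true(all(diff(v_tm) <= 1e-15))
    cs <- sort(runif(20, 0, 35))
    v_c <- vapply(cs, function(ch) lsd_decay(5, t_mix, ch, kc), numeric(1))
    expect_true(all(diff(v_c) <= 1e-15))
  }
})

test_that("kernel matrix layout and bounds are correct", {
  t_grid <- seq(0, 10, by = 0.5)
  t_mix <- c(120, 1920)
  c_grid <- c(0, 5, 10, 20)
  K <- kernel_matrix(t_grid, t_mix, c_grid, kc)
  expect_equal(dim(K), c(2 * length(t_grid), 4))
  # no protons, no decay
  expect_true(all(K[, 1] == 1))
  expect_true(all(K > 0 & K <= 1))
  # row block order is trace-major
  expect_equal(K[seq_along(t_grid), 3], lsd_decay(t_grid, 120, 10, kc))
  expect_equal(K[length(t_grid) + seq_along(t_grid), 3],
               lsd_decay(t_grid, 1920, 10, kc))
  # degenerate single-trace single-cell shape
  K1 <- kernel_matrix(t_grid, 960, 7, kc)
  expect_equal(drop(K1), lsd_decay(t_grid, 960, 7, kc))
  # columns non-increasing along each trace's time axis
  set.seed(3)
  Kr <- kernel_matrix(sort(runif(15, 0, 14)), c(60, 480), runif(5, 1, 30), kc)
  for (k in 1:5) {
    expect_true(all(diff(Kr[1:15, k]) <= 1e-15))
    expect_true(all(diff(Kr[16:30, k]) <= 1e-15))
  }
  # larger concentrations decay at least as fast everywhere
  cs <- sort(runif(4, 1, 30))
  Kc <- kernel_matrix(seq(0, 14, 0.5), c(240, 1920), cs, kc)
  for (k in 1:3) expect_true(all(Kc[, k + 1] <= Kc[, k] + 1e-15))
  expect_error(kernel_matrix(numeric(0), 100, 5, kc), "non-empty")
})

test_that("1/e times reproduce the canonical window boundaries", {
  expect_equal(one_over_e_time(14), 4.2, tolerance = 0.05 / 4.2)
  expect_equal(one_over_e_time(7), 8.4, tolerance = 0.05 / 8.4)
  expect_equal(one_over_e_time(4.6), 12.8, tolerance = 0.05 / 12.8)
  # closed form in the levelled-grid limit
  expect_equal(one_over_e_time(14), 1 / (2 * sqrt(kc$beta) * 14),
               tolerance = 1e-12)
  expect_error(one_over_e_time(0), "positive")
  expect_error(one_over_e_time(7, t_mix = 0), "t_mix = 0")
})

test_that("bisection at near-saturating mixing time agrees with the closed form", {
  for (c_h in c(4.6, 7, 14, 25)) {
    sg <- kernel_constants()$gamma_sigma * c_h
    tau_inf <- 1 / (2 * sqrt(kc$beta) * c_h)
    t_big <- 50 / (kc$k3 * sg^3 * tau_inf^2)   # deep saturation at the 1/e point
    expect_equal(one_over_e_time(c_h, t_mix = t_big), tau_inf,
                 tolerance = 1e-3 / tau_inf)
  }
  # finite mixing time can only delay the 1/e crossing
  expect_gt(one_over_e_time(7, t_mix = 1920), one_over_e_time(7))
})

test_that("sensitivity windows partition the time axis as published", {
  b <- sensitivity_windows(c(14, 7, 4.6))
  expect_equal(b, c(4.2, 8.4, 12.8), tolerance = 0.05 / 4.2)
  expect_true(all(diff(b) > 0))
  expect_length(sensitivity_windows(10), 1L)
  # closed-form scaling: doubled thresholds halve the boundaries
  expect_equal(sensitivity_windows(2 * c(14, 7, 4.6)), b / 2,
               tolerance = 1e-12)
  expect_error(sensitivity_windows(c(7, 14)), "decreasing")
  expect_error(sensitivity_windows(c(-1)), "positive")
})

test_that("kernel constants are validated and configurable", {
  expect_error(kernel_constants(beta = -1), "positive")
  expect_error(kernel_constants(gamma_sigma = 0), "positive")
  cfg <- tempfile(fileext = ".yml")
  writeLines(c("beta: 7.0e-5", "k3: 0.02"), cfg)
  kc2 <- constants_from_config(cfg)
  expect_equal(kc2$beta, 7e-5)
  expect_equal(kc2$k3, 0.02)
  expect_equal(kc2$gamma_sigma, 0.0214)
  writeLines("betta: 1", cfg)
  expect_error(constants_from_config(cfg), "unknown config keys")
})
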