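test_that("pulse feet delimit the first completed cycle", {
  fs <- 500
  pulse <- cyclepw:::central_pulse(70, 40, 200)
  w <- detect_first_pulse(tile_pulse(pulse, 200, 650), fs)
  expect_equal(w$end - w$start, 200)
  expect_equal(w$start, 1L)
  # exactly two cycles: the window is the first one
  w2 <- detect_first_pulse(rep(pulse, 2), fs)
  expect_equal(c(w2$start, w2$end), c(1L, 201L))
  expect_error(detect_first_pulse(rep(1, 100), fs), "constant")
  expect_error(detect_first_pulse(c(1, 2), fs), "too short")
  # a single cycle ending at its foot is closed at the boundary
  w3 <- detect_first_pulse(pulse, fs)
  expect_equal(c(w3$start, w3$end), c(1L, 201L))
})

test_that("diameter from circular lumen area", {
  expect_equal(area_to_diameter(pi), 2)
  expect_equal(area_to_diameter(pi / 4), 1)
  a <- sort(runif(10, 0.5, 4))
  expect_true(all(diff(area_to_diameter(a)) > 0))
  expect_error(area_to_diameter(c(1, -1)), "positive")
})

test_that("strain uses the diastolic diameter as reference", {
  d <- c(2.0, 2.2, 2.1)
  area <- pi * d^2 / 4
  expect_equal(strain_from_area(area), c(0, 10, 5))
  expect_equal(strain_from_area(rep(2, 5)), rep(0, 5))
  a2 <- runif(30, 1, 3)
  expect_equal(strain_from_area(a2), strain_from_area(3.7 * a2),
               tolerance = 1e-12)
})

test_that("pe_modulus is the least-squares slope of P on strain", {
  eps <- runif(50, 0, 8)
  expect_equal(pe_modulus(80 + 5 * eps, eps), 5)
  p <- 80 + 5 * eps + rnorm(50)
  expect_equal(pe_modulus(p, eps), pe_modulus(p, eps + 3.2))
  expect_error(pe_modulus(p, rep(1, 50)), "variance")
  expect_error(pe_modulus(p, eps[-1]), "mismatch")
})

test_that("loop area follows the shoelace formula with viscous orientation", {
  # collinear points enclose nothing
  eps <- seq(0, 5, length.out = 20)
  expect_equal(loop_area(70 + 4 * eps, eps), 0)
  # parametric circle of radius r: area pi r^2, traversed with P leading
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  r <- 2.5
  p <- 100 + r * sin(th)
  e <- 3 + r * sin(th - pi / 2)        # strain lags pressure
  expect_equal(loop_area(p, e), pi * r^2, tolerance = 0.01 * pi * r^2)
  expect_equal(loop_area(rev(p), rev(e)), -loop_area(p, e))
  expect_error(loop_area(p[1:2], e[1:2]), "3 vertices")
})

test_that("pulse_rmse truncates to the shorter pulse and is symmetric", {
  a <- rnorm(100)
  expect_equal(pulse_rmse(a, a), 0)
  expect_equal(pulse_rmse(a, a + 3), 3)
  b <- rnorm(80)
  expect_equal(pulse_rmse(a, b), pulse_rmse(b, a))
  expect_equal(pulse_rmse(a, b), sqrt(mean((a[1:80] - b)^2)))
  expect_error(pulse_rmse(numeric(0), a), "empty")
})

test_that("beta_errors reproduces hand-computed ME and MAPE", {
  expect_equal(beta_errors(c(5, 7), c(5, 7)), c(me = 0, mape = 0))
  expect_equal(beta_errors(100, 90), c(me = 10, mape = 10))
  expect_equal(beta_errors(c(10, 20), c(8, 24)), c(me = -1, mape = 20))
  expect_error(beta_errors(c(0, 1), c(1, 1)), "zero")
})

test_that("bland_altman reproduces hand-computed limits of agreement", {
  x <- rnorm(10)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_low, 0)
  ba <- bland_altman(c(1, 0), c(0, 1))   # diffs 1, -1
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  ba2 <- bland_altman(x, x + 0.5)
  expect_equal(ba2$mean_diff, -0.5)
  expect_equal(ba2$sd_diff, 0)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("identity-model evaluation is exactly zero end to end", {
  sc <- make_cohort(8, seed = 41)
  m <- make_identity_model(sc$cohort)
  ev <- suppressWarnings(evaluate(m, sc$cohort, identity_model = TRUE))
  expect_equal(ev$n + ev$n_excluded, 8L)
  expect_identical(unname(ev$rmse_pressure["mean"]), 0)
  expect_identical(unname(ev$rmse_area["mean"]), 0)
  expect_identical(ev$me_beta, 0)
  expect_identical(ev$mape_beta, 0)
  for (b in ev$bland_altman) {
    expect_identical(b$mean_diff, 0)
    expect_identical(b$loa_low, 0)
    expect_identical(b$loa_high, 0)
  }
  expect_equal(nrow(ev$per_subject), ev$n)
})

test_that("evaluation recovers the generator's elastic modulus at low viscosity", {
  sc <- make_cohort(12, seed = 43, viscosity_range = c(0.02, 0.05))
  m <- make_identity_model(sc$cohort)
  ev <- evaluate(m, sc$cohort, identity_model = TRUE)
  rec <- merge(ev$per_subject, sc$truth, by = "subject_id")
  mape <- 100 * mean(abs(rec$beta_true - rec$e_true) / rec$e_true)
  expect_lt(mape, 5)
})
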