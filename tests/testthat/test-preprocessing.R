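test_that("area unit conversion multiplies by 1e4 exactly once", {
  r <- make_cohort(1)$cohort$records[[1]]
  r$a_abdominal <- rep(3e-4, length(r$a_abdominal))
  rc <- convert_area_to_cm2(r)
  expect_equal(rc$a_abdominal[1], 3)
  expect_identical(rc$units_area, "cm2")
  expect_error(convert_area_to_cm2(rc), "double conversion")
})

test_that("tile_pulse repeats the pulse periodically and guards lengths", {
  pulse <- sin(seq(0, 2 * pi, length.out = 400))
  tiled <- tile_pulse(pulse, 400, 512)
  expect_length(tiled, 512L)
  expect_identical(tiled[401:512], pulse[1:112])
  expect_identical(tile_pulse(pulse, 400, 400), pulse)
  expect_error(tile_pulse(pulse, 400, 300), "exceeds")
  expect_error(tile_pulse(pulse, 1, 300), ">= 2")
})

test_that("tiled signals are periodic: autocorrelation peaks at the pulse lag", {
  pulse <- cyclepw:::central_pulse(70, 40, 100)
  tiled <- tile_pulse(pulse, 100, 350)
  ac <- stats::acf(tiled, lag.max = 120, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[50:120]) + 49, 100)
})

test_that("resampling preserves length ratio and identity", {
  x <- rnorm(500)
  expect_identical(resample_signal(x, 500, 500), x)
  y <- resample_signal(x, 500, 256)
  expect_length(y, 256L)
})

test_that("resampled sine matches the analytic waveform away from edges", {
  fs_in <- 500; fs_out <- 256; f0 <- 5
  t_in <- (0:2499) / fs_in
  y <- resample_signal(sin(2 * pi * f0 * t_in), fs_in, fs_out)
  t_out <- (seq_along(y) - 1) / fs_out
  core <- 40:(length(y) - 40)
  expect_lt(max(abs(y[core] - sin(2 * pi * f0 * t_out[core]))), 1e-3)
})

test_that("periodic extension removes the edge roll-off for tiled windows", {
  pulse_len <- 400
  pulse <- cyclepw:::central_pulse(70, 40, pulse_len)
  tiled <- tile_pulse(pulse, pulse_len, 600)
  y <- resample_signal(tiled, 500, 256, period = pulse_len)
  # the continuous-time signal is periodic; compare against resampling a
  # much longer tiling and cutting the interior
  long <- tile_pulse(pulse, pulse_len, 600 + 2 * pulse_len)
  ref <- resample_signal(long, 500, 256)
  ref_core <- ref[(round(pulse_len * 256 / 500) + 1):
                  (round(pulse_len * 256 / 500) + 100)]
  y_core <- y[(round(pulse_len * 256 / 500) + 1):
              (round(pulse_len * 256 / 500) + 100)]
  expect_equal(y_core, ref_core, tolerance = 1e-6)
})

test_that("window_spec takes the cohort-maximum pulse duration", {
  sc <- make_cohort(5, seed = 23)
  w <- window_spec(sc$cohort, fs_target = 128)
  pl <- vapply(sc$cohort$records, function(r) round(r$pulse_period * r$fs),
               numeric(1))
  expect_equal(w$window_len_source, max(pl))
  expect_equal(w$window_len_target, round(max(pl) * 128 / 250))
})

test_that("min-max spec maps the training range onto [-1, 1] without clipping", {
  sc <- make_cohort(4, seed = 13)
  sp <- make_specs(sc$cohort)
  pressures <- unlist(lapply(sp$conv$records, function(r)
    c(r$p_brachial, r$p_radial, r$p_abdominal)))
  expect_equal(normalize(min(pressures), sp$norm, "pressure"), -1)
  expect_equal(normalize(max(pressures), sp$norm, "pressure"), 1)
  mid <- (sp$norm$area_min + sp$norm$area_max) / 2
  expect_equal(normalize(mid, sp$norm, "area"), 0)
  # out-of-range values map outside [-1, 1]: affine, no clamp
  beyond <- sp$norm$pressure_max + 10
  expect_gt(normalize(beyond, sp$norm, "pressure"), 1)
  v <- runif(20, 40, 200)
  expect_equal(normalize(normalize(v, sp$norm, "pressure"), sp$norm,
                         "pressure", invert = TRUE), v, tolerance = 1e-12)
  expect_error(fit_minmax(sc$cohort), "cm2")
  const <- sp$conv
  for (i in seq_along(const$records))
    const$records[[i]]$a_abdominal[] <- 2.5
  expect_error(fit_minmax(const), "degenerate")
})

test_that("build_dataset applies the four steps and stays inside [-1, 1]", {
  sc <- make_cohort(6, seed = 29)
  sp <- make_specs(sc$cohort)
  ds <- build_dataset(sc$cohort, sp$norm, sp$window)
  expect_length(ds, 6L)
  for (s in ds) {
    expect_identical(dim(s$x), c(2L, sp$window$window_len_target))
    expect_identical(dim(s$y), c(2L, sp$window$window_len_target))
  }
  vals <- unlist(lapply(ds, function(s) c(s$x, s$y)))
  # band-limited interpolation may overshoot the sampled extrema slightly
  expect_lt(max(abs(vals)), 1 + 1e-2)
  # subject with the maximum pulse duration holds exactly one full cycle
  pl <- vapply(ds, `[[`, integer(1), "pulse_len_target")
  expect_equal(max(pl), sp$window$window_len_target)
})

test_that("denormalization inverts preprocessing to the resampled signal", {
  sc <- make_cohort(4, seed = 31)
  sp <- make_specs(sc$cohort)
  ds <- build_dataset(sc$cohort, sp$norm, sp$window)
  for (i in seq_along(ds)) {
    r <- sp$conv$records[[i]]
    pl <- round(r$pulse_period * r$fs)
    for (ch in list(list("p_abdominal", 1, "pressure"),
                    list("a_abdominal", 2, "area"))) {
      direct <- resample_signal(
        tile_pulse(r[[ch[[1]]]], pl, sp$window$window_len_source),
        sp$window$fs_source, sp$window$fs_target, period = pl)
      inv <- normalize(ds[[i]]$y[ch[[2]], ], sp$norm, ch[[3]], invert = TRUE)
      expect_lt(max(abs(inv - direct)) / max(abs(direct)), 1e-6)
    }
  }
})
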