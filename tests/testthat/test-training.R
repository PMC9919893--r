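test_that("train_config enforces the loss-dependent critic iterations", {
  c1 <- train_config("lsgan", d_iters = 25L)
  expect_identical(c1$d_iters, 1L)
  c2 <- train_config("wgan_gp", d_iters = 15L)
  expect_identical(c2$d_iters, 15L)
  expect_identical(train_config("wgan_gp")$d_iters, 5L)
  expect_identical(train_config()$learning_rate, 1e-4)
  expect_identical(train_config()$batch_size, 96L)
})

test_that("one LSGAN step updates all four networks once", {
  samples <- make_toy_samples(6, len = 64)
  X <- cyclepw:::stack_samples(samples, "x")
  Y <- cyclepw:::stack_samples(samples, "y")
  cfg <- train_config("lsgan", g_gru = 8L, d_l1 = 4L, epochs = 1L,
                      batch_size = 6L, seed = 2L)
  models <- build_models(generator_spec(8), discriminator_spec(4), 64L,
                         seed = 3)
  set.seed(cfg$seed)
  st <- training_step(X, Y, models, cfg)
  expect_s3_class(st$report, "data.frame")
  expect_true(all(is.finite(unlist(st$report[c("adv_x", "adv_y", "cyc_x",
                                               "cyc_y", "g_loss")]))))
  expect_identical(st$opt$dy$t, 1L)
  for (net in c("gxy", "gyx", "dx", "dy"))
    expect_false(identical(unlist(models[[net]]), unlist(st$models[[net]])))
  expect_error(training_step(X, Y[1:3, , , drop = FALSE], models, cfg),
               "equal shapes")
})

test_that("WGAN-GP steps run d_iters critic updates and stay finite", {
  samples <- make_toy_samples(4, len = 127)
  X <- cyclepw:::stack_samples(samples, "x")
  Y <- cyclepw:::stack_samples(samples, "y")
  cfg <- train_config("wgan_gp", g_gru = 8L, d_l1 = 4L, d_iters = 3L,
                      batch_size = 4L, epochs = 1L, seed = 9L)
  models <- build_models(generator_spec(8),
                         discriminator_spec(4, "instance"), 127L, seed = 4)
  set.seed(cfg$seed)
  st <- training_step(X, Y, models, cfg)
  # each critic saw d_iters Adam steps
  expect_identical(st$opt$dy$t, 3L)
  expect_identical(st$opt$gxy$t, 1L)
  expect_true(is.finite(st$report$gp_y) && st$report$gp_y >= 0)
})

test_that("training is deterministic given the config seed", {
  samples <- make_toy_samples(6, len = 64)
  cfg <- train_config("lsgan", g_gru = 8L, d_l1 = 4L, epochs = 3L,
                      batch_size = 3L, seed = 21L)
  f1 <- fit_cyclegan(samples, cfg)
  f2 <- fit_cyclegan(samples, cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(unlist(f1$models$gxy), unlist(f2$models$gxy))
})

test_that("batching arithmetic keeps the last partial batch", {
  samples <- make_toy_samples(10, len = 64)
  cfg <- train_config("lsgan", g_gru = 8L, d_l1 = 4L, epochs = 2L,
                      batch_size = 96L, seed = 1L)
  f <- fit_cyclegan(samples, cfg)
  expect_equal(nrow(f$log), 2L)              # one step per epoch
  cfg2 <- train_config("lsgan", g_gru = 8L, d_l1 = 4L, epochs = 1L,
                       batch_size = 4L, seed = 1L)
  f2 <- fit_cyclegan(samples, cfg2)          # 3 batches: 4 + 4 + 2
  expect_equal(nrow(f2$log), 1L)
})

test_that("cycle loss decreases over a short smoke run", {
  samples <- make_toy_samples(8, len = 64)
  cfg <- train_config("lsgan", g_gru = 8L, d_l1 = 4L, epochs = 50L,
                      batch_size = 8L, seed = 7L)
  f <- fit_cyclegan(samples, cfg)
  first <- f$log$cyc_x[1] + f$log$cyc_y[1]
  last <- f$log$cyc_x[50] + f$log$cyc_y[50]
  expect_lt(last, first)
})

test_that("stronger cycle weights reconstruct the toy mapping better", {
  samples <- make_toy_samples(8, len = 64)
  rec_err <- vapply(c(1, 5, 25), function(lam) {
    cfg <- train_config("lsgan", g_gru = 8L, d_l1 = 4L, epochs = 40L,
                        batch_size = 8L, lambda_cyc = lam, seed = 11L)
    f <- fit_cyclegan(samples, cfg)
    X <- cyclepw:::stack_samples(samples, "x")
    rec <- cyclepw:::gen_fwd(f$models$gyx,
                             cyclepw:::gen_fwd(f$models$gxy, X)$Y)$Y
    mean(abs(rec - X))
  }, numeric(1))
  expect_true(all(diff(rec_err) < 0))
})

test_that("the hyperparameter grid enumerates 12 + 36 experiments", {
  g <- grid_combinations()
  expect_equal(nrow(g), 48L)
  expect_equal(sum(g$loss == "lsgan"), 12L)
  expect_equal(sum(g$loss == "wgan_gp"), 36L)
  expect_true(all(g$d_iters[g$loss == "lsgan"] == 1L))
  g1 <- grid_combinations(loss_kinds = "lsgan", g_gru = 64L, d_l1 = 8L,
                          lambda_cyc = 5)
  expect_equal(nrow(g1), 1L)
})

test_that("grid_search trains each combination and ranks by pressure RMSE", {
  sc <- make_cohort(8, seed = 47)
  sp <- split_cohort(sc$cohort, 0.25, seed = 1)
  base <- train_config(epochs = 2L, batch_size = 6L, seed = 1L)
  grid <- grid_combinations(loss_kinds = "lsgan", g_gru = 8L, d_l1 = 4L,
                            lambda_cyc = c(5, 15))
  res <- suppressWarnings(grid_search(sp$train, sp$test, base, grid,
                                      fs_target = 128))
  expect_equal(nrow(res), 2L)
  expect_true(all(diff(res$rmse_pressure) >= 0))
  expect_true(all(c("rmse_pressure", "rmse_area", "mape_beta") %in%
                    names(res)))
})
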