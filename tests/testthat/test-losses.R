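test_that("LSGAN losses take their closed-form values", {
  expect_equal(lsgan_discriminator_loss(rep(1, 4), rep(0, 4)), 0)
  expect_equal(lsgan_discriminator_loss(rep(0.5, 3), rep(0.5, 3)), 0.25)
  expect_equal(lsgan_discriminator_loss(rep(1, 2), rep(1, 2)), 0.5)
  expect_equal(lsgan_generator_loss(rep(1, 5)), 0)
  expect_equal(lsgan_generator_loss(rep(0, 5)), 0.5)
  expect_equal(lsgan_generator_loss(rep(0.5, 5)), 0.125)
  expect_error(lsgan_generator_loss(numeric(0)), "empty")
  # minimization structure over a score grid
  grid <- seq(0.05, 0.95, by = 0.05)
  dvals <- outer(grid, grid, function(r, f)
    0.5 * (r - 1)^2 + 0.5 * f^2)
  expect_equal(unname(which(dvals == min(dvals), arr.ind = TRUE)[1, ]),
               c(length(grid), 1L))
  gvals <- vapply(grid, lsgan_generator_loss, numeric(1))
  expect_equal(which.min(gvals), length(grid))
})

test_that("WGAN-GP losses take their closed-form values", {
  expect_equal(wgan_gp_discriminator_loss(c(2, 2), c(2, 2), 0), 0)
  expect_equal(wgan_gp_discriminator_loss(rep(3, 4), rep(1, 4), 0.1, 10), -1)
  gp <- 0.37
  expect_equal(wgan_gp_discriminator_loss(rep(0, 2), rep(0, 2), gp, 10),
               10 * gp)
  expect_equal(wgan_generator_loss(rep(0, 3)), 0)
  expect_equal(wgan_generator_loss(rep(5, 3)), -5)
  s <- rnorm(6)
  expect_lt(wgan_generator_loss(s + 1), wgan_generator_loss(s))
  expect_error(wgan_gp_discriminator_loss(1, 1, -0.1), ">= 0")
})

test_that("cycle-consistency loss is a symmetric per-element L1 mean", {
  x <- array(runif(2 * 2 * 10), c(2, 2, 10))
  y <- array(runif(2 * 2 * 10), c(2, 2, 10))
  expect_equal(cycle_consistency_loss(x, x, y, y), 0)
  expect_equal(cycle_consistency_loss(x, x + 0.1, y, y), 0.1)
  expect_equal(cycle_consistency_loss(x, x + 0.2, y, y - 0.3),
               cycle_consistency_loss(y, y - 0.3, x, x + 0.2))
  expect_error(cycle_consistency_loss(x, x[, , 1:5], y, y), "shape")
})

test_that("gradient penalty vanishes for unit-gradient critics", {
  B <- 4; len <- 20
  real <- array(runif(B * 2 * len), c(B, 2, len))
  fake <- array(runif(B * 2 * len), c(B, 2, len))
  a <- rnorm(2 * len)
  a <- a / sqrt(sum(a^2))              # ||a||_2 = 1
  critic_grad <- function(v) {
    g <- array(0, dim(v))
    for (b in seq_len(dim(v)[1])) g[b, , ] <- a
    g
  }
  expect_equal(gradient_penalty(critic_grad, real, fake, seed = 3), 0)
  # D(v) = 2 v for a scalar input: penalty (2 - 1)^2 = 1
  r1 <- array(runif(5), c(5, 1, 1))
  f1 <- array(runif(5), c(5, 1, 1))
  two_grad <- function(v) array(2, dim(v))
  expect_equal(gradient_penalty(two_grad, r1, f1, seed = 1), 1)
  expect_error(gradient_penalty(two_grad, r1, array(0, c(4, 1, 1))), "shape")
})

test_that("analytic critic input gradient matches finite differences", {
  dsc <- cyclepw:::with_seed(11, cyclepw:::init_discriminator(
    discriminator_spec(4, "instance"), 127L))
  v <- array(runif(2 * 2 * 127, -1, 1), c(2, 2, 127))
  g <- discriminator_input_grad(dsc, v)
  set.seed(404)
  idx <- sample(length(v), 30)
  eps <- 1e-6
  fd <- vapply(idx, function(i) {
    v1 <- v; v1[i] <- v1[i] + eps
    v2 <- v; v2[i] <- v2[i] - eps
    (sum(cyclepw:::disc_fwd(dsc, v1)$score) -
       sum(cyclepw:::disc_fwd(dsc, v2)$score)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(g[idx] - fd)) / max(abs(fd)), 1e-4)
})

test_that("gradient penalty delta draws are reproducible from the seed", {
  dsc <- cyclepw:::with_seed(2, cyclepw:::init_discriminator(
    discriminator_spec(4, "instance"), 127L))
  real <- array(runif(3 * 2 * 127, -1, 1), c(3, 2, 127))
  fake <- array(runif(3 * 2 * 127, -1, 1), c(3, 2, 127))
  p1 <- gradient_penalty(dsc, real, fake, seed = 42)
  p2 <- gradient_penalty(dsc, real, fake, seed = 42)
  expect_identical(p1, p2)
  expect_gte(p1, 0)
})

test_that("finite-difference penalty parameter gradients track the penalty", {
  # moving the critic parameters along the negative penalty gradient must
  # reduce the penalty (first-order correctness of the update direction)
  dsc <- cyclepw:::with_seed(5, cyclepw:::init_discriminator(
    discriminator_spec(4, "instance"), 127L))
  set.seed(77)
  real <- array(runif(4 * 2 * 127, -1, 1), c(4, 2, 127))
  fake <- array(runif(4 * 2 * 127, -1, 1), c(4, 2, 127))
  delta <- runif(4)
  gg <- cyclepw:::gp_param_grads(dsc, real, fake, delta)
  gvec <- unlist(gg$grads, use.names = FALSE)
  step <- 1e-3 / sqrt(sum(gvec^2))
  moved <- cyclepw:::unflatten_like(
    unlist(dsc, use.names = FALSE) - step * gvec, dsc)
  attributes(moved) <- attributes(dsc)
  gg2 <- cyclepw:::gp_param_grads(moved, real, fake, delta)
  expect_lt(gg2$penalty, gg$penalty)
})
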