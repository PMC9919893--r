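# Adversarial, cycle-consistency and gradient-penalty objectives.

check_scores <- function(...) {
  for (s in list(...))
    if (length(s) == 0L) stop("empty score set")
}

#' Least-squares GAN discriminator loss
#'
#' The discriminator regresses real scores toward 1 and fake scores toward
#' 0: `0.5 * mean((s_real - 1)^2) + 0.5 * mean(s_fake^2)`, a Pearson
#' chi-squared divergence objective. Minimized (= 0) iff the discriminator
#' outputs exactly 1 on real and 0 on fake samples.
#'
#' @param scores_real,scores_fake Numeric score vectors from a sigmoid-head
#'   discriminator.
#' @return Scalar loss.
#' @export
lsgan_discriminator_loss <- function(scores_real, scores_fake) {
  check_scores(scores_real, scores_fake)
  0.5 * mean((scores_real - 1)^2) + 0.5 * mean(scores_fake^2)
}

#' Least-squares GAN generator loss
#'
#' `0.5 * mean((s_fake - 1)^2)`: the generator is rewarded when the
#' discriminator scores its samples as real.
#'
#' @param scores_fake Numeric score vector for generated samples.
#' @return Scalar loss.
#' @export
lsgan_generator_loss <- function(scores_fake) {
  check_scores(scores_fake)
  0.5 * mean((scores_fake - 1)^2)
}

#' Wasserstein critic loss with gradient penalty
#'
#' `mean(s_fake) - mean(s_real) + lambda_gp * gp`, where `gp` is the
#' gradient penalty of [gradient_penalty()] enforcing an approximately
#' 1-Lipschitz critic.
#'
#' @param scores_real,scores_fake Numeric score vectors from a linear-head
#'   critic.
#' @param gp Gradient-penalty value (>= 0).
#' @param lambda_gp Penalty weight (the reference setting is 10).
#' @return Scalar loss.
#' @export
wgan_gp_discriminator_loss <- function(scores_real, scores_fake, gp,
                                       lambda_gp = 10) {
  check_scores(scores_real, scores_fake)
  if (gp < 0) stop("`gp` must be >= 0")
  mean(scores_fake) - mean(scores_real) + lambda_gp * gp
}

#' Wasserstein generator loss
#'
#' `-mean(s_fake)`: the generator pushes critic scores of its samples up.
#'
#' @param scores_fake Numeric score vector for generated samples.
#' @return Scalar loss.
#' @export
wgan_generator_loss <- function(scores_fake) {
  check_scores(scores_fake)
  -mean(scores_fake)
}

#' Cycle-consistency loss
#'
#' Mean absolute element-wise error of the X-domain reconstruction
#' `Gyx(Gxy(x))` against `x`, plus that of the Y-domain reconstruction.
#' The L1 norm is averaged per element so the weight `lambda_cyc` is
#' comparable across window lengths.
#'
#' @param x,x_rec Original and reconstructed X-domain batches (same shape).
#' @param y,y_rec Original and reconstructed Y-domain batches (same shape).
#' @return Scalar loss (>= 0).
#' @export
cycle_consistency_loss <- function(x, x_rec, y, y_rec) {
  if (!identical(dim(x), dim(x_rec)) || !identical(dim(y), dim(y_rec)))
    stop("shape mismatch between originals and reconstructions")
  mean(abs(x_rec - x)) + mean(abs(y_rec - y))
}

# Interpolates between real and fake batches, one delta ~ U[0,1] per sample.
gp_interpolate <- function(real, fake, delta) {
  # batch is the fastest-varying dimension, so a length-B vector recycles
  # to a per-sample broadcast
  real * delta + fake * (1 - delta)
}

#' Gradient penalty for an approximately 1-Lipschitz critic
#'
#' Draws one `delta ~ U[0, 1]` per sample, forms the interpolates
#' `v = delta * real + (1 - delta) * fake`, and returns
#' `mean((||grad_v D(v)||_2 - 1)^2)`. The input gradient is computed by
#' exact backpropagation.
#'
#' @param critic A discriminator parameter state (instance-norm/linear
#'   head), or a function `f(v)` returning the per-sample score gradient
#'   with the shape of `v` (useful for closed-form critics).
#' @param real,fake Batches `[batch, channels, T]` of identical shape.
#' @param seed Integer seed for the `delta` draws; `NULL` uses the current
#'   RNG stream.
#' @return Scalar penalty (>= 0).
#' @export
gradient_penalty <- function(critic, real, fake, seed = NULL) {
  if (!identical(dim(real), dim(fake)))
    stop("`real` and `fake` must have the same shape")
  B <- dim(real)[1]
  delta <- if (is.null(seed)) runif(B) else with_seed(seed, runif(B))
  v <- gp_interpolate(real, fake, delta)
  g <- if (is.function(critic)) critic(v) else discriminator_input_grad(critic, v)
  norms <- sqrt(rowSums(matrix(g, B)^2))
  mean((norms - 1)^2)
}

# Gradient of the penalty with respect to the critic parameters.
# With g_b = grad_v D(v_b) and P = mean_b (||g_b|| - 1)^2, the chain rule
# gives dP/dtheta = d/dtheta [ sum_b u_b . grad_v D(v_b) ] at fixed
# u_b = (2/B) (||g_b|| - 1) / ||g_b|| g_b — a derivative of the scalar
# directional derivative of D along u. It is evaluated by a central finite
# difference of two ordinary backward passes at v +- eps u, which avoids
# hand-deriving a second backward pass; the O(eps^2) truncation error only
# perturbs the critic update, never the reported penalty.
gp_param_grads <- function(dsc, real, fake, delta) {
  B <- dim(real)[1]
  v <- gp_interpolate(real, fake, delta)
  f <- disc_fwd(dsc, v)
  g <- disc_bwd(dsc, f$cache, rep(1, B), want_param_grads = FALSE)$dX
  norms <- sqrt(rowSums(matrix(g, B)^2))
  penalty <- mean((norms - 1)^2)
  u <- g * ((2 / B) * (norms - 1) / pmax(norms, 1e-12))
  eps <- 1e-4 / (sqrt(mean(u * u)) + 1e-20)
  fp <- disc_fwd(dsc, v + eps * u)
  fm <- disc_fwd(dsc, v - eps * u)
  gp_ <- disc_bwd(dsc, fp$cache, rep(1, B))$grads
  gm_ <- disc_bwd(dsc, fm$cache, rep(1, B))$grads
  list(penalty = penalty,
       grads = tree_scale(tree_add(gp_, tree_scale(gm_, -1)), 1 / (2 * eps)))
}
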