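#' Training configuration
#'
#' Collects the optimization hyperparameters: adversarial loss family,
#' cycle-consistency weight, gradient-penalty weight, critic iterations,
#' Adam settings and batching. The reference settings are Adam at learning
#' rate 1e-4, batch size 96 and 1750 epochs; `epochs` is configurable down
#' for desk-scale runs. For the LSGAN loss the number of discriminator
#' updates per generator update is always 1; `d_iters` only applies to the
#' WGAN-GP critic (grid 5/15/25).
#'
#' @param loss_kind `"lsgan"` or `"wgan_gp"`.
#' @param g_gru Generator GRU feature count (grid: 64 or 128).
#' @param d_l1 Discriminator first-layer feature count (grid: 6 or 8).
#' @param lambda_cyc Cycle-consistency weight (grid: 5/15/25).
#' @param lambda_gp Gradient-penalty weight (10; WGAN-GP only).
#' @param d_iters Critic updates per generator update; forced to 1 for
#'   LSGAN, default 5 for WGAN-GP.
#' @param learning_rate Adam learning rate (1e-4).
#' @param batch_size Samples per optimization step (96).
#' @param epochs Training epochs (1750 at full scale).
#' @param adam_betas Adam `(beta1, beta2)`; (0.5, 0.999), the usual GAN
#'   setting.
#' @param seed Integer seed controlling initialization, shuffling and the
#'   gradient-penalty draws.
#' @return An object of class `train_config`.
#' @export
train_config <- function(loss_kind = c("lsgan", "wgan_gp"),
                         g_gru = 64L, d_l1 = 6L,
                         lambda_cyc = 5, lambda_gp = 10, d_iters = NULL,
                         learning_rate = 1e-4, batch_size = 96L,
                         epochs = 1750L, adam_betas = c(0.5, 0.999),
                         seed = 1L) {
  loss_kind <- match.arg(loss_kind)
  if (loss_kind == "lsgan") {
    d_iters <- 1L
  } else if (is.null(d_iters)) {
    d_iters <- 5L
  }
  stopifnot(lambda_cyc >= 0, lambda_gp >= 0, d_iters >= 1L,
            learning_rate > 0, batch_size >= 1L, epochs >= 1L,
            length(adam_betas) == 2L)
  structure(list(loss_kind = loss_kind, g_gru = as.integer(g_gru),
                 d_l1 = as.integer(d_l1), lambda_cyc = lambda_cyc,
                 lambda_gp = lambda_gp, d_iters = as.integer(d_iters),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), adam_betas = adam_betas,
                 seed = as.integer(seed)),
            class = "train_config")
}

# --- Adam (coordinate-wise, on flattened parameter trees) -------------------

adam_init <- function(params) {
  n <- param_count(params)
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas, eps = 1e-8) {
  p <- unlist(params, use.names = FALSE)
  g <- unlist(grads, use.names = FALSE)
  state$t <- state$t + 1L
  state$m <- betas[1] * state$m + (1 - betas[1]) * g
  state$v <- betas[2] * state$v + (1 - betas[2]) * g * g
  mhat <- state$m / (1 - betas[1]^state$t)
  vhat <- state$v / (1 - betas[2]^state$t)
  new <- unflatten_like(p - lr * mhat / (sqrt(vhat) + eps), params)
  attributes(new) <- attributes(params)
  list(params = new, state = state)
}

# --- one optimization step ---------------------------------------------------

#' One CycleGAN optimization step on a paired batch
#'
#' Updates the two discriminators (for WGAN-GP, `d_iters` critic updates on
#' detached fake samples), then both generators once on the adversarial plus
#' `lambda_cyc`-weighted cycle objective.
#'
#' @param batch_x,batch_y `[batch, 2, T]` arrays of peripheral / central
#'   samples (equal batch sizes).
#' @param models A [build_models()] object.
#' @param config A [train_config()].
#' @param opt Optimizer state list as returned by this function (or `NULL`
#'   to initialize).
#' @return List with updated `models`, `opt` and a one-row `report`
#'   data.frame of loss scalars.
#' @export
training_step <- function(batch_x, batch_y, models, config, opt = NULL) {
  stopifnot(inherits(models, "cyclegan_models"),
            inherits(config, "train_config"))
  if (!identical(dim(batch_x), dim(batch_y)))
    stop("batch_x and batch_y must have equal shapes")
  if (is.null(opt))
    opt <- list(gxy = adam_init(models$gxy), gyx = adam_init(models$gyx),
                dx = adam_init(models$dx), dy = adam_init(models$dy))
  lr <- config$learning_rate
  bt <- config$adam_betas
  B <- dim(batch_x)[1]
  lsgan <- config$loss_kind == "lsgan"

  # fake samples; generator parameters are frozen during the D updates, so
  # these forwards are reused (with their caches) for the generator step
  fx <- gen_fwd(models$gxy, batch_x)   # y_hat = Gxy(x)
  fy <- gen_fwd(models$gyx, batch_y)   # x_hat = Gyx(y)

  upd_disc <- function(dsc, st, real, fake) {
    gp_val <- NA_real_
    for (it in seq_len(config$d_iters)) {
      fr <- disc_fwd(dsc, real)
      ff <- disc_fwd(dsc, fake)
      if (lsgan) {
        loss <- lsgan_discriminator_loss(fr$score, ff$score)
        g <- tree_add(disc_bwd(dsc, fr$cache, (fr$score - 1) / B)$grads,
                      disc_bwd(dsc, ff$cache, ff$score / B)$grads)
      } else {
        delta <- runif(B)
        gpg <- gp_param_grads(dsc, real, fake, delta)
        gp_val <- gpg$penalty
        loss <- wgan_gp_discriminator_loss(fr$score, ff$score, gpg$penalty,
                                           config$lambda_gp)
        g <- tree_add(
          tree_add(disc_bwd(dsc, fr$cache, rep(-1 / B, B))$grads,
                   disc_bwd(dsc, ff$cache, rep(1 / B, B))$grads),
          tree_scale(gpg$grads, config$lambda_gp))
      }
      if (!is.finite(loss)) stop("discriminator loss diverged (NaN)")
      up <- adam_step(dsc, g, st, lr, bt)
      dsc <- up$params; st <- up$state
    }
    list(dsc = dsc, st = st, loss = loss, gp = gp_val)
  }
  uy <- upd_disc(models$dy, opt$dy, batch_y, fx$Y)
  ux <- upd_disc(models$dx, opt$dx, batch_x, fy$Y)
  models$dy <- uy$dsc; opt$dy <- uy$st
  models$dx <- ux$dsc; opt$dx <- ux$st

  # generator step: adversarial terms against the updated discriminators
  sfy <- disc_fwd(models$dy, fx$Y)
  sfx <- disc_fwd(models$dx, fy$Y)
  if (lsgan) {
    adv_y <- lsgan_generator_loss(sfy$score)
    adv_x <- lsgan_generator_loss(sfx$score)
    dy_fake <- disc_bwd(models$dy, sfy$cache, (sfy$score - 1) / B,
                        want_param_grads = FALSE)$dX
    dx_fake <- disc_bwd(models$dx, sfx$cache, (sfx$score - 1) / B,
                        want_param_grads = FALSE)$dX
  } else {
    adv_y <- wgan_generator_loss(sfy$score)
    adv_x <- wgan_generator_loss(sfx$score)
    dy_fake <- disc_bwd(models$dy, sfy$cache, rep(-1 / B, B),
                        want_param_grads = FALSE)$dX
    dx_fake <- disc_bwd(models$dx, sfx$cache, rep(-1 / B, B),
                        want_param_grads = FALSE)$dX
  }

  rx <- gen_fwd(models$gyx, fx$Y)      # x_rec = Gyx(Gxy(x))
  ry <- gen_fwd(models$gxy, fy$Y)      # y_rec = Gxy(Gyx(y))
  cyc_x <- mean(abs(rx$Y - batch_x))
  cyc_y <- mean(abs(ry$Y - batch_y))
  ne <- length(batch_x)
  lam <- config$lambda_cyc

  b_rx <- gen_bwd(models$gyx, rx$cache, lam * sign(rx$Y - batch_x) / ne)
  b_fx <- gen_bwd(models$gxy, fx$cache, dy_fake + b_rx$dX)
  b_ry <- gen_bwd(models$gxy, ry$cache, lam * sign(ry$Y - batch_y) / ne)
  b_fy <- gen_bwd(models$gyx, fy$cache, dx_fake + b_ry$dX)

  g_total <- adv_x + adv_y + lam * (cyc_x + cyc_y)
  if (!is.finite(g_total)) stop("generator loss diverged (NaN)")

  up <- adam_step(models$gxy, tree_add(b_fx$grads, b_ry$grads), opt$gxy,
                  lr, bt)
  models$gxy <- up$params; opt$gxy <- up$state
  up <- adam_step(models$gyx, tree_add(b_fy$grads, b_rx$grads), opt$gyx,
                  lr, bt)
  models$gyx <- up$params; opt$gyx <- up$state

  list(models = models, opt = opt,
       report = data.frame(adv_x = adv_x, adv_y = adv_y, cyc_x = cyc_x,
                           cyc_y = cyc_y, gp_x = ux$gp, gp_y = uy$gp,
                           d_x_loss = ux$loss, d_y_loss = uy$loss,
                           g_loss = g_total))
}

# Stack a list of paired samples into [n, 2, T] arrays.
stack_samples <- function(samples, field) {
  Tn <- ncol(samples[[1]][[field]])
  n <- length(samples)
  out <- array(0, c(n, 2L, Tn))
  for (i in seq_len(n)) out[i, , ] <- samples[[i]][[field]]
  out
}

#' Train a CycleGAN on preprocessed paired samples
#'
#' Runs `config$epochs` epochs of [training_step()] with per-epoch
#' reshuffling; the last partial batch is kept. All randomness
#' (initialization, shuffling, gradient-penalty draws) derives from
#' `config$seed`, so two runs with the same inputs are identical.
#'
#' @param samples List of paired samples from [build_dataset()].
#' @param config A [train_config()].
#' @param models Optional pre-built [build_models()] object; by default the
#'   architecture is derived from `config` (`g_gru`, `d_l1`, and the
#'   loss-dependent normalization/head pairing).
#' @param verbose Print a progress line every 50 epochs.
#' @param checkpoint_dir,checkpoint_every Optional directory and epoch
#'   interval for saving intermediate model states.
#' @return An object of class `cyclegan_fit`: `models`, `config` and `log`
#'   (one row of loss scalars per epoch).
#' @export
fit_cyclegan <- function(samples, config, models = NULL, verbose = FALSE,
                         checkpoint_dir = NULL, checkpoint_every = 0L) {
  stopifnot(length(samples) >= 1L, inherits(config, "train_config"))
  X <- stack_samples(samples, "x")
  Y <- stack_samples(samples, "y")
  n <- dim(X)[1]
  set.seed(config$seed)
  if (is.null(models)) {
    g_spec <- generator_spec(config$g_gru)
    d_spec <- discriminator_spec(
      config$d_l1,
      norm_kind = if (config$loss_kind == "lsgan") "batch" else "instance")
    models <- build_models(g_spec, d_spec, dim(X)[3],
                           seed = child_seed(config$seed, 1L))
  }
  opt <- NULL
  log <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    rows <- vector("list", length(batches))
    for (b in seq_along(batches)) {
      ib <- batches[[b]]
      step <- tryCatch(
        training_step(X[ib, , , drop = FALSE], Y[ib, , , drop = FALSE],
                      models, config, opt),
        error = function(e) stop("divergence at epoch ", epoch, ", step ", b,
                                 ": ", conditionMessage(e), call. = FALSE))
      models <- step$models; opt <- step$opt
      rows[[b]] <- step$report
    }
    log[[epoch]] <- cbind(epoch = epoch,
                          as.data.frame(lapply(do.call(rbind, rows), mean)))
    if (verbose && (epoch %% 50L == 0L || epoch == 1L))
      message(sprintf("epoch %4d: g=%.4f cyc=%.4f d=(%.4f, %.4f)",
                      epoch, log[[epoch]]$g_loss,
                      log[[epoch]]$cyc_x + log[[epoch]]$cyc_y,
                      log[[epoch]]$d_x_loss, log[[epoch]]$d_y_loss))
    if (!is.null(checkpoint_dir) && checkpoint_every > 0L &&
        epoch %% checkpoint_every == 0L) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(models = models, config = config, epoch = epoch),
              file.path(checkpoint_dir, sprintf("epoch%05d.rds", epoch)))
    }
  }
  structure(list(models = models, config = config,
                 log = do.call(rbind, log)),
            class = "cyclegan_fit")
}

#' Train the full pipeline on a cohort
#'
#' Convenience wrapper binding preprocessing and training: converts areas to
#' cm^2, fits the window and min-max specifications (on the given training
#' cohort unless supplied — pass a window computed on the full cohort when a
#' train/test split is in use), builds the paired dataset and fits the
#' CycleGAN. The returned object carries everything needed for inference
#' and exact inversion to physical units.
#'
#' @param train A training [cohort()].
#' @param config A [train_config()].
#' @param fs_target Target sampling frequency in Hz (default 256).
#' @param window Optional [window_spec()]; default computed from `train`.
#' @param norm Optional [fit_minmax()] spec; default fitted on `train`.
#' @param ... Passed on to [fit_cyclegan()] (`verbose`, checkpointing).
#' @return An object of class `cyclegan_model` with elements `fit`,
#'   `models`, `norm_spec`, `window`, `config`.
#' @export
train_cyclegan <- function(train, config, fs_target = 256, window = NULL,
                           norm = NULL, ...) {
  stopifnot(inherits(train, "cohort"))
  conv <- cohort(lapply(train$records, function(r)
    if (r$units_area == "m2") convert_area_to_cm2(r) else r),
    role = train$role)
  if (is.null(window)) window <- window_spec(conv, fs_target)
  if (is.null(norm)) norm <- fit_minmax(conv)
  samples <- build_dataset(conv, norm, window)
  fitres <- fit_cyclegan(samples, config, ...)
  structure(list(fit = fitres, models = fitres$models, norm_spec = norm,
                 window = window, config = config),
            class = "cyclegan_model")
}

#' @export
print.cyclegan_model <- function(x, ...) {
  cat(sprintf(
    "<cyclegan_model> %s, G_GRU=%d, D_l1=%d, lambda_cyc=%g, %d epochs, window %d @ %g Hz\n",
    x$config$loss_kind, x$config$g_gru, x$config$d_l1, x$config$lambda_cyc,
    x$config$epochs, x$window$window_len_target, x$window$fs_target))
  invisible(x)
}

#' Enumerate the hyperparameter grid
#'
#' LSGAN combinations vary generator features, first-layer discriminator
#' features and the cycle weight (discriminator iterations fixed at 1);
#' WGAN-GP combinations additionally vary the critic iterations. The
#' default grid yields 12 LSGAN + 36 WGAN-GP = 48 experiments.
#'
#' @param loss_kinds,g_gru,d_l1,d_iters,lambda_cyc Grid axes.
#' @return data.frame with one row per experiment.
#' @export
grid_combinations <- function(loss_kinds = c("lsgan", "wgan_gp"),
                              g_gru = c(64L, 128L), d_l1 = c(6L, 8L),
                              d_iters = c(5L, 15L, 25L),
                              lambda_cyc = c(5, 15, 25)) {
  out <- list()
  if ("lsgan" %in% loss_kinds)
    out$lsgan <- expand.grid(loss = "lsgan", g_gru = g_gru, d_l1 = d_l1,
                             d_iters = 1L, lambda_cyc = lambda_cyc,
                             stringsAsFactors = FALSE)
  if ("wgan_gp" %in% loss_kinds)
    out$wgan <- expand.grid(loss = "wgan_gp", g_gru = g_gru, d_l1 = d_l1,
                            d_iters = d_iters, lambda_cyc = lambda_cyc,
                            stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Grid search over hyperparameter combinations
#'
#' Trains one model per grid row and ranks the experiments by validation
#' pressure RMSE (ascending). Note that ranking on the test split, as the
#' headline experiment tables do, lets the selection see the evaluation
#' data; there is no third split.
#'
#' @param train Training [cohort()].
#' @param val Validation/test [cohort()] used for ranking.
#' @param base_config A [train_config()] supplying all non-grid settings.
#' @param grid data.frame from [grid_combinations()].
#' @param fs_target Target sampling frequency in Hz.
#' @param verbose Print one line per experiment.
#' @return data.frame: the grid plus `rmse_pressure`, `rmse_area`,
#'   `mape_beta` per row, sorted by `rmse_pressure`; the fitted models are
#'   attached as the `"models"` attribute (in grid order).
#' @export
grid_search <- function(train, val, base_config, grid = grid_combinations(),
                        fs_target = 256, verbose = FALSE) {
  stopifnot(nrow(grid) >= 1L)
  full <- cohort(c(train$records, val$records), role = "full")
  window <- window_spec(cohort(lapply(full$records, function(r)
    if (r$units_area == "m2") convert_area_to_cm2(r) else r), "full"),
    fs_target)
  fits <- vector("list", nrow(grid))
  metrics <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$loss_kind <- grid$loss[i]
    cfg$g_gru <- grid$g_gru[i]
    cfg$d_l1 <- grid$d_l1[i]
    cfg$d_iters <- if (grid$loss[i] == "lsgan") 1L else grid$d_iters[i]
    cfg$lambda_cyc <- grid$lambda_cyc[i]
    m <- train_cyclegan(train, cfg, fs_target = fs_target, window = window)
    ev <- evaluate(m, val)
    fits[[i]] <- m
    metrics[[i]] <- data.frame(rmse_pressure = ev$rmse_pressure["mean"],
                               rmse_area = ev$rmse_area["mean"],
                               mape_beta = ev$mape_beta)
    if (verbose)
      message(sprintf("[%d/%d] %s G=%d D=%d it=%d lam=%g -> RMSE_P %.3f",
                      i, nrow(grid), grid$loss[i], grid$g_gru[i],
                      grid$d_l1[i], cfg$d_iters, grid$lambda_cyc[i],
                      metrics[[i]]$rmse_pressure))
  }
  res <- cbind(grid, do.call(rbind, metrics))
  rownames(res) <- NULL
  res <- res[order(res$rmse_pressure), ]
  attr(res, "models") <- fits
  res
}
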