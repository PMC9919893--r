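# Low-level neural-network layers with hand-derived forward/backward passes.
# Batch tensors are 3D arrays [batch, channels, time]; the batch dimension is
# fastest-varying, so per-channel or per-sample statistics broadcast by plain
# R recycling. All heavy products go through BLAS (crossprod/tcrossprod).

sigmoid <- function(x) 1 / (1 + exp(-x))

# Random orthogonal matrix (QR of a Gaussian matrix).
orthogonal_matrix <- function(n) qr.Q(qr(matrix(rnorm(n * n), n, n)))

# --- GRU layer -------------------------------------------------------------
# Gate order in the stacked weight matrices: reset (r), update (z),
# candidate (n), following the usual convention
#   r_t = s(Wi_r x + bi_r + Wh_r h + bh_r)
#   z_t = s(Wi_z x + bi_z + Wh_z h + bh_z)
#   n_t = tanh(Wi_n x + bi_n + r_t * (Wh_n h + bh_n))
#   h_t = (1 - z_t) * n_t + z_t * h_{t-1}

init_gru_layer <- function(in_dim, hidden, recurrent_gain = 0.9) {
  k <- 1 / sqrt(hidden)
  Wh <- do.call(cbind, lapply(1:3, function(i)
    recurrent_gain * orthogonal_matrix(hidden)))
  list(Wi = matrix(runif(in_dim * 3L * hidden, -k, k), in_dim, 3L * hidden),
       Wh = Wh, bi = numeric(3L * hidden), bh = numeric(3L * hidden))
}

# Sequences flow through the GRU as "stacked" matrices of shape
# [B*T, features] whose rows are grouped time-major (rows (t-1)*B+1 .. t*B
# hold timestep t), avoiding 3D-array slicing in the hot loop. Per-timestep
# caches are lists of small matrices (stored by reference, not copied).

gru_forward_m <- function(p, Xmat, B, Tn) {
  out <- gru_fwd_cpp(p$Wi, p$Wh, p$bi, p$bh, Xmat, B, Tn)
  out$Xmat <- Xmat
  out
}

gru_backward_m <- function(p, cache, dHmat, B, Tn) {
  out <- gru_bwd_cpp(p$Wi, p$Wh, cache$Xmat, cache$Hmat, cache$R, cache$Z,
                     cache$N, cache$M, dHmat, B, Tn)
  list(grads = list(Wi = out$dWi, Wh = out$dWh,
                    bi = as.numeric(out$dbi), bh = as.numeric(out$dbh)),
       dXmat = out$dXmat)
}

# --- generator: 2 stacked GRU layers + per-timestep linear head + tanh -----

init_generator <- function(spec) {
  H <- spec$gru_features
  structure(
    list(l1 = init_gru_layer(spec$in_channels, H),
         l2 = init_gru_layer(H, H),
         proj = list(W = matrix(rnorm(H * spec$out_channels, 0, 0.02),
                                H, spec$out_channels),
                     b = numeric(spec$out_channels))),
    spec = spec, class = "gru_generator")
}

gen_fwd <- function(gen, X) {
  d <- dim(X); B <- d[1]; Cin <- d[2]; Tn <- d[3]
  Cout <- ncol(gen$proj$W)
  Xmat <- matrix(aperm(X, c(1, 3, 2)), B * Tn, Cin)
  f1 <- gru_forward_m(gen$l1, Xmat, B, Tn)
  f2 <- gru_forward_m(gen$l2, f1$Hmat, B, Tn)
  Ymat <- tanh(f2$Hmat %*% gen$proj$W + rep(gen$proj$b, each = B * Tn))
  list(Y = aperm(array(Ymat, c(B, Tn, Cout)), c(1, 3, 2)),
       cache = list(f1 = f1, f2 = f2, Ymat = Ymat,
                    dims = c(B, Tn, Cin, Cout)))
}

gen_bwd <- function(gen, cache, dY) {
  d <- cache$dims; B <- d[1]; Tn <- d[2]; Cin <- d[3]; Cout <- d[4]
  dYmat <- matrix(aperm(dY, c(1, 3, 2)), B * Tn, Cout)
  dpre <- dYmat * (1 - cache$Ymat^2)
  dW <- crossprod(cache$f2$Hmat, dpre)
  db <- colSums(dpre)
  b2 <- gru_backward_m(gen$l2, cache$f2, tcrossprod(dpre, gen$proj$W),
                       B, Tn)
  b1 <- gru_backward_m(gen$l1, cache$f1, b2$dXmat, B, Tn)
  list(grads = list(l1 = b1$grads, l2 = b2$grads,
                    proj = list(W = dW, b = db)),
       dX = aperm(array(b1$dXmat, c(B, Tn, Cin)), c(1, 3, 2)))
}

# --- 1D convolution via im2col ---------------------------------------------
# Column order of the unrolled patch matrix (and of W's rows) is channel-
# fastest: row (c, k) of W sits at index c + (k - 1) * C_in.

conv1d_forward <- function(p, X, k, stride, pad) {
  d <- dim(X); B <- d[1]; Cin <- d[2]; Tn <- d[3]
  Tp <- Tn + 2L * pad
  if (Tp < k) stop("input too short for convolution kernel")
  T_out <- (Tp - k) %/% stride + 1L
  Xp <- array(0, c(B, Cin, Tp))
  Xp[, , pad + (1:Tn)] <- X
  A <- array(0, c(B, Cin, k, T_out))
  idx <- lapply(1:k, function(j) seq(j, by = stride, length.out = T_out))
  for (j in 1:k) A[, , j, ] <- Xp[, , idx[[j]]]
  colmat <- matrix(aperm(A, c(1, 4, 2, 3)), B * T_out, Cin * k)
  Cout <- length(p$b)
  Ymat <- colmat %*% p$W + rep(p$b, each = B * T_out)
  list(Y = aperm(array(Ymat, c(B, T_out, Cout)), c(1, 3, 2)),
       cache = list(colmat = colmat, idx = idx,
                    dims = c(B, Cin, Tn, T_out, Tp)))
}

conv1d_backward <- function(p, cache, dY, k, pad, want_param_grads = TRUE) {
  d <- cache$dims; B <- d[1]; Cin <- d[2]; Tn <- d[3]; T_out <- d[4]
  Tp <- d[5]
  Cout <- length(p$b)
  dYmat <- matrix(aperm(dY, c(1, 3, 2)), B * T_out, Cout)
  grads <- NULL
  if (want_param_grads)
    grads <- list(W = crossprod(cache$colmat, dYmat), b = colSums(dYmat))
  dA <- aperm(array(tcrossprod(dYmat, p$W), c(B, T_out, Cin, k)),
              c(1, 3, 4, 2))
  dXp <- array(0, c(B, Cin, Tp))
  for (j in 1:k)
    dXp[, , cache$idx[[j]]] <- array(dXp[, , cache$idx[[j]]],
                                     c(B, Cin, T_out)) +
      array(dA[, , j, ], c(B, Cin, T_out))
  list(grads = grads, dX = dXp[, , pad + (1:Tn), drop = FALSE])
}

# --- normalization layers ---------------------------------------------------

# Batch normalization over (batch, time) per channel, affine, batch statistics.
bn_forward <- function(p, X, eps = 1e-5) {
  d <- dim(X); B <- d[1]; Tn <- d[3]; m <- B * Tn
  mu <- rowSums(colSums(X)) / m
  Xc <- X - rep(mu, each = B)
  v <- rowSums(colSums(Xc * Xc)) / m
  istd <- 1 / sqrt(v + eps)
  Xh <- Xc * rep(istd, each = B)
  list(Y = Xh * rep(p$gamma, each = B) + rep(p$beta, each = B),
       cache = list(Xh = Xh, istd = istd, dims = d))
}

bn_backward <- function(p, cache, dY, want_param_grads = TRUE) {
  d <- cache$dims; B <- d[1]; m <- B * d[3]
  Xh <- cache$Xh
  grads <- NULL
  if (want_param_grads)
    grads <- list(gamma = rowSums(colSums(dY * Xh)),
                  beta = rowSums(colSums(dY)))
  dXh <- dY * rep(p$gamma, each = B)
  s_d <- rowSums(colSums(dXh)) / m
  s_dx <- rowSums(colSums(dXh * Xh)) / m
  dX <- (dXh - rep(s_d, each = B) - Xh * rep(s_dx, each = B)) *
    rep(cache$istd, each = B)
  list(grads = grads, dX = dX)
}

# Instance normalization over time per (sample, channel), no affine terms.
in_forward <- function(X, eps = 1e-5) {
  d <- dim(X); Tn <- d[3]
  mu <- rowSums(X, dims = 2) / Tn
  Xc <- X - c(mu)
  v <- rowSums(Xc * Xc, dims = 2) / Tn
  istd <- 1 / sqrt(v + eps)
  Xh <- Xc * c(istd)
  list(Y = Xh, cache = list(Xh = Xh, istd = istd, dims = d))
}

in_backward <- function(cache, dY) {
  Tn <- cache$dims[3]
  Xh <- cache$Xh
  s_d <- rowSums(dY, dims = 2) / Tn
  s_dx <- rowSums(dY * Xh, dims = 2) / Tn
  (dY - c(s_d) - Xh * c(s_dx)) * c(cache$istd)
}

lrelu_forward <- function(X, slope) {
  mask <- X > 0
  Y <- X
  Y[!mask] <- slope * Y[!mask]
  list(Y = Y, cache = mask)
}

lrelu_backward <- function(mask, dY, slope) {
  dX <- dY
  dX[!mask] <- slope * dX[!mask]
  dX
}

# --- discriminator: 5 conv layers (norm + LeakyReLU each), flatten, linear --

init_discriminator <- function(spec, t_in) {
  chans <- disc_channels(spec)
  t <- t_in
  convs <- vector("list", spec$num_conv_layers)
  norms <- if (spec$norm_kind == "batch")
    vector("list", spec$num_conv_layers) else NULL
  for (l in seq_len(spec$num_conv_layers)) {
    cin <- chans[l]; cout <- chans[l + 1L]
    convs[[l]] <- list(W = matrix(rnorm(cin * spec$kernel * cout, 0, 0.02),
                                  cin * spec$kernel, cout),
                       b = numeric(cout))
    if (spec$norm_kind == "batch")
      norms[[l]] <- list(gamma = rep(1, cout), beta = numeric(cout))
    t <- conv_output_length(t, spec$kernel, spec$stride, spec$padding)
  }
  flat <- as.integer(chans[spec$num_conv_layers + 1L] * t)
  params <- list(convs = convs,
                 head = list(W = matrix(rnorm(flat, 0, 0.02), flat, 1L),
                             b = 0))
  if (!is.null(norms)) params$norms <- norms
  structure(params, spec = spec, t_in = t_in, flat_len = flat,
            class = "conv_discriminator")
}

disc_fwd <- function(dsc, X) {
  spec <- attr(dsc, "spec")
  h <- X
  caches <- vector("list", spec$num_conv_layers)
  for (l in seq_len(spec$num_conv_layers)) {
    cf <- conv1d_forward(dsc$convs[[l]], h, spec$kernel, spec$stride,
                         spec$padding)
    nf <- if (spec$norm_kind == "batch") bn_forward(dsc$norms[[l]], cf$Y)
          else in_forward(cf$Y)
    lf <- lrelu_forward(nf$Y, spec$leaky_relu_slope)
    caches[[l]] <- list(conv = cf$cache, norm = nf$cache, act = lf$cache)
    h <- lf$Y
  }
  d <- dim(h); B <- d[1]
  hmat <- matrix(h, B, d[2] * d[3])
  pre <- as.numeric(hmat %*% dsc$head$W) + dsc$head$b
  s <- if (spec$final_activation == "sigmoid") sigmoid(pre) else pre
  list(score = s, cache = list(layers = caches, hmat = hmat, hdims = d,
                               s = s))
}

disc_bwd <- function(dsc, cache, dscore, want_param_grads = TRUE) {
  spec <- attr(dsc, "spec")
  d <- cache$hdims; B <- d[1]
  dpre <- if (spec$final_activation == "sigmoid")
    dscore * cache$s * (1 - cache$s) else dscore
  dpre <- matrix(dpre, B, 1L)
  grads <- NULL
  if (want_param_grads)
    grads <- list(convs = vector("list", spec$num_conv_layers),
                  head = list(W = crossprod(cache$hmat, dpre),
                              b = sum(dpre)))
  if (want_param_grads && spec$norm_kind == "batch")
    grads$norms <- vector("list", spec$num_conv_layers)
  dh <- array(tcrossprod(dpre, dsc$head$W), d)
  for (l in spec$num_conv_layers:1) {
    cl <- cache$layers[[l]]
    dh <- lrelu_backward(cl$act, dh, spec$leaky_relu_slope)
    if (spec$norm_kind == "batch") {
      nb <- bn_backward(dsc$norms[[l]], cl$norm, dh, want_param_grads)
      if (want_param_grads) grads$norms[[l]] <- nb$grads
      dh <- nb$dX
    } else {
      dh <- in_backward(cl$norm, dh)
    }
    cb <- conv1d_backward(dsc$convs[[l]], cl$conv, dh, spec$kernel,
                          spec$padding, want_param_grads)
    if (want_param_grads) grads$convs[[l]] <- cb$grads
    dh <- cb$dX
  }
  list(grads = grads, dX = dh)
}

# --- parameter trees ---------------------------------------------------------
# Parameters are nested lists with numeric leaves only; gradients mirror the
# structure exactly, so flattening with unlist() lines both up for Adam.

tree_add <- function(a, b) {
  if (is.list(a)) return(mapply(tree_add, a, b, SIMPLIFY = FALSE))
  a + b
}

tree_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, tree_scale, s = s))
  a * s
}

unflatten_like <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(sk) {
    if (is.list(sk)) return(lapply(sk, walk))
    n <- length(sk)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(sk)
    out
  }
  walk(skeleton)
}

param_count <- function(params) length(unlist(params, use.names = FALSE))
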