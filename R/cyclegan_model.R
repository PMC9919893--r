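#' Generator architecture specification
#'
#' Each generator is two stacked gated recurrent unit (GRU) layers followed
#' by a per-timestep linear projection to two output features and a `tanh`
#' activation, so outputs lie strictly in (-1, 1) and the sequence length is
#' preserved. The recurrence is unidirectional (causal) with the hidden
#' state reset at the start of every window.
#'
#' @param gru_features Hidden feature count of each GRU layer (the
#'   hyperparameter grid uses 64 or 128).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(gru_features = 64L) {
  if (gru_features < 1L) stop("`gru_features` must be positive")
  structure(list(gru_features = as.integer(gru_features),
                 num_gru_layers = 2L, in_channels = 2L, out_channels = 2L,
                 output_activation = "tanh"),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Five stacked 1D convolution layers (kernel 5, stride 2, padding 1), each
#' followed by a normalization layer and LeakyReLU(0.2); the output feature
#' count doubles at every layer starting from `first_layer_features`.
#' A final linear projection over the flattened feature map yields one
#' scalar score. The normalization kind and final activation are tied to the
#' adversarial loss in use: batch normalization with a sigmoid head for
#' LSGAN, instance normalization with a linear head for WGAN-GP.
#'
#' @param first_layer_features Output features of the first convolution
#'   (grid: 6 or 8).
#' @param norm_kind `"batch"` or `"instance"`.
#' @param final_activation `"sigmoid"` or `"linear"`; must pair with
#'   `norm_kind` as described above.
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(first_layer_features = 6L,
                               norm_kind = c("batch", "instance"),
                               final_activation = NULL) {
  norm_kind <- match.arg(norm_kind)
  if (is.null(final_activation))
    final_activation <- if (norm_kind == "batch") "sigmoid" else "linear"
  final_activation <- match.arg(final_activation, c("sigmoid", "linear"))
  ok <- (norm_kind == "batch" && final_activation == "sigmoid") ||
    (norm_kind == "instance" && final_activation == "linear")
  if (!ok)
    stop("norm_kind/final_activation must pair as batch+sigmoid (LSGAN) ",
         "or instance+linear (WGAN-GP)")
  if (first_layer_features < 1L) stop("`first_layer_features` must be positive")
  structure(list(first_layer_features = as.integer(first_layer_features),
                 num_conv_layers = 5L, kernel = 5L, stride = 2L,
                 padding = 1L, leaky_relu_slope = 0.2, in_channels = 2L,
                 norm_kind = norm_kind, final_activation = final_activation),
            class = "discriminator_spec")
}

disc_channels <- function(spec)
  as.integer(c(spec$in_channels,
               spec$first_layer_features * 2^(0:(spec$num_conv_layers - 1L))))

#' Output length of a strided 1D convolution
#'
#' `floor((len_in + 2 * padding - kernel) / stride) + 1`.
#'
#' @param len_in Input length in samples.
#' @param kernel,stride,padding Convolution geometry (defaults 5, 2, 1).
#' @return Output length in samples.
#' @export
conv_output_length <- function(len_in, kernel = 5L, stride = 2L,
                               padding = 1L) {
  if (len_in < kernel - 2L * padding)
    stop("`len_in` too small for this kernel/padding")
  as.integer((len_in + 2L * padding - kernel) %/% stride + 1L)
}

# Minimum window length accepted by a discriminator spec.
min_disc_input <- function(spec) {
  t <- 1L
  for (l in seq_len(spec$num_conv_layers))
    t <- (t - 1L) * spec$stride + spec$kernel - 2L * spec$padding
  t
}

#' Build the four CycleGAN networks
#'
#' Initializes the parameter states of the two generators (`gxy`: peripheral
#' to central, `gyx`: central to peripheral) and two discriminators (`dx`
#' scores peripheral windows, `dy` central windows). The four states are
#' independent (no weight sharing) and reproducible from the seed.
#' Recurrent weights use a small-gain orthogonal initialization;
#' convolutional and linear weights are drawn from N(0, 0.02).
#'
#' The discriminator head is a linear projection over the flattened
#' last feature map, so the window length is fixed at build time; the
#' flatten size `first_layer_features * 2^4 * conv_output_length^5(T)` is
#' asserted against the window specification.
#'
#' @param g_spec A [generator_spec()].
#' @param d_spec A [discriminator_spec()].
#' @param window A [window_spec()] or an integer window length in samples.
#' @param seed Integer seed for the initialization.
#' @return An object of class `cyclegan_models` with elements `gxy`, `gyx`,
#'   `dx`, `dy`, plus the two specs and the window length.
#' @export
build_models <- function(g_spec, d_spec, window, seed = 1L) {
  stopifnot(inherits(g_spec, "generator_spec"),
            inherits(d_spec, "discriminator_spec"))
  t_in <- if (inherits(window, "window_spec")) window$window_len_target
          else as.integer(window)
  if (t_in < min_disc_input(d_spec))
    stop("window length ", t_in, " too short for ",
         d_spec$num_conv_layers, " stride-", d_spec$stride, " conv layers ",
         "(minimum ", min_disc_input(d_spec), ")")
  models <- with_seed(seed, list(
    gxy = init_generator(g_spec),
    gyx = init_generator(g_spec),
    dx = init_discriminator(d_spec, t_in),
    dy = init_discriminator(d_spec, t_in)))
  t5 <- t_in
  for (l in seq_len(d_spec$num_conv_layers))
    t5 <- conv_output_length(t5, d_spec$kernel, d_spec$stride, d_spec$padding)
  if (d_spec$norm_kind == "instance" && t5 < 2L)
    stop("window length ", t_in, " leaves a final feature length of ", t5,
         "; instance normalization needs at least 2 (window >= 127)")
  expected <- d_spec$first_layer_features * 2L^(d_spec$num_conv_layers - 1L) * t5
  stopifnot(attr(models$dx, "flat_len") == expected,
            attr(models$dy, "flat_len") == expected)
  structure(c(models, list(g_spec = g_spec, d_spec = d_spec,
                           window_len = t_in)),
            class = "cyclegan_models")
}

# Promote a 2 x T matrix to a [1, 2, T] batch; return it with a restorer.
as_batch <- function(x, in_channels = 2L) {
  if (is.matrix(x)) {
    if (nrow(x) != in_channels)
      stop("expected ", in_channels, " channels, got ", nrow(x))
    list(X = array(x, c(1L, nrow(x), ncol(x))), matrix_in = TRUE)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[2] != in_channels)
      stop("expected ", in_channels, " channels, got ", dim(x)[2])
    list(X = x, matrix_in = FALSE)
  } else stop("input must be a channels x time matrix or [batch, channels, time] array")
}

#' Run a generator forward
#'
#' @param gen A generator parameter state (e.g. `models$gxy`).
#' @param x A 2 x T matrix or a `[batch, 2, T]` array with values in
#'   `[-1, 1]`.
#' @return Output of the same shape as the input, values in (-1, 1).
#' @export
generator_forward <- function(gen, x) {
  stopifnot(inherits(gen, "gru_generator"))
  b <- as_batch(x, attr(gen, "spec")$in_channels)
  Y <- gen_fwd(gen, b$X)$Y
  if (b$matrix_in) matrix(Y[1, , ], dim(Y)[2], dim(Y)[3]) else Y
}

#' Run a discriminator forward
#'
#' @param disc A discriminator parameter state (e.g. `models$dy`).
#' @param v A 2 x T matrix or a `[batch, 2, T]` array.
#' @return One scalar score per sample: in (0, 1) for a sigmoid head
#'   (LSGAN), unbounded for a linear head (WGAN-GP critic).
#' @export
discriminator_forward <- function(disc, v) {
  stopifnot(inherits(disc, "conv_discriminator"))
  spec <- attr(disc, "spec")
  b <- as_batch(v, spec$in_channels)
  if (dim(b$X)[3] != attr(disc, "t_in"))
    stop("discriminator built for windows of ", attr(disc, "t_in"),
         " samples, got ", dim(b$X)[3])
  disc_fwd(disc, b$X)$score
}

#' Gradient of discriminator scores with respect to the input
#'
#' Computes `d/dv sum_b D(v_b)` by backpropagation. With instance
#' normalization (the WGAN-GP critic) samples do not interact, so the
#' result is each sample's own score gradient — the quantity the gradient
#' penalty constrains.
#'
#' @param disc A discriminator parameter state.
#' @param v A 2 x T matrix or `[batch, 2, T]` array.
#' @return Gradient array of the same shape as `v`.
#' @export
discriminator_input_grad <- function(disc, v) {
  stopifnot(inherits(disc, "conv_discriminator"))
  b <- as_batch(v, attr(disc, "spec")$in_channels)
  f <- disc_fwd(disc, b$X)
  g <- disc_bwd(disc, f$cache, rep(1, dim(b$X)[1]),
                want_param_grads = FALSE)$dX
  if (b$matrix_in) matrix(g[1, , ], dim(g)[2], dim(g)[3]) else g
}
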