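#' Convert a record's luminal area from m^2 to cm^2
#'
#' @param record A [waveform_record()] with `units_area = "m2"`.
#' @return The record with `a_abdominal` multiplied by 10^4 and
#'   `units_area = "cm2"`. Converting an already-converted record errors,
#'   guarding against double conversion.
#' @export
convert_area_to_cm2 <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  if (record$units_area != "m2")
    stop("record area already in cm2 (double conversion)")
  record$a_abdominal <- record$a_abdominal * 1e4
  record$units_area <- "cm2"
  record
}

#' Tile one pulse periodically to fill a fixed time window
#'
#' Shorter pulses are repeated, assuming a stationary beat, until the window
#' is full: `out[j] = signal[((j - 1) mod pulse_len) + 1]`.
#'
#' @param signal Numeric series containing at least one full pulse.
#' @param pulse_len Samples in one cardiac cycle (>= 2, <= `window_len`).
#' @param window_len Output length in samples.
#' @return Numeric series of length `window_len`.
#' @export
tile_pulse <- function(signal, pulse_len, window_len) {
  if (pulse_len < 2L) stop("`pulse_len` must be >= 2")
  if (pulse_len > window_len) stop("`pulse_len` exceeds `window_len`")
  if (length(signal) < pulse_len) stop("signal shorter than `pulse_len`")
  pulse <- signal[seq_len(pulse_len)]
  pulse[((seq_len(window_len) - 1L) %% pulse_len) + 1L]
}

# Rational approximation p/q of a positive ratio (smallest q within tol).
rational_ratio <- function(ratio, max_den = 1024L, tol = 1e-9) {
  for (q in seq_len(max_den)) {
    p <- round(ratio * q)
    if (p >= 1 && abs(ratio - p / q) < tol) return(c(p = p, q = q))
  }
  c(p = round(ratio * max_den), q = max_den)
}

#' Band-limited resampling by a rational factor
#'
#' Polyphase rational resampling at ratio `fs_out/fs_in` with a
#' Kaiser-windowed sinc anti-aliasing low-pass (linear phase, group delay
#' compensated). By default the signal is treated as zero outside its
#' support, so the outermost samples roll off; when `period` is given the
#' signal is extended periodically with that period (exact for tiled pulse
#' windows, which are periodic by construction).
#'
#' @param signal Numeric series.
#' @param fs_in,fs_out Input and output sampling frequencies in Hz.
#' @param period Optional period in input samples used to extend the signal
#'   beyond its ends.
#' @return Numeric series of length `round(length(signal) * fs_out / fs_in)`.
#' @export
resample_signal <- function(signal, fs_in, fs_out, period = NULL) {
  if (fs_in <= 0 || fs_out <= 0) stop("sampling frequencies must be positive")
  if (fs_in == fs_out) return(signal)
  n <- length(signal)
  pq <- rational_ratio(fs_out / fs_in)
  p <- pq[["p"]]; q <- pq[["q"]]
  n_out <- round(n * p / q)

  # Kaiser-windowed sinc at the upsampled rate fs_in * p; passband edge at
  # min(fs_in, fs_out)/2 i.e. normalized cutoff 1 / (2 * max(p, q)).
  half_periods <- 10L
  beta <- 12
  m <- max(p, q)
  halfw <- half_periods * m
  i <- -halfw:halfw
  c0 <- 1 / (2 * m)
  sinc <- ifelse(i == 0, 1, sin(2 * pi * c0 * i) / (2 * pi * c0 * i))
  kais <- besselI(beta * sqrt(pmax(0, 1 - (i / halfw)^2)), 0) / besselI(beta, 0)
  h <- p * 2 * c0 * sinc * kais          # gain p restores amplitude
  n_h <- length(h)

  # normalize each polyphase branch to unit DC gain so constants (and the
  # offset of an affine normalization) pass through exactly
  phase_gain <- vapply(0:(p - 1L), function(ph) {
    j <- ceiling((ph - halfw) / p):floor((ph + halfw) / p)
    sum(h[ph + halfw - j * p + 1L])
  }, numeric(1))

  out <- numeric(n_out)
  for (m_out in 0:(n_out - 1L)) {
    u <- m_out * q                        # center at upsampled rate
    j_lo <- ceiling((u - halfw) / p)
    j_hi <- floor((u + halfw) / p)
    j <- j_lo:j_hi                        # contributing input samples (0-based)
    taps <- h[u + halfw - j * p + 1L] / phase_gain[(u %% p) + 1L]
    if (is.null(period)) {
      keep <- j >= 0L & j < n
      out[m_out + 1L] <- sum(taps[keep] * signal[j[keep] + 1L])
    } else {
      out[m_out + 1L] <- sum(taps * signal[(j %% period) + 1L])
    }
  }
  out
}

#' Fixed time-window specification for a cohort
#'
#' The window length at the source rate is the maximum pulse duration across
#' the whole cohort, in samples; the target length is that window re-expressed
#' at the target sampling frequency.
#'
#' @param x A [cohort()] (use the full cohort, before splitting, so train
#'   and test share one window).
#' @param fs_target Target sampling frequency in Hz (default 256).
#' @return An object of class `window_spec` with fields
#'   `window_len_source`, `window_len_target`, `fs_source`, `fs_target`.
#' @export
window_spec <- function(x, fs_target = 256) {
  stopifnot(inherits(x, "cohort"), length(x$records) >= 1L)
  fs <- unique(vapply(x$records, `[[`, numeric(1), "fs"))
  if (length(fs) != 1L) stop("all records must share one sampling frequency")
  wls <- max(vapply(x$records, function(r) round(r$pulse_period * r$fs),
                    numeric(1)))
  structure(list(window_len_source = as.integer(wls),
                 window_len_target = as.integer(round(wls * fs_target / fs)),
                 fs_source = fs, fs_target = fs_target),
            class = "window_spec")
}

#' Fit the min-max normalization on a training cohort
#'
#' One global specification per magnitude: the pressure range is taken over
#' all three pressure channels of every training subject and the area range
#' over the area channel, preserving cross-channel calibration relationships
#' (e.g. peripheral systolic pressure exceeding central systolic pressure).
#' Fitting on the training cohort only prevents test-set leakage.
#'
#' @param train A [cohort()] whose records have areas in cm^2.
#' @return An object of class `minmax_spec`.
#' @export
fit_minmax <- function(train) {
  stopifnot(inherits(train, "cohort"), length(train$records) >= 1L)
  if (any(vapply(train$records, `[[`, character(1), "units_area") != "cm2"))
    stop("areas must be converted to cm2 before fitting (convert_area_to_cm2)")
  p <- unlist(lapply(train$records, function(r)
    range(r$p_brachial, r$p_radial, r$p_abdominal)))
  a <- unlist(lapply(train$records, function(r) range(r$a_abdominal)))
  spec <- list(pressure_min = min(p), pressure_max = max(p),
               area_min = min(a), area_max = max(a),
               fit_scope = "train_only")
  if (spec$pressure_max <= spec$pressure_min)
    stop("degenerate pressure range (min == max)")
  if (spec$area_max <= spec$area_min)
    stop("degenerate area range (min == max)")
  structure(spec, class = "minmax_spec")
}

#' Min-max normalization to \[-1, 1\] and its exact inverse
#'
#' Forward: `v -> 2 * (v - min) / (max - min) - 1`. The map is affine with
#' no clipping, so test-set values outside the fitted range map outside
#' `[-1, 1]`; `invert = TRUE` composes to the identity to machine precision.
#'
#' @param values Numeric vector/matrix in physical units (or in normalized
#'   units when `invert = TRUE`).
#' @param spec A [fit_minmax()] specification.
#' @param magnitude `"pressure"` or `"area"` — selects the fitted range.
#' @param invert Apply the inverse map back to physical units.
#' @return Transformed values, same shape as the input.
#' @export
normalize <- function(values, spec, magnitude = c("pressure", "area"),
                      invert = FALSE) {
  stopifnot(inherits(spec, "minmax_spec"))
  magnitude <- match.arg(magnitude)
  rng <- if (magnitude == "pressure") c(spec$pressure_min, spec$pressure_max)
         else c(spec$area_min, spec$area_max)
  if (invert) (values + 1) / 2 * (rng[2] - rng[1]) + rng[1]
  else 2 * (values - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Build paired, preprocessed training samples from a cohort
#'
#' Applies the four preparation steps in order: (1) area unit conversion to
#' cm^2, (2) pulse tiling at the source rate to the fixed window, (3) min-max
#' normalization to \[-1, 1\], (4) band-limited resampling to the target rate
#' (with periodic extension, since a tiled window is periodic). Each subject
#' yields a paired sample: `x` holds the two peripheral pressure channels
#' (brachial, radial) and `y` the central channels (abdominal pressure,
#' abdominal area), each a 2 x `window_len_target` matrix.
#'
#' @param x A [cohort()].
#' @param spec A [fit_minmax()] specification (fitted on training data).
#' @param window A [window_spec()] computed from the full cohort.
#' @return List of paired samples, each a list with `subject_id`, `x`, `y`
#'   and `pulse_len_target` (samples of one cycle at the target rate).
#' @export
build_dataset <- function(x, spec, window) {
  stopifnot(inherits(x, "cohort"), inherits(spec, "minmax_spec"),
            inherits(window, "window_spec"))
  lapply(x$records, function(r) {
    if (r$units_area == "m2") r <- convert_area_to_cm2(r)
    if (r$fs != window$fs_source)
      stop("record ", r$subject_id, " sampled at ", r$fs,
           " Hz but window expects ", window$fs_source, " Hz")
    pl <- round(r$pulse_period * r$fs)
    prep <- function(sig, magnitude) {
      tiled <- tile_pulse(sig, pl, window$window_len_source)
      normed <- normalize(tiled, spec, magnitude)
      resample_signal(normed, window$fs_source, window$fs_target, period = pl)
    }
    list(subject_id = r$subject_id,
         x = rbind(prep(r$p_brachial, "pressure"),
                   prep(r$p_radial, "pressure")),
         y = rbind(prep(r$p_abdominal, "pressure"),
                   prep(r$a_abdominal, "area")),
         pulse_len_target = as.integer(
           round(pl * window$fs_target / window$fs_source)))
  })
}
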