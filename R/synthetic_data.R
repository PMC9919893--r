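#' Configuration for the synthetic virtual-subject generator
#'
#' Defines the cohort-level distributions from which per-subject
#' cardiovascular parameters are drawn. Defaults produce physiologic
#' magnitudes for a healthy adult population: diastolic pressure 60-90 mmHg,
#' pulse pressure 30-60 mmHg, heart rate 50-90 bpm, diastolic abdominal
#' aortic diameter 1.2-2.2 cm, pressure-strain elastic modulus 4-12 mmHg/%
#' and wall viscosity 0.02-0.2 mmHg s/%. Peripheral (brachial/radial)
#' pressures are amplitude-amplified, delayed copies of the central pulse;
#' the amplification lower bound must exceed 1 so peripheral systolic
#' pressure always exceeds central systolic pressure.
#'
#' @param n_subjects Number of virtual subjects (>= 1).
#' @param fs Sampling frequency in Hz.
#' @param heart_rate_range Beats/min interval.
#' @param dbp_range Diastolic pressure interval, mmHg.
#' @param pp_range Pulse-pressure interval, mmHg.
#' @param e_modulus_range Pressure-strain elastic modulus interval, mmHg/%.
#' @param viscosity_range Wall viscosity interval, mmHg s/%.
#' @param diastolic_diameter_range Diastolic aortic diameter interval, cm.
#' @param peripheral_amplification_range Dimensionless systolic
#'   amplification interval; lower bound must be > 1.
#' @param peripheral_delay_range Aorta-to-radial transit delay interval, s.
#' @param noise_sd Additive Gaussian noise, as a fraction of each signal's
#'   pulse amplitude (default 0: the emulated database is noiseless).
#' @param n_beats Number of cardiac cycles per record (>= 3).
#' @param seed Integer seed; together with the subject index it fully
#'   determines every generated record.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 64L,
                             fs = 500,
                             heart_rate_range = c(50, 90),
                             dbp_range = c(60, 90),
                             pp_range = c(30, 60),
                             e_modulus_range = c(4, 12),
                             viscosity_range = c(0.02, 0.2),
                             diastolic_diameter_range = c(1.2, 2.2),
                             peripheral_amplification_range = c(1.05, 1.25),
                             peripheral_delay_range = c(0.05, 0.12),
                             noise_sd = 0,
                             n_beats = 3L,
                             seed = 1L) {
  rng <- list(heart_rate_range = heart_rate_range, dbp_range = dbp_range,
              pp_range = pp_range, e_modulus_range = e_modulus_range,
              viscosity_range = viscosity_range,
              diastolic_diameter_range = diastolic_diameter_range,
              peripheral_amplification_range = peripheral_amplification_range,
              peripheral_delay_range = peripheral_delay_range)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2L || !is.numeric(r) || r[1] > r[2])
      stop("`", nm, "` must be a numeric interval c(lo, hi) with lo <= hi")
  }
  if (peripheral_amplification_range[1] <= 1)
    stop("peripheral amplification lower bound must be > 1 ",
         "(peripheral SBP must exceed central SBP)")
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1")
  if (fs <= 0) stop("`fs` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (n_beats < 3L) stop("`n_beats` must be >= 3")
  structure(c(list(n_subjects = as.integer(n_subjects), fs = fs), rng,
              list(noise_sd = noise_sd, n_beats = as.integer(n_beats),
                   seed = as.integer(seed))),
            class = "synthetic_config")
}

#' Periodic strain response of a Voigt (spring-dashpot) arterial wall
#'
#' Solves `P(t) - dbp = E * eps(t) + eta * d eps/dt` for the strain
#' `eps` on the periodic steady state. The input is treated as one period of
#' a periodic forcing and the solution is computed harmonic-by-harmonic:
#' each Fourier component of `P - dbp` is divided by `E + i w eta`, which is
#' exact for band-limited periodic signals. With `eta > 0` the strain lags
#' the pressure, producing a counter-clockwise-in-time pressure-strain
#' hysteresis loop; with `eta = 0` the loop degenerates to the line
#' `eps = (P - dbp) / E`.
#'
#' @param pressure Numeric pressure series in mmHg (one period).
#' @param dbp Diastolic (reference) pressure in mmHg.
#' @param e_modulus Elastic modulus E in mmHg per % strain (> 0).
#' @param viscosity Wall viscosity eta in mmHg s per % strain (>= 0).
#' @param fs Sampling frequency in Hz.
#' @return Strain series in %, same length as `pressure`.
#' @export
voigt_strain_response <- function(pressure, dbp, e_modulus, viscosity, fs) {
  if (any(!is.finite(pressure))) stop("`pressure` must be finite (no NaN)")
  if (length(pressure) < 2L) stop("`pressure` must have length >= 2")
  if (e_modulus <= 0) stop("`e_modulus` must be > 0")
  if (viscosity < 0) stop("`viscosity` must be >= 0")
  n <- length(pressure)
  k <- 0:(n - 1L)
  k <- ifelse(k > n / 2, k - n, k)      # signed harmonic index
  omega <- 2 * pi * k * fs / n          # rad/s
  ph <- fft(pressure - dbp)
  eh <- ph / (e_modulus + 1i * omega * viscosity)
  Re(fft(eh, inverse = TRUE)) / n
}

# One central pressure cycle: raised-cosine systolic upstroke followed by an
# exponential diastolic decay returning exactly to DBP at the next foot.
central_pulse <- function(dbp, pp, n_samp, upstroke_frac = 0.3) {
  n_up <- max(2L, round(upstroke_frac * n_samp))
  n_dec <- n_samp - n_up
  up <- dbp + pp * (1 - cos(pi * (0:(n_up - 1L)) / n_up)) / 2
  tau <- n_dec / 3
  s <- 0:(n_dec - 1L)
  dec <- dbp + pp * (exp(-s / tau) - exp(-n_dec / tau)) / (1 - exp(-n_dec / tau))
  c(up, dec)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Map a uniform coupling coordinate into [lo, hi] of a range.
range_at <- function(range, u) range[1] + (range[2] - range[1]) * u

#' Generate one synthetic virtual subject
#'
#' Builds a [waveform_record()] plus its ground truth. The central pressure
#' is a smooth parametric pulse repeated over `n_beats` cycles; the central
#' luminal area follows a circular lumen of diastolic diameter `D_d`
#' distended by the Voigt-wall strain, `A = pi * (D_d * (1 + eps/100))^2 / 4`
#' (stored in m^2, as a database deposit would provide it). Brachial and
#' radial pressures are delayed, amplitude-amplified copies of the central
#' pressure with distinct per-site amplification.
#'
#' Per-subject parameters are drawn from the configured ranges with
#' physiologically motivated couplings: subjects with a stiffer wall (higher
#' elastic modulus) tend to have higher pulse pressure, a wider diastolic
#' diameter and lower peripheral amplification, with bounded jitter around
#' those trends. The couplings keep the peripheral-to-central mapping
#' identifiable, as in real virtual-subject databases where cardiovascular
#' properties co-vary.
#'
#' @param config A [synthetic_config()].
#' @param subject_index Positive integer; `(config$seed, subject_index)`
#'   fully determines the record.
#' @return List with `record` (a [waveform_record()]) and `truth` (one-row
#'   data.frame: subject_id, e_true, eta_true, amplification_brachial,
#'   amplification_radial, dbp, pp, heart_rate, diastolic_diameter).
#' @export
synth_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "synthetic_config"), subject_index >= 1)
  with_seed(child_seed(config$seed, subject_index), {
    fs <- config$fs
    hr <- runif(1, config$heart_rate_range[1], config$heart_rate_range[2])
    n_pulse <- max(16L, round(60 / hr * fs))
    pulse_period <- n_pulse / fs

    e_rng <- config$e_modulus_range
    e_true <- runif(1, e_rng[1], e_rng[2])
    u_e <- if (diff(e_rng) > 0) (e_true - e_rng[1]) / diff(e_rng) else 0.5
    jit <- function() runif(1, -0.15, 0.15)
    pp <- range_at(config$pp_range, clamp01(u_e + jit()))
    d_d <- range_at(config$diastolic_diameter_range, clamp01(u_e + jit()))
    amp_b <- range_at(config$peripheral_amplification_range,
                      clamp01(1 - u_e + jit()))
    amp_r <- amp_b * runif(1, 1.01, 1.05)
    dbp <- runif(1, config$dbp_range[1], config$dbp_range[2])
    eta <- runif(1, config$viscosity_range[1], config$viscosity_range[2])
    delay_r <- runif(1, config$peripheral_delay_range[1],
                     config$peripheral_delay_range[2])
    delay_b <- 0.6 * delay_r

    pc <- central_pulse(dbp, pp, n_pulse)
    eps <- voigt_strain_response(pc, dbp, e_true, eta, fs)
    area_cm2 <- pi * (d_d * (1 + eps / 100))^2 / 4
    shift_pulse <- function(x, delay, amp) {
      s <- round(delay * fs) %% length(x)
      shifted <- if (s > 0) c(x[(length(x) - s + 1L):length(x)],
                              x[1:(length(x) - s)]) else x
      dbp + amp * (shifted - dbp)
    }
    pb <- shift_pulse(pc, delay_b, amp_b)
    pr <- shift_pulse(pc, delay_r, amp_r)

    tile <- function(x) rep(x, config$n_beats)
    pb <- tile(pb); pr <- tile(pr); pa <- tile(pc); aa <- tile(area_cm2)
    if (config$noise_sd > 0) {
      nn <- length(pa)
      pb <- pb + rnorm(nn, 0, config$noise_sd * amp_b * pp)
      pr <- pr + rnorm(nn, 0, config$noise_sd * amp_r * pp)
      pa <- pa + rnorm(nn, 0, config$noise_sd * pp)
      aa <- aa + rnorm(nn, 0, config$noise_sd * diff(range(aa)))
      aa <- pmax(aa, min(area_cm2) * 0.5)   # keep areas positive
    }
    id <- sprintf("synth%04d", subject_index)
    rec <- waveform_record(
      subject_id = id, fs = fs, p_brachial = pb, p_radial = pr,
      p_abdominal = pa, a_abdominal = aa / 1e4,
      pulse_period = pulse_period, units_area = "m2")
    truth <- data.frame(
      subject_id = id, e_true = e_true, eta_true = eta,
      amplification_brachial = amp_b, amplification_radial = amp_r,
      dbp = dbp, pp = pp, heart_rate = hr, diastolic_diameter = d_d,
      stringsAsFactors = FALSE)
    list(record = rec, truth = truth)
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `cohort` (a [cohort()] of `config$n_subjects` records)
#'   and `truth` (data.frame, one row per subject, aligned by `subject_id`).
#' @export
synth_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- lapply(seq_len(config$n_subjects), function(i)
    synth_subject(config, i))
  list(cohort = cohort(lapply(out, `[[`, "record"), role = "full"),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}
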