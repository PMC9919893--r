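# Physical-unit evaluation: pulse segmentation, pressure-strain elastic
# modulus, hysteresis-loop geometry, error statistics and agreement analysis.

#' Detect the first completed pulse in a signal
#'
#' Pulse feet are local minima preceding the systolic upstroke, accepted
#' when the subsequent rise reaches at least 5% of the signal range and
#' separated by at least 0.25 s. The window spans the first two successive
#' feet, half-open `[start, end)`. When the series ends exactly at the end
#' of a cycle — it descends into the boundary after a drop of at least 5%
#' of the range, as happens for the subject whose pulse defines the fixed
#' time window — the position one past the last sample is accepted as the
#' closing foot.
#'
#' @param signal Numeric series (length >= 3).
#' @param fs Sampling frequency in Hz.
#' @return An object of class `pulse_window`: `start`, `end` (1-based
#'   sample indices, half-open) and `fs`.
#' @export
detect_first_pulse <- function(signal, fs) {
  n <- length(signal)
  if (n < 3L) stop("signal too short for pulse detection")
  rng <- max(signal) - min(signal)
  if (rng <= 0) stop("no pulse detected: constant signal")
  interior <- 2:(n - 1L)
  cand <- interior[signal[interior] < signal[interior - 1L] &
                   signal[interior] <= signal[interior + 1L]]
  if (signal[1L] <= signal[2L]) cand <- c(1L, cand)
  # prominence: the rise between this foot and the next candidate (or the
  # signal end) must reach 5% of the signal range
  # prominence: a foot must be reached by a >= 5%-of-range descent or be
  # followed by such a rise (the latter can be cut off by the signal end)
  keep <- vapply(seq_along(cand), function(i) {
    upto <- if (i < length(cand)) cand[i + 1L] else n
    from <- if (i > 1L) cand[i - 1L] else 1L
    rise <- max(signal[cand[i]:upto]) - signal[cand[i]]
    drop <- max(signal[from:cand[i]]) - signal[cand[i]]
    max(rise, drop) >= 0.05 * rng
  }, logical(1))
  cand <- cand[keep]
  # boundary-completed cycle: the series descends into its end after a
  # full-height drop, so the next foot sits one sample past the end
  if (length(cand) && signal[n] < signal[n - 1L] &&
      max(signal[cand[length(cand)]:n]) - signal[n] >= 0.05 * rng)
    cand <- c(cand, n + 1L)
  min_gap <- round(0.25 * fs)
  feet <- integer(0)
  for (f in cand)
    if (!length(feet) || f - feet[length(feet)] >= min_gap)
      feet <- c(feet, f)
  if (length(feet) < 2L)
    stop("no pulse detected: fewer than two pulse feet")
  structure(list(start = feet[1L], end = feet[2L], fs = fs),
            class = "pulse_window")
}

pulse_slice <- function(signal, w) signal[w$start:(w$end - 1L)]

#' Diameter of a circular lumen from its cross-sectional area
#'
#' `D = 2 * sqrt(A / pi)`.
#'
#' @param area Area value(s) in cm^2, strictly positive.
#' @return Diameter value(s) in cm.
#' @export
area_to_diameter <- function(area) {
  if (any(area <= 0)) stop("`area` must be strictly positive")
  2 * sqrt(area / pi)
}

#' Strain series from an area pulse
#'
#' The strain of sample `j` is `100 * (D_j - D_ref) / D_ref` in %, with the
#' reference diameter `D_ref` taken as the pulse minimum (diastolic)
#' diameter, so strain is non-negative over the pulse. Scaling all areas by
#' a constant leaves the strain unchanged.
#'
#' @param area Area pulse in cm^2, strictly positive.
#' @return Strain series in %.
#' @export
strain_from_area <- function(area) {
  d <- area_to_diameter(area)
  100 * (d - min(d)) / min(d)
}

#' Pressure-strain elastic modulus
#'
#' The slope of the simple linear regression of pressure on strain over one
#' pulse: `beta = sum((e - mean(e)) * (p - mean(p))) / sum((e - mean(e))^2)`
#' in mmHg/%. This is the working definition of arterial stiffness used
#' throughout the evaluation.
#'
#' @param pressure Pressure pulse in mmHg.
#' @param strain Strain pulse in % (same length, non-constant).
#' @return Scalar slope in mmHg/%.
#' @export
pe_modulus <- function(pressure, strain) {
  if (length(pressure) != length(strain)) stop("length mismatch")
  if (length(pressure) < 2L) stop("need at least 2 samples")
  ec <- strain - mean(strain)
  den <- sum(ec * ec)
  if (den == 0) stop("zero strain variance: slope undefined")
  sum(ec * (pressure - mean(pressure))) / den
}

#' Signed area of the pressure-strain hysteresis loop
#'
#' Shoelace polygon area over the time-ordered loop vertices, closed
#' between the last and first samples. The sign convention makes the area
#' positive when strain lags pressure (the viscoelastic traversal
#' direction); reversing the traversal flips the sign.
#'
#' @param pressure Pressure pulse in mmHg (length >= 3).
#' @param strain Strain pulse in % (same length).
#' @return Signed loop area in mmHg %.
#' @export
loop_area <- function(pressure, strain) {
  if (length(pressure) != length(strain)) stop("length mismatch")
  n <- length(pressure)
  if (n < 3L) stop("need at least 3 vertices to enclose an area")
  nxt <- c(2:n, 1L)
  # contour integral of P d(eps): positive when pressure leads strain
  0.5 * sum(pressure * strain[nxt] - pressure[nxt] * strain)
}

#' Root-mean-square error between two pulses
#'
#' Both pulses are truncated to the shorter length before comparison, to
#' accommodate duration differences between true and estimated pulses.
#'
#' @param pulse_true,pulse_est Numeric pulses (non-empty).
#' @return Scalar RMSE in the signal's units.
#' @export
pulse_rmse <- function(pulse_true, pulse_est) {
  if (!length(pulse_true) || !length(pulse_est)) stop("empty pulse")
  m <- min(length(pulse_true), length(pulse_est))
  sqrt(mean((pulse_true[seq_len(m)] - pulse_est[seq_len(m)])^2))
}

#' Mean error and mean absolute percentage error of stiffness estimates
#'
#' `ME = mean(beta_true - beta_est)` in mmHg/%;
#' `MAPE = 100 * mean(|beta_true - beta_est| / beta_true)` in %.
#'
#' @param beta_true,beta_est Per-subject modulus values (equal lengths;
#'   `beta_true` must be non-zero elementwise).
#' @return Named numeric vector `c(me, mape)`.
#' @export
beta_errors <- function(beta_true, beta_est) {
  if (length(beta_true) != length(beta_est)) stop("length mismatch")
  if (any(beta_true == 0)) stop("zero true modulus: MAPE undefined")
  c(me = mean(beta_true - beta_est),
    mape = 100 * mean(abs(beta_true - beta_est) / beta_true))
}

#' Bland-Altman agreement summary
#'
#' Differences are `true - estimated`; limits of agreement are the mean
#' difference plus/minus 1.96 sample standard deviations.
#'
#' @param true_values,est_values Paired measurements (length >= 2).
#' @return List with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(true_values, est_values) {
  if (length(true_values) != length(est_values)) stop("length mismatch")
  if (length(true_values) < 2L) stop("need at least 2 pairs")
  d <- true_values - est_values
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Predict central signals in physical units
#'
#' Runs the peripheral-to-central generator on a cohort preprocessed with
#' the model's stored window and normalization specifications, and inverts
#' the normalization, returning abdominal pressure (mmHg) and area (cm^2)
#' at the model's target sampling rate.
#'
#' @param object A [train_cyclegan()] model.
#' @param cohort A [cohort()] to predict for.
#' @param identity_model Debug flag: bypass the generator and return the
#'   (preprocessed, denormalized) true central signals.
#' @param ... Unused.
#' @return List per subject: `subject_id`, `pressure`, `area`, `fs`,
#'   `pulse_len` plus the matching true signals `pressure_true`,
#'   `area_true`.
#' @export
predict.cyclegan_model <- function(object, cohort, identity_model = FALSE,
                                   ...) {
  stopifnot(inherits(cohort, "cohort"))
  samples <- build_dataset(cohort, object$norm_spec, object$window)
  Y <- stack_samples(samples, "y")
  Yhat <- if (identity_model) Y else gen_fwd(object$models$gxy,
                                             stack_samples(samples, "x"))$Y
  lapply(seq_along(samples), function(i) {
    list(subject_id = samples[[i]]$subject_id,
         pressure = normalize(Yhat[i, 1, ], object$norm_spec, "pressure",
                              invert = TRUE),
         area = normalize(Yhat[i, 2, ], object$norm_spec, "area",
                          invert = TRUE),
         pressure_true = normalize(Y[i, 1, ], object$norm_spec, "pressure",
                                   invert = TRUE),
         area_true = normalize(Y[i, 2, ], object$norm_spec, "area",
                               invert = TRUE),
         fs = object$window$fs_target,
         pulse_len = samples[[i]]$pulse_len_target)
  })
}

#' Evaluate a trained model on a cohort
#'
#' For every subject the central prediction is inverted to physical units,
#' the first completed pulse is located in both the true and the estimated
#' pressure signal, and the per-pulse metrics are computed: pressure and
#' area RMSE (over the truncated common length), the pressure-strain
#' elastic modulus of each signal's own complete pulse, the signed
#' hysteresis-loop area, systolic/diastolic pressure and maximum/minimum
#' diameter. Cohort statistics aggregate these as mean +- SD (RMSE), mean
#' error and mean absolute percentage error (modulus), and Bland-Altman
#' summaries (SBP, DBP, d_max, d_min). Subjects whose estimated signal has
#' no detectable pulse are excluded with a warning.
#'
#' @param model A [train_cyclegan()] model.
#' @param cohort A [cohort()] (typically the test split).
#' @param identity_model Debug flag: evaluate the oracle `y_hat := y`,
#'   which must yield exactly zero errors.
#' @return An object of class `eval_report`.
#' @export
evaluate <- function(model, cohort, identity_model = FALSE) {
  stopifnot(inherits(model, "cyclegan_model"))
  preds <- predict(model, cohort, identity_model = identity_model)
  fs <- model$window$fs_target
  rows <- list()
  excluded <- character(0)
  for (p in preds) {
    res <- tryCatch({
      wt <- detect_first_pulse(p$pressure_true, fs)
      we <- detect_first_pulse(p$pressure, fs)
      pt <- pulse_slice(p$pressure_true, wt)
      pe <- pulse_slice(p$pressure, we)
      at <- pulse_slice(p$area_true, wt)
      ae <- pulse_slice(p$area, we)
      st <- strain_from_area(at)
      se <- strain_from_area(ae)
      dt <- area_to_diameter(at)
      de <- area_to_diameter(ae)
      data.frame(
        subject_id = p$subject_id,
        rmse_p = pulse_rmse(pt, pe), rmse_a = pulse_rmse(at, ae),
        beta_true = pe_modulus(pt, st), beta_est = pe_modulus(pe, se),
        loop_area_true = loop_area(pt, st), loop_area_est = loop_area(pe, se),
        sbp_true = max(pt), sbp_est = max(pe),
        dbp_true = min(pt), dbp_est = min(pe),
        dmax_true = max(dt), dmax_est = max(de),
        dmin_true = min(dt), dmin_est = min(de),
        stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("subject ", p$subject_id, " excluded: ",
              conditionMessage(res), call. = FALSE)
      excluded <- c(excluded, p$subject_id)
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no subject could be evaluated")
  per <- do.call(rbind, rows)
  be <- beta_errors(per$beta_true, per$beta_est)
  ba <- list(sbp = bland_altman(per$sbp_true, per$sbp_est),
             dbp = bland_altman(per$dbp_true, per$dbp_est),
             d_max = bland_altman(per$dmax_true, per$dmax_est),
             d_min = bland_altman(per$dmin_true, per$dmin_est))
  structure(list(
    rmse_pressure = c(mean = mean(per$rmse_p), sd = sd(per$rmse_p)),
    rmse_area = c(mean = mean(per$rmse_a), sd = sd(per$rmse_a)),
    me_beta = be[["me"]],
    me_beta_sd = sd(per$beta_true - per$beta_est),
    mape_beta = be[["mape"]],
    mape_beta_sd = sd(100 * abs(per$beta_true - per$beta_est) /
                        per$beta_true),
    bland_altman = ba,
    per_subject = per,
    n = nrow(per), n_excluded = length(excluded), excluded = excluded),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d subjects (%d excluded)\n", x$n, x$n_excluded))
  cat(sprintf("  Pressure RMSE [mmHg]   : %.2f +- %.2f\n",
              x$rmse_pressure["mean"], x$rmse_pressure["sd"]))
  cat(sprintf("  Area RMSE [cm^2]       : %.3f +- %.3f\n",
              x$rmse_area["mean"], x$rmse_area["sd"]))
  cat(sprintf("  E_P-eps ME [mmHg/%%]    : %.2f +- %.2f\n",
              x$me_beta, x$me_beta_sd))
  cat(sprintf("  E_P-eps MAPE [%%]       : %.2f +- %.2f\n",
              x$mape_beta, x$mape_beta_sd))
  for (nm in names(x$bland_altman)) {
    b <- x$bland_altman[[nm]]
    cat(sprintf("  Bland-Altman %-6s    : mean %.3f, LOA [%.3f, %.3f]\n",
                nm, b$mean_diff, b$loa_low, b$loa_high))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the cohort-level summary as JSON and the per-subject table as CSV.
#'
#' @param report An [evaluate()] report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- report[c("rmse_pressure", "rmse_area", "me_beta", "me_beta_sd",
                      "mape_beta", "mape_beta_sd", "bland_altman", "n",
                      "n_excluded", "excluded")]
  jsonlite::write_json(summary, file.path(dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.table::fwrite(report$per_subject, file.path(dir, "per_subject.csv"))
  invisible(dir)
}
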