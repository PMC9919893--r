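# Shared fixture builders. Everything is generated in code; cohorts are
# kept small and sampled coarsely so the suite stays fast.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small synthetic cohort at a reduced sampling rate.
make_cohort <- function(n = 6, seed = 3, fs = 250,
                        heart_rate_range = c(60, 90), ...) {
  synth_cohort(synthetic_config(n_subjects = n, fs = fs,
                                heart_rate_range = heart_rate_range,
                                seed = seed, ...))
}

# Preprocessing specs fitted on a cohort (areas converted to cm^2).
make_specs <- function(coh, fs_target = 128) {
  conv <- cohort(lapply(coh$records, function(r)
    if (r$units_area == "m2") convert_area_to_cm2(r) else r), coh$role)
  list(conv = conv, norm = fit_minmax(conv),
       window = window_spec(conv, fs_target))
}

# A model shell carrying only the preprocessing specs — enough for
# identity-model evaluation, which never touches the networks.
make_identity_model <- function(coh, fs_target = 128) {
  sp <- make_specs(coh, fs_target)
  structure(list(models = NULL, norm_spec = sp$norm, window = sp$window,
                 config = NULL),
            class = "cyclegan_model")
}

# Hand-built paired samples for toy training runs: smooth 2-channel x and
# an exactly invertible linear map for y.
make_toy_samples <- function(n = 8, len = 64, seed = 5) {
  cyclepw:::with_seed(seed, lapply(seq_len(n), function(i) {
    t <- seq(0, 2 * pi, length.out = len)
    x <- rbind(0.7 * sin(t * runif(1, 1, 3) + runif(1, 0, pi)),
               0.7 * cos(t * runif(1, 1, 3) + runif(1, 0, pi)))
    list(subject_id = sprintf("toy%02d", i), x = x,
         y = 0.8 * x[2:1, , drop = FALSE], pulse_len_target = len)
  }))
}
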