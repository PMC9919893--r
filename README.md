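# cyclepw

Central arterial dynamics from peripheral blood-pressure waveforms, in R.

Increased aortic stiffness is a major cardiovascular risk factor, but the
signals that quantify it directly — central (abdominal aortic) pressure and
luminal area over the cardiac cycle — require invasive measurement. This
package learns a mapping from the two peripheral pressure waveforms that
*are* routinely accessible (brachial and radial) to the central
pressure–area pair, using a one-dimensional CycleGAN, and then evaluates
central stiffness from the reconstruction: the pressure–strain hysteresis
loop and its elastic modulus.

**Who it is for:** researchers working with virtual (simulated) pulse-wave
databases who want a fully reproducible, dependency-light reference
implementation of GAN-based waveform domain transfer plus the downstream
stiffness analysis — including a synthetic cohort generator with known
ground truth, so the entire pipeline is testable without any data download.

## The model

Domain *X* holds 2-channel peripheral samples (brachial, radial pressure);
domain *Y* holds 2-channel central samples (abdominal pressure, abdominal
area). Two GRU-based generators map G<sub>xy</sub>: X → Y and
G<sub>yx</sub>: Y → X; two convolutional discriminators D<sub>x</sub>,
D<sub>y</sub> judge realism per domain. The training objective is

&nbsp;&nbsp;&nbsp;&nbsp;L = L<sub>GAN</sub>(G<sub>xy</sub>, D<sub>y</sub>) +
L<sub>GAN</sub>(G<sub>yx</sub>, D<sub>x</sub>) +
λ<sub>cyc</sub> · [ E‖G<sub>yx</sub>(G<sub>xy</sub>(x)) − x‖₁ +
E‖G<sub>xy</sub>(G<sub>yx</sub>(y)) − y‖₁ ]

with L<sub>GAN</sub> either the least-squares (LSGAN) or the Wasserstein
gradient-penalty (WGAN-GP, λ<sub>GP</sub> = 10) adversarial loss. Networks,
backpropagation (GRU time loops in C++/Armadillo) and Adam are implemented
in the package; every analytic gradient is verified against finite
differences in the test suite.

Stiffness is read off a reconstructed central pair as the pressure–strain
elastic modulus: with diameter D = 2√(A/π) and strain
ε = 100·(D − D<sub>ref</sub>)/D<sub>ref</sub> (diastolic reference), the
modulus is the least-squares slope

&nbsp;&nbsp;&nbsp;&nbsp;β̂ = Σ(ε<sub>j</sub> − ε̄)(P<sub>j</sub> − P̄) / Σ(ε<sub>j</sub> − ε̄)²&nbsp;&nbsp;[mmHg/%],

computed on the first completed pulse of each signal. Cohort-level reports
give waveform RMSE (mean ± SD), modulus mean error and mean absolute
percentage error, and Bland–Altman limits of agreement for SBP, DBP and
the diameter extremes.

## Worked example

A smoke-scale run end to end (16 synthetic subjects, a small generator,
60 epochs — a few seconds of training):

```r
library(cyclepw)

## 1. a synthetic cohort of 16 virtual subjects (500 Hz, known stiffness)
cohort_cfg <- synthetic_config(n_subjects = 16, seed = 42)
sc <- synth_cohort(cohort_cfg)
sc$cohort
#> <cohort> role=full, 16 subjects
head(sc$truth[, c("subject_id", "e_true", "eta_true", "pp")], 3)
#>   subject_id   e_true   eta_true       pp
#> 1  synth0001 4.727294 0.13733185 30.00000
#> 2  synth0002 4.539843 0.06030265 31.24880
#> 3  synth0003 5.500748 0.18248594 36.50722

## 2. split, train a small CycleGAN for a short desk run
sp <- split_cohort(sc$cohort, test_fraction = 0.25, seed = 1)
cfg <- train_config("lsgan", g_gru = 16, d_l1 = 4, lambda_cyc = 5,
                    epochs = 60, batch_size = 6, seed = 1)
full_conv <- cohort(lapply(sc$cohort$records, convert_area_to_cm2), "full")
model <- train_cyclegan(sp$train, cfg, window = window_spec(full_conv, 256))

## 3. evaluate the peripheral-to-central generator on held-out subjects
evaluate(model, sp$test)
#> <eval_report> 4 subjects (0 excluded)
#>   Pressure RMSE [mmHg]   : 19.29 +- 4.44
#>   Area RMSE [cm^2]       : 0.378 +- 0.333
#>   E_P-eps ME [mmHg/%]    : 7.39 +- 0.68
#>   E_P-eps MAPE [%]       : 81.45 +- 1.85
#>   Bland-Altman sbp       : mean 20.530, LOA [8.289, 32.770]
#>   Bland-Altman dbp       : mean -27.896, LOA [-42.375, -13.417]
#>   Bland-Altman d_max     : mean 0.140, LOA [-0.158, 0.438]
#>   Bland-Altman d_min     : mean 0.044, LOA [-0.248, 0.337]
```

Sixty epochs of a 16-unit generator only roughs in the central waveform —
the pressure RMSE of ~19 mmHg and modulus MAPE of ~81% say "mostly the
cohort average, little subject conditioning yet", and that is the honest
reading of a smoke run. The pipeline around the model, in contrast, is
exact: evaluating the identity oracle (ŷ := y) through the same
preprocessing, inversion and pulse analysis gives strict zeros,

```r
ev0 <- evaluate(model, sp$test, identity_model = TRUE)
c(rmse = unname(ev0$rmse_pressure["mean"]), mape = ev0$mape_beta)
#> rmse mape
#>    0    0
```

and on noiseless, low-viscosity cohorts the slope estimator recovers the
synthetic generator's true modulus to well under 5% MAPE (see
`tests/testthat/test-acceptance.R`).

There is also a command-line interface over the same functions:

```sh
Rscript inst/cli/cyclepw.R synthesize --config synth.yaml --out arch/
Rscript inst/cli/cyclepw.R train --data arch/ --out run/ --loss lsgan \
        --g-gru 64 --d-l1 6 --lambda-cyc 5 --epochs 300 --seed 1
Rscript inst/cli/cyclepw.R evaluate --checkpoint run/checkpoint.rds \
        --data arch/ --out report/
```

## Package layout

| Area | Functions |
| --- | --- |
| Data I/O | `waveform_record`, `cohort`, `load_database`, `write_archive`, `split_cohort` |
| Synthetic cohorts | `synthetic_config`, `voigt_strain_response`, `synth_subject`, `synth_cohort` |
| Preprocessing | `convert_area_to_cm2`, `tile_pulse`, `resample_signal`, `window_spec`, `fit_minmax`, `normalize`, `build_dataset` |
| Model | `generator_spec`, `discriminator_spec`, `conv_output_length`, `build_models`, `generator_forward`, `discriminator_forward`, `discriminator_input_grad` |
| Losses/training | `lsgan_*`, `wgan_*`, `cycle_consistency_loss`, `gradient_penalty`, `train_config`, `training_step`, `fit_cyclegan`, `train_cyclegan`, `grid_combinations`, `grid_search` |
| Evaluation | `detect_first_pulse`, `area_to_diameter`, `strain_from_area`, `pe_modulus`, `loop_area`, `pulse_rmse`, `beta_errors`, `bland_altman`, `evaluate`, `predict`, `write_eval_report` |
| CLI | `cmd_synthesize`, `cmd_train`, `cmd_evaluate`, `cli_main` |

The methods vignette (`vignettes/central-waveform-transfer.Rmd`) documents
the model assumptions, the synthetic data design and every numerical
decision in detail.
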