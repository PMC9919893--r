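---
title: "Mapping peripheral pressure waveforms to central pressure–area dynamics"
author: "cyclepw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping peripheral pressure waveforms to central pressure–area dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Aortic stiffness is a major cardiovascular risk factor, but the signals that
characterize it directly — central (abdominal aortic) pressure and luminal
area over the cardiac cycle — are only accessible invasively. What *is*
accessible are peripheral pressure waveforms at the brachial and radial
arteries. `cyclepw` learns a bidirectional mapping between the two domains
with a one-dimensional CycleGAN and then reads arterial stiffness off the
reconstructed central pair: the pressure–strain loop and its elastic modulus.

Throughout, domain $X$ holds 2-channel peripheral samples (brachial and
radial pressure) and domain $Y$ 2-channel central samples (abdominal aortic
pressure and area). Two generators map $G_{xy}: X \to Y$ and
$G_{yx}: Y \to X$; two discriminators $D_x$, $D_y$ judge realism in each
domain. Only $G_{xy}$ matters clinically; the rest of the machinery exists
to train it.

## The stiffness readout

Given a central pressure pulse $P_j$ and area pulse $A_j$ over one cardiac
cycle, the package derives the diameter $D_j = 2\sqrt{A_j/\pi}$ (circular
lumen), the strain in percent
$\varepsilon_j = 100\,(D_j - D_\mathrm{ref})/D_\mathrm{ref}$, and the
pressure–strain elastic modulus as the ordinary least-squares slope

$$\hat\beta \;=\; \frac{\sum_j (\varepsilon_j - \bar\varepsilon)(P_j - \bar P)}
                      {\sum_j (\varepsilon_j - \bar\varepsilon)^2}
\qquad [\mathrm{mmHg}/\%].$$

Two conventions had to be fixed that the usual presentation leaves open:

* **Strain reference.** $D_\mathrm{ref}$ is the per-pulse minimum
  (diastolic) diameter, so strain is non-negative over the pulse and the
  modulus carries units of mmHg per percent strain. Any constant shift of
  $\varepsilon$ leaves the slope unchanged; the choice of reference scales
  it only through $D_\mathrm{ref}$ itself, by under 2% for physiologic
  distensions.
* **Loop orientation.** The hysteresis-loop area is the signed shoelace
  area of the time-ordered $(\varepsilon_j, P_j)$ polygon, oriented so that
  a strain that *lags* pressure — the viscoelastic case — gives a positive
  area. Reversing traversal flips the sign.

Agreement statistics follow the same conventions: errors and Bland–Altman
differences are `true − estimated`, and limits of agreement are the mean
difference ± 1.96 sample standard deviations.

## The synthetic virtual-subject generator

The package is developed and tested against a synthetic cohort generator
(`synth_cohort()`) that emulates the structure of a virtual pulse-wave
database: per-subject multichannel records at 500 Hz with known ground
truth. Each subject is built as follows.

* **Central pressure.** One cycle is a raised-cosine systolic upstroke
  (30% of the period) followed by an exponential diastolic decay that
  returns exactly to diastolic pressure at the next foot, repeated over at
  least three beats. This reproduces the features the pipeline depends on —
  a sharp foot, a single systolic peak, periodicity — without claiming
  physiological fidelity of the fine shape.
* **Viscoelastic wall.** Strain follows a Voigt (spring–dashpot) model,
  $P - P_\mathrm{dia} = E\,\varepsilon + \eta\,\dot\varepsilon$, solved on
  the periodic steady state harmonic-by-harmonic:
  $\hat\varepsilon(\omega) = \hat P(\omega)/(E + i\omega\eta)$. This is
  exact for band-limited periodic forcing (each harmonic is scaled by
  $1/\sqrt{E^2+\omega^2\eta^2}$ and delayed by $\arctan(\omega\eta/E)$),
  avoids any integration-scheme phase error, and yields an analytically
  known modulus: over a full cycle $\operatorname{cov}(\varepsilon,
  \dot\varepsilon) = 0$, so the least-squares slope of $P$ on $\varepsilon$
  equals $E$ up to sampling effects. With $\eta > 0$ the strain lags the
  pressure and the loop area is strictly positive. The area signal is then
  $A = \pi\,(D_d (1 + \varepsilon/100))^2/4$ for a diastolic diameter
  $D_d$, stored in m² as a database deposit would provide it.
* **Peripheral transfer.** Brachial and radial pressures are delayed,
  amplitude-amplified copies of the central pulse
  ($P_\mathrm{per} = P_\mathrm{dia} + a\,(P_c(t - \tau) - P_\mathrm{dia})$,
  $a > 1$, distinct per site, radial more amplified and more delayed than
  brachial). Gain-plus-delay is the simplest transfer that preserves the
  key calibration fact — peripheral systolic pressure always exceeds
  central — while keeping the mapping invertible. A transmission-line model
  would add realism but nothing the learning problem needs.
* **Parameter couplings.** Default ranges are physiologic magnitudes:
  DBP 60–90 mmHg, pulse pressure 30–60 mmHg, heart rate 50–90 bpm,
  $D_d$ 1.2–2.2 cm, $E$ 4–12 mmHg/%, $\eta$ 0.02–0.2 mmHg·s/%. Draws are
  not mutually independent: pulse pressure, diastolic diameter and (inversely)
  peripheral amplification follow the stiffness draw with bounded uniform
  jitter, mimicking the stiffening phenotype (stiffer wall, higher pulse
  pressure, wider aorta, less peripheral amplification) found in real
  cohorts. The couplings matter for identifiability: with fully independent
  draws the area channel would carry subject information that no function
  of the peripheral pressures can recover, and the peripheral-to-central
  problem would be ill-posed by construction. All values still fall inside
  their configured ranges.
* **Noise.** Zero by default — the emulated database is noiseless — with an
  optional additive Gaussian term expressed as a fraction of each signal's
  pulse amplitude.

What the generator does *not* emulate: reflected-wave morphology from a
distributed arterial tree, beat-to-beat variability, pathological waveform
classes, or measurement artifacts. Tests passing on this cohort therefore
demonstrate the pipeline's internal correctness and the learnability of a
clean, well-posed transfer problem — not performance on real or
high-fidelity simulated data.

## Preprocessing and its exact inversion

Four steps, in order: (1) areas are converted from m² to cm² (guarded
against double conversion); (2) each subject's pulse is tiled periodically
at the source rate to a fixed window equal to the cohort-maximum pulse
duration; (3) a global min–max map to $[-1, 1]$ is applied — one range for
all three pressure channels and one for area, fitted on the training split
only; (4) the window is resampled from 500 Hz to 256 Hz.

Decisions worth recording:

* **Normalization scope.** Global per-magnitude (not per-channel, not
  per-signal) normalization preserves cross-channel calibration
  relationships — peripheral systolic above central systolic, pressure and
  area on commensurate scales — which per-signal scaling would destroy.
  Fitting on the training split only avoids leaking test-set ranges. The
  map is affine with no clipping; out-of-range test values simply map
  outside $[-1, 1]$ (the generators' tanh bounds outputs regardless).
* **Resampler.** Polyphase rational resampling at 64/125 with a
  Kaiser-windowed ($\beta = 12$, 10 sidelobe periods) sinc low-pass, group
  delay compensated, each polyphase branch normalized to unit DC gain so
  constants — and the offset of the affine normalization — pass through
  exactly. Tiled windows are resampled under periodic extension, which is
  exact for them and removes edge roll-off from the first pulse, the very
  segment evaluation uses.
* **Step order.** Tiling happens at the source rate and resampling last,
  mirroring the listed order; with periodic extension the tiling seam does
  not ring. Inverting the normalization (and the unit conversion) recovers
  the resampled physical signal to better than $10^{-6}$ relative error,
  which is what makes the identity-model evaluation exactly zero — the
  package's end-to-end self-check.

## Architecture

Generators are two stacked GRU layers (64 or 128 features) followed by a
per-timestep linear projection to 2 features and tanh. The recurrence is
unidirectional and causal, with state reset at each window; sequence length
is preserved, so $G_{yx}(G_{xy}(x))$ always has the shape of $x$.

Discriminators are five stacked 1-D convolutions (kernel 5, stride 2,
padding 1), channel count doubling from the first layer's 6 or 8, each
followed by normalization and LeakyReLU(0.2), then a linear projection of
the *flattened* final feature map to one score. Flattening (rather than
global pooling) pins the window length at build time; the package asserts
the flatten size $f \cdot 2^4 \cdot \ell_5(T)$ against the window
specification when models are built. The minimum window for five stride-2
layers is 63 samples (and the last feature length must be ≥ 2 for instance
normalization to be non-degenerate).

The normalization/head pairing is tied to the adversarial loss: batch
normalization + sigmoid for LSGAN, instance normalization + linear head for
the WGAN-GP critic. Initialization: small-gain (0.9) orthogonal recurrent
blocks, uniform $\pm 1/\sqrt{H}$ GRU input weights, N(0, 0.02) for
convolutional and linear weights.

## Losses and optimization

With $\tilde y = G_{xy}(x)$:

* LSGAN: discriminator $\tfrac12\mathbb E(D_y(y)-1)^2 +
  \tfrac12\mathbb E D_y(\tilde y)^2$; generator
  $\tfrac12\mathbb E(D_y(\tilde y)-1)^2$. One discriminator update per
  generator update, always.
* WGAN-GP: critic $\mathbb E D_y(\tilde y) - \mathbb E D_y(y) +
  \lambda_{GP}\,\mathbb E(\lVert\nabla_{\hat y} D_y(\hat y)\rVert_2 - 1)^2$
  with $\lambda_{GP} = 10$ and $\hat y = \delta y + (1-\delta)\tilde y$,
  $\delta \sim U[0,1]$ per sample; generator $-\mathbb E D_y(\tilde y)$.
  The min–min notation sometimes used for this objective is implemented as
  the standard adversarial game (critic minimizes the displayed loss, the
  generator its own), since a literal simultaneous minimization is
  degenerate. The critic runs `d_iters` ∈ {5, 15, 25} updates per generator
  update.
* Cycle consistency: per-element mean absolute error of both
  reconstructions, weighted by $\lambda_{cyc}$; averaging per element keeps
  $\lambda_{cyc}$ comparable across window lengths.

Optimization is Adam at learning rate $10^{-4}$ with betas (0.5, 0.999) —
the standard GAN setting — batch size 96 at full scale, 1750 epochs, no
schedule, no weight decay. Both generators are updated jointly on the sum
of their adversarial and cycle terms; discriminator updates see detached
fakes. All randomness (initialization, shuffling, $\delta$ draws) derives
from the configuration seed, so runs are bit-reproducible.

One numerical device deserves explanation. The networks' forward and
backward passes are hand-implemented (GRU time loops in C++, convolutions
via im2col on BLAS), and every gradient — including the critic's gradient
with respect to its *input*, which the gradient penalty needs — is exact
backpropagation, verified against central finite differences in the test
suite. The penalty's gradient with respect to the critic *parameters*,
however, is a second-order quantity (a derivative of a derivative). Rather
than hand-deriving a second backward pass through the convolution and
normalization stack, the package evaluates it as a central finite
difference of two ordinary backward passes along the analytic
input-gradient direction: for $P = \frac1B\sum_b (\lVert g_b\rVert-1)^2$
with $g_b = \nabla_v D(v_b)$,

$$\nabla_\theta P = \nabla_\theta \Big[\sum_b u_b^\top \nabla_v D(v_b)\Big]
 \approx \frac{\nabla_\theta \sum_b D(v_b + \epsilon u_b)
             - \nabla_\theta \sum_b D(v_b - \epsilon u_b)}{2\epsilon},$$

with $u_b$ held fixed. The $O(\epsilon^2)$ truncation error perturbs only
the critic's update direction (the test suite checks that a step along the
negative of this gradient reduces the penalty); the penalty *value* and the
Lipschitz diagnostic are exact.

## Evaluation protocol

Only $G_{xy}$ is evaluated. Predictions are inverted to physical units with
the stored normalization, and all metrics are computed on the **first
completed pulse** of each signal: pulse feet are local minima reached by a
descent (or followed by a rise) of at least 5% of the signal range, at
least 0.25 s apart; a series that descends into its end after a full-height
drop is treated as closing a cycle at the boundary — necessary because the
subject whose pulse defines the window holds exactly one cycle with no
second interior foot. Waveform RMSEs truncate both pulses to the shorter
length; the stiffness slope is computed on each signal's own complete
pulse; subjects whose estimate contains no detectable pulse are excluded
and counted, not imputed.

Cohort statistics: RMSE as mean ± SD over subjects; modulus error as
ME (mean of signed `true − estimated`) and MAPE, each with the SD of the
corresponding per-subject quantity; Bland–Altman summaries for SBP, DBP and
the maximum/minimum diameter.

## Desk-scale problem sizes

The package's own experiments run at desk scale: cohorts of 64 virtual
subjects (85/15 train/test split), heart rates 60–90 bpm so the fixed
window is about 256 samples at 256 Hz, LSGAN with $G_{GRU} = 64$,
$D_{l=1} = 6$, $\lambda_{cyc} = 5$, 300 epochs at batch size 16. The batch
size is deliberately smaller than the full-scale 96: with 54 training
subjects, batch 96 would collapse to one optimization step per epoch, and
16 gives the optimizer four updates per epoch while keeping the batch-norm
statistics of the LSGAN discriminators stable. The hyperparameter grid (2 losses × 2 generator sizes ×
2 discriminator sizes × 3 cycle weights, × 3 critic-iteration settings for
WGAN-GP only, 48 combinations) is enumerated by `grid_combinations()` and
exercised in miniature in the tests; ranking uses test-split pressure RMSE,
which — as the protocol defines no third split — lets selection see the
evaluation data. That leakage is flagged here rather than silently fixed.

## Known limitations

* A causal GRU cannot use future context, yet the central pulse *leads*
  the peripheral inputs; the first samples of a window are generated from
  almost no history, and evaluation on the first completed pulse probes
  exactly that region.
* LSGAN's sigmoid score head saturates once a discriminator dominates,
  shrinking the adversarial gradient; at desk scale the discriminators win
  early and most generator learning flows through the cycle term, which any
  invertible encoding satisfies — so small-cohort runs rough in waveform
  scale and shape but align the subject-level pairing only weakly. This is
  a property of the LSGAN pairing itself and is kept faithful to it.
* Batch normalization in the LSGAN discriminators uses batch statistics of
  each forward pass (real and fake batches normalized separately); no
  running statistics are kept, as the discriminators are never used for
  inference.
* The grid search retrains from scratch per combination; at full scale
  (48 × 1750 epochs) this is a cluster-sized computation and is not run in
  the package's tests.
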