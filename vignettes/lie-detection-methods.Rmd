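---
title: "Models and methods behind fnirsbluff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fnirsbluff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsbluff)
```

This vignette is the package's own account of its modelling choices: what
the synthetic-data generator emulates and what it deliberately does not,
how the optical and statistical stages are defined, which parameters
matter, and where the design was genuinely open.

## The measurement model

Continuous-wave fNIRS observes detected light intensity `I(k)` per channel
at two wavelengths. Incident intensity is unobservable, so the
optical-density change is referenced within the recording:

$$\Delta OD^{\lambda}(k) = -\ln\frac{I^{\lambda}(k)}{I_{\mathrm{ref}}^{\lambda}},$$

with $I_{\mathrm{ref}}$ the mean intensity over a baseline window — by
default the first card-arrangement phase `[0, 15) s`, configurable to the
whole-recording mean. Two consequences are load-bearing for the tests:
the conversion is invariant to any global rescaling of the detector gain,
and with the sign written as above a *decrease* in detected light (more
absorbing hemoglobin) yields a *positive* ΔOD and a positive ΔHbO during
activation, the physically standard convention.

Concentration changes follow from the modified Beer–Lambert law. With
emitter–detector distance $l$ (3 cm), differential path-length factors
$d^{\lambda}$ (6.63 at 640 nm, 2.765 at 910 nm, taken as ordered pairs),
and extinction coefficients $\alpha$:

$$\begin{pmatrix}\Delta c_{HbO}\\ \Delta c_{HbR}\end{pmatrix}
 = A^{-1}\begin{pmatrix}\Delta OD^{\lambda_1}\\ \Delta OD^{\lambda_2}\end{pmatrix},
 \qquad
 A = \begin{pmatrix}
 l\,d^{\lambda_1}\alpha^{\lambda_1}_{HbO} & l\,d^{\lambda_1}\alpha^{\lambda_1}_{HbR}\\
 l\,d^{\lambda_2}\alpha^{\lambda_2}_{HbO} & l\,d^{\lambda_2}\alpha^{\lambda_2}_{HbR}
 \end{pmatrix}.$$

The extinction coefficients are not universal constants of this analysis;
they come from a standard published compilation of hemoglobin spectra,
converted to base-e (µmol/L)⁻¹ cm⁻¹, and live in an editable CSV
(`inst/extdata/extinction_coefficients.csv`). Every quantitative guarantee
in the test suite is a *round-trip* property (forward model composed with
inversion is the identity), so results do not depend on the specific
table; only nonsingularity of `A` is required (checked at |det| > 1e−12).

## What the simulator emulates

`simulate_experiment()` generates the full experiment: 10 subjects, 20
contiguous 30 s sessions (15 s arrange / 5 s claim / 10 s response), 12
channels × 2 wavelengths at 3.8 Hz, ending at 600 s per subject.

**Labels.** Sessions are lies with probability `lie_fraction = 0.35`
(roughly the prevalence the card deck induces); any subject drawn with
fewer than `min_lies = 4` lies has randomly chosen truth sessions flipped
until the minimum holds, because the deck's unmatched cards force at least
four lies. Pure redrawing cannot implement this constraint — at
`lie_fraction = 0` it would never terminate — so top-up flipping is used,
which also makes the degenerate configuration well-defined (exactly four
lies).

**Event responses.** Each claim convolves a canonical double-gamma
hemodynamic response (gamma densities peaking at 6 s and 16 s, undershoot
ratio 1/6) with a 5 s boxcar, normalized to unit peak so amplitudes are
stated directly in µmol/L: `amp_lie_uM = 1.2` versus
`amp_truth_uM = 0.6`, reflecting the stronger prefrontal response to
deception. ΔHbR is −1/3 of the ΔHbO event component. The response is
identical across channels: the analysis averages all 12 channels, so
inter-channel spatial structure would be invisible downstream, and
modelling it would only slow the simulator.

**Noise**, injected in concentration space so the forward model stays
analytically invertible:

| component | default | frequency | structure |
|---|---|---|---|
| cardiac | 0.30 µM | 1.1 Hz | systemic, coherent across channels |
| respiration | 0.15 µM | 0.3 Hz | systemic, coherent |
| Mayer waves | 0.10 µM | 0.1 Hz | systemic, coherent |
| drift | sd 4e−4 µM/s | — | linear, independent per channel |
| white | sd 0.30 µM | — | independent per channel and sample |

Two structural choices deserve their rationale. First, the oscillations
are *coherent across channels* (one random phase per subject and
component): heartbeat, breathing and vasomotion are global physiology, and
making them independent per channel would let the 12-channel average
suppress them by √12 — an unrealistically easy problem. Second, each
oscillation's phase performs a random walk
(`noise_phase_sd = 0.3` rad/√s). This models the natural wander of heart
and respiratory rate, and it removes a degeneracy of fixed-frequency
sinusoids: the 30 s session length is an exact multiple of all three
nominal periods (0.909, 3.33 and 10 s), so without phase wander every
session would sample the oscillations at identical phase and they would
contribute *no trial-to-trial variance at all*. Shot noise at the detector
is approximated by the white concentration term.

The free noise amplitudes were set so that the default end-to-end pipeline
lands in the 80–90% accuracy band typical of two-feature HbO lie/truth
classification (the M3 network averages ~90% test accuracy over five
independent runs); the lie/truth amplitudes and the white-noise level were
fixed first and not revisited.

**What is not emulated** — and therefore what passing tests cannot show
about real data: motion artifacts and optode-contact changes, subject-
and trial-level response variability (amplitudes are deterministic given
the label), scalp/skull partial-volume effects, spatial channel structure,
and the excluded-subject behavior of real cohorts. The generator
demonstrates that the *pipeline* is correct and well-calibrated, not that
the effect size in any human population matches its defaults.

## Preprocessing

The 0.15 Hz second-order low-pass is realized as a Butterworth IIR design.
Whether the original analysis filtered causally or with zero phase is not
stated anywhere; both are provided, with zero-phase (forward–backward) the
default so that claim-window features are not delayed by the filter's
group delay. The forward–backward pass runs on an odd-reflection extension
of the series (10 cycles of the cutoff period per edge) so start-up
transients decay inside the padding; without this, edge transients of the
plain two-pass filter corrupt the first sessions. DC gain is exactly 1 and
the effective magnitude response is squared, i.e. ~0.988 at 0.05 Hz and
~2e−4 at 1.0 Hz at the default rate.

Channel averaging happens after filtering and before feature extraction.
Claim windows are half-open `[onset, onset + 5 s)` on the acquisition
grid — half-open so concatenated windows never double-count a boundary
sample — giving 19 samples at 3.8 Hz.

## Features

SM is the arithmetic mean and SS the ordinary-least-squares slope (per
second) of claim-window HbO. OLS is the convention for "signal slope" in
the fNIRS feature literature; both are linear functionals of the window.
Whether features should be computed per channel and then averaged, or on
the channel-averaged signal, is an open reading; since averaging and both
functionals are linear, the two orders agree exactly for SM and SS, and
the channel-averaged signal is used. The feature table is *not*
standardized by default. A `zscore` switch exists because KNN and
kernel SVMs are scale-sensitive — with raw micromolar features and unit
box constraint the linear SVM visibly underfits (it sits near the
majority-class rate in the default pipeline), which is retained as an
honest property of unscaled features rather than silently corrected.

## The networks

M1 (`2-10-10-8-5-2`), M2 (`2-8-8-4-4-2`) and M3 (`2-6-8-6-2`) are fully
connected ReLU networks with a two-way softmax head, implemented from
scratch (forward pass, analytic backpropagation, Adam) rather than via a
framework, because they are the package's core subject. Weights start
Kaiming-uniform (`U[−√(6/fan_in), +√(6/fan_in)]`, variance `2/fan_in`),
biases at zero.

The architecture family is described as having four hidden layers, yet
M3's printed width sequence `2→6→8→6→2` contains three. Both readings are
selectable — `mlp_spec("m3")` is the literal three-hidden-layer sequence
(default), `mlp_spec("m3_wide")` the four-layer `2-6-8-8-6-2` variant —
and no attempt is made to guess which was meant.

Loss, optimizer and schedule are the de-facto defaults of small-network
practice: multinomial cross-entropy, Adam at 1e−3 with moment decays
0.9/0.999, batch 16, exactly 50 epochs, no early stopping (final-epoch
weights kept), five independently seeded repetitions for repeated
evaluation. One conditioning detail matters: the networks standardize
their inputs internally (training mean/sd stored in the model and
re-applied at prediction). Claim-window features live at ~0.1 µmol/L,
two orders of magnitude below the unit scale that Kaiming-initialized
weights and a 1e−3 step size assume; without conditioning, 50 epochs of
Adam cannot move the weights far enough and the networks plateau near the
majority class. Standardizing inside the model keeps the stated
hyperparameters effective while leaving the feature table untouched.

Baseline hyperparameters mirror common desktop-toolbox presets: KNN with
`k = 5`; a "simple" tree capped at depth 2 and a "complex" tree grown
effectively unpruned (`cp = 0`, depth 30) — the toolbox presets cap the
*number of splits* (4 and 100) which rpart cannot do directly, so depth
caps are the nearest equivalent; SVMs with box constraint 1 and the exact
inhomogeneous polynomial kernel `(xᵀy + 1)^ρ` (`gamma = 1`, `coef0 = 1`,
no internal rescaling). The test suite verifies the kernel by expanding
the fitted decision function over the support vectors by hand.

## Evaluation

The positive class is *lie* throughout — the detection target. ROC curves
sweep a threshold over every distinct score with ties grouped at a single
threshold; trapezoidal AUC then equals the probability that a random lie
outscores a random truth with ties counting ½ (the Mann–Whitney identity),
which the tests check against exhaustive pair enumeration. The 60/20/20
split is stratified by label — at 35% lie prevalence an unstratified
40-trial test set is too unstable — with cumulative-fraction rounding so
200 rows give exactly 120/40/40. LOSO folds hold out one subject entirely.

**Null calibration.** The chance-level check (no amplitude difference
between lies and truths) runs on a *balanced* design: `lie_fraction =
0.5`, equal amplitudes. Under the default 35% prevalence a degenerate
predictor that always answers "truth" scores ~65%, so an interval around
50% is only a meaningful null band when chance itself is 50%. The check
compares every classifier's LOSO accuracy, pooled over all 200 held-out
trials, against the 95% binomial interval around 50% (±6.9 points at
n = 200). Two caveats are worth recording: held-out trials within a fold
share a trained model, so the true sampling variance slightly exceeds
binomial; and with nine classifiers checked simultaneously, the *maximum*
deviation across classifiers will occasionally leave the interval for a
perfectly null pipeline (the acceptance script therefore also reports the
mean absolute deviation, the stabler summary).

## Problem sizes and runtime choices

The test suite and the acceptance script run the full default experiment
(10 × 20 trials) wherever a claim depends on it: the effect-size check
averages five complete simulate–train–test repetitions, the null check
runs one full LOSO per classifier, and unit tests use 1–4 subjects with
3–10 sessions. These sizes make the whole suite complete in well under a
minute while keeping every statistical check at the n its interval
arithmetic assumes. Filter gains are measured on 8192-sample tones;
the ROC/AUC oracle comparison uses 100 random instances of up to 50
scores with heavy ties.

## Known limitations

- The generator's effect size is an assumption, not an estimate; nothing
  here validates the magnitude of deception-related HbO responses in
  humans.
- HbR is simulated and converted but never classified; HbO-only analysis
  is a deliberate scope bound.
- The linear SVM's weakness on raw micromolar features is a property of
  the chosen (unscaled) feature convention, not of linear SVMs.
- `class::knn` breaks exact distance ties randomly; with continuous
  features ties have probability zero, but byte-level reproducibility of
  KNN predictions assumes untied distances.
- The intensity reader infers the sampling rate from timestamp spacing;
  irregular sampling is not supported.
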