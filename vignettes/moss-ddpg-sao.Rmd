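---
title: "Single-step sensorless adaptive optics: model, agent and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step sensorless adaptive optics: model, agent and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A confocal scanning laser ophthalmoscope (SLO) images the retina of small
animals through the optics of the eye itself. The eye contributes wavefront
aberrations that blur the image, and in a *sensorless* adaptive-optics (SAO)
system there is no wavefront sensor to measure them: the only available
signal is the image, summarized by a sharpness metric. Correction therefore
becomes an optimization problem — find the deformable-mirror (DM) Zernike
coefficients that maximize the metric — and the practical cost of any method
is the number of images it must acquire, because each acquisition takes
time during which the animal's eye moves, blinks and bleaches.

This package implements, entirely in silico, a single-step solution: an
LSTM actor-critic trained by deterministic policy gradient that maps one
fixed set of `2N+1` sharpness observations directly to the `N` correction
coefficients. It also implements the two model-based comparators used to
judge it — per-mode parabolic maximization from the same `2N+1`
observations, and the three-round Zernike-mode hill-climbing (ZMHC)
coordinate search — and a Monte Carlo harness that scores all methods by
residual RMS wavefront error.

## Image formation model

The wavefront error is a Noll-indexed Zernike expansion
`W(x, y) = sum_i c_i Z_i(x, y)` over modes 4..15 (defocus through the
fourth radial order); piston, tip and tilt are excluded because a scanned
confocal image is insensitive to piston and merely translated by tip/tilt.
Modes are Noll-normalized, so the pupil RMS of the wavefront equals the
Euclidean norm of the coefficient vector — which is why the benchmark's
residual score `sqrt(sum((c + c_corr)^2))` is an RMS wavefront error.

The intensity PSF is `h = |FFT{A exp(-j phi)}|^2` on a zero-padded pupil
grid. The confocal system is double-pass: illumination and detection each
traverse the same aberrated path, and the detection channel collects light
through a multimode fiber several Airy-disk diameters (ADD) wide. The
effective PSF is `hs = h1 * (f (*) h2)` with `f` a uniform disk of the
fiber's diameter and `(*)` circular convolution; with a point detector this
reduces to `hs = h1 * h2`. The detected image is `I = hs (*) r_f` for a
sample fluorescence profile `r_f`, and the sharpness metric is
`m = sum_p I_p^2`. All convolutions are FFT-based and circular; the
package exploits Parseval's identity to score the metric without forming
the image, and the equality of the two routes is a unit test.

### Coefficient units and the DM gain

Zernike coefficients are expressed in *commanded micrometres of the DM*,
the unit in which an instrument operator works. The conversion from a
commanded micrometre to optical path difference at the pupil is an
instrument constant that is never printed for any real system: it folds
together pupil demagnification (here a 10:1 telescope chain),
actuator-influence-function normalization, and reflection geometry. The
simulator makes it explicit as `dm_gain` (default 0.28), calibrated once so
the simulated metric-coefficient response — and with it the accuracy of
the model-based parabolic benchmark under the B and C aberration
configurations — matches the scale reported for the physical instrument.
With `dm_gain = 1` the same code gives the textbook "one micrometre of
coefficient is one micrometre of OPD" response, which is far more
aberration-sensitive than any real confocal channel we know of.

Two further detector-side knobs exist: `fiber_diameter` (default 4 ADD;
real instruments of this class quote only "several" Airy disks) and
`background`, a constant detected floor expressed relative to the
diffraction-limited mean image intensity (default 0, i.e. off) that can
emulate stray light and out-of-focus fluorescence when robustness to a
compressed metric range is of interest.

### Sampling choices

The default pupil is 128 px across, zero-padded 2x before the FFT (the
Airy core then spans ~5 px), and the effective PSF is cropped to a central
33 x 33 kernel before convolution with a 128 x 128 sample. These sizes keep
one image formation at a few milliseconds on one CPU core so that
1,000-trial benchmarks and full training runs are desk-scale; pupil
discretization keeps Noll orthonormality within about 1% (about 0.4% at a
256-px pupil, which the test suite checks at that resolution). The
half-pixel edge convention (coordinates scaled by `pupil_radius + 0.5`)
noticeably reduces discretization error at small pupils.

### Synthetic samples

`generate_sample_image()` provides three reproducible texture families
standing in for the bench samples: `fibers` (smooth random curves with two
stroke widths, like lens tissue), `cells` (a jittered hexagonal mosaic of
soft disks, like a ganglion-cell layer) and `mixed` (a field of view
containing both, in diagonal quadrants). They emulate the *spectral*
character of real samples well enough for the metric to behave
consistently across them — the benchmark harness checks that parabolic
accuracy varies by less than 15% across the three kinds — but they carry
no biological structure, no photon noise and no motion, so passing tests
here say nothing about robustness to those effects on a real instrument.

## Aberration statistics

Hidden aberrations are drawn per mode, in micrometres:

| config | distribution | limit |
|---|---|---|
| A / train_uniform | uniform | ±0.15 |
| B | Gaussian, SD 0.06 | ±0.15 |
| C | Gaussian, SD 0.08 / 0.06 / 0.04 by radial order | ±0.2 |

Higher-order modes (Noll 16..28) always receive Gaussian noise with SD
0.01 um limited to ±0.025 um; they corrupt every observation but are not
corrected and are excluded from the residual score. Limits are enforced by
resampling until inside, i.e. an exact truncated normal: clamping to the
boundary would put probability atoms at the limits, whereas the quoted
"98.76% do not exceed the limit" is a plain Gaussian tail statement. The
truncation is not cosmetic — at 2.5 SD it shrinks the realized SD by 4.5%,
which the distribution tests account for explicitly.

## The environment and the agent

An episode hides one aberration draw and acquires `2N+1` metrics: the
unbiased wavefront, then `-b` and `+b` probes of each mode in ascending
Noll order, with `b = 0.5` um by default. The metric column is normalized
by its maximum, and each row carries a `{-1, 0, +1}` code marking the
probed mode, giving the `(2N+1) x (N+1)` observation matrix. The episode
ends after a single corrective action; the reward is the corrected metric
divided by the metric of the zero-target-aberration wavefront (an
`baseline_metric` override supports the instrument-style benchmark
denominator). Because the row order is fixed, any stable order would do —
the agent learns whatever order it is trained with.

The actor reads the observation matrix row by row with a single-layer
LSTM and maps the final hidden state through a `tanh` head scaled by
`action_limit` (default 0.2 um — deliberately above the 0.15 um training
limit so that extrapolation to configuration C's ±0.2 um range is not
clipped by the head). The critic encodes the same sequence, concatenates
the (limit-scaled) action to the final hidden state and predicts the
reward through one rectified hidden layer. There are no target networks:
each episode is one step, the reward is immediate, and there is no future
return to bootstrap — the critic is a plain regression onto observed
rewards, which makes training markedly more stable than generic
actor-critic setups.

Exploration adds zero-mean Gaussian noise to the actor output, with SD
annealed linearly from `exploration_sd0` (default 0.05 um) to exactly zero
at the final episode. Each episode evaluates `k` noise profiles (default
15) against the same hidden aberration, multiplying the transition yield
per acquisition batch; during the warm-up phase (default the first 10% of
episodes) the networks stay frozen and only this exploration fills the
replay buffer. After warm-up every episode runs several critic
regressions and a smaller number of policy-gradient steps
(`updates_per_episode` / `actor_updates_per_episode`); the critic needs
roughly an order of magnitude more gradient steps than episodes before
its action-gradient becomes informative, which is why the defaults
decouple the two counts. The LSTM forward/backward core is compiled
(RcppArmadillo) with the plain-R implementation retained as a reference
oracle; a unit test checks the two routes agree to machine precision.

## Baselines

*Parabolic maximization* fits, per mode, the parabola through
`(-b, M-)`, `(0, M0)`, `(+b, M+)` and drives the mirror to its vertex,
`c_corr = b (M+ - M-) / (2 (2 M0 - M+ - M-))`. The sign convention is
fixed by algebra: on a concave metric peaked where the probe cancels a
hidden aberration `a`, the vertex abscissa is `-a`, so the *correction* is
the vertex itself while the raw aberration *estimate* `+a` is exposed as
an attribute. Degenerate (flat or convex) observation triples are flagged
and left uncorrected, and vertex magnitudes are clamped to a working
limit. The method is exact on separable quadratic metrics — a property
the tests verify on an analytic quadratic environment — and its bias
value matters: 0.2 um performs best here, with 0.5 um available for the
matched-observation comparison against the agent.

*ZMHC* scans each mode over 11 uniformly spaced values centred on the
current estimate, keeping the argmax (first on ties), over three rounds
with half-widths 0.2, 0.1, 0.05 um: 132 images per round, 396 in total,
and a final resolution of 0.01 um per coefficient.

## Benchmarks, problem sizes and limitations

`run_benchmark()` draws all aberrations up front from the seed, so
competing methods face bitwise-identical sequences. It reports mean and SD
of the residual RMS wavefront error and the fraction of trials below the
Marechal criterion `lambda/14 = 0.0349` um, both as an empirical count and
as the Gaussian approximation `Phi((threshold - mean)/sd)` (the latter
matches how such fractions are usually quoted from mean and SD alone).

The package's own test and acceptance runs use these problem sizes, chosen
to keep a complete verification pass desk-scale: the parabolic benchmarks
run 1,000 trials per configuration on the default 128-px simulator in the
acceptance script (and reduced trial counts inside the test suite); the
agent's parameter-recovery experiment is a scaled-down setting with N = 3
modes (4..6), a 64-px sample and pupil, 3,000 episodes with k = 10, LSTM
width 48 and batch 96; transfer learning fine-tunes that agent for 1,000
episodes with k = 7 on a perturbed simulator (fiber 4 to 5 ADD plus a fixed
0.03 um astigmatism offset) standing in for a real instrument. The full
12-mode, 40,000-episode configuration of `scripts/train_full.R` reproduces
the full-scale experiment but is a multi-day single-CPU job and is not part
of any automated run.

Known limitations: the simulator is noise-free (a multiplicative metric
noise option exists but defaults to off), monochromatic, and static per
episode; the fiber is a uniform disk; illumination and detection share one
aberration map (the double-pass assumption — per-path aberrations are not
modelled); `dm_gain`, the fiber diameter and the sample textures are
calibration surrogates for unprinted instrument constants, so absolute
benchmark numbers carry that calibration uncertainty even where relative
comparisons between methods are robust to it.
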