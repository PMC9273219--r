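---
title: "Quantifying the breakdown of C. elegans neural dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the breakdown of C. elegans neural dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormdyn)
```

# The scientific problem

Whole-brain calcium imaging in immobilized *C. elegans* captures the
simultaneous activity of ~120 head-region neurons (GCaMP6s fluorescence, 2
volumes/s for 10 minutes). In young adults this population organizes into
smoothly cycling system states: groups of co-active neurons, strongly
anti-correlated opposing groups, and low-dimensional trajectories that loop
through a well-defined activity manifold. With age this organization
degrades along several measurable axes: spectral content drifts toward
higher frequencies, strongly anti-correlated neuron pairs become rare while
positively correlated pairs persist (a selective loss of inhibition-like
coupling), state-space trajectories become erratic, and animals enter
sleep-like bouts of global neural quiescence.

`wormdyn` implements the full metric pipeline for quantifying these
phenotypes from trace matrices, plus a seeded synthetic generator that
emulates the statistical structure of such recordings so every stage can be
validated against known ground truth without any imaging data.

# Normalization

Raw per-neuron fluorescence is converted to dF/F0 = (F - F0)/F0. Two
baseline dialects are provided, matching the two acquisition settings:

* **lowest-percentile** (population recordings): F0 is the mean of the
  lowest 1% of that neuron's samples (`ceiling(0.01 * frames)` values, at
  least one). This anchors dF/F0 at each neuron's quiet level even when the
  neuron is active much of the trial.
* **trace-mean** (single-neuron AVA recordings): F0 is the trace mean.

Both are invariant to multiplying a trace by a positive constant, and
dF/F0 together with F0 reconstructs the raw trace to machine precision.
A caveat worth knowing: with additive noise of standard deviation s, the
lowest-1% baseline sits roughly 2.7 s below the quiet level, shifting all
dF/F0 values up by about that amount. This matters when measurement noise
approaches the dynamic range — the synthetic presets keep noise at a
realistic few percent of signal so relative thresholds behave as intended.

# Transition kinetics (bistable neurons)

AVA-style command interneurons show binary ON/OFF dynamics. Candidate
transitions are found by a hysteresis detector (up-cross at 70% of the
dynamic range after being below 30%, and vice versa, on a lightly smoothed
copy), replacing by-eye annotation with a reproducible rule. Each candidate
window is then fit with the four-parameter sigmoid

$$F(t) = b + \tfrac{a}{2}\left(1 + s\,\tanh\!\frac{t - t_0}{\tau}\right),
\qquad s = \pm 1,$$

and the 5-to-95% transition time follows analytically:
$t_{5\to95} = 2\tau\,\mathrm{atanh}(0.9) \approx 2.944\,\tau$. Computing
the crossing points from the fitted curve rather than the raw data removes
the noise dependence of threshold timing. Fits initialize $t_0$ at the
extreme-derivative frame of a ~1 s-smoothed copy (raw frame-to-frame
differences are noise-dominated) and $\tau$ from the smoothed 25-75%
crossing span around it, with window/10 and one frame as fallback starts;
the best valid fit by residual wins, and a fit is flagged unusable when
$\tau$ falls outside (half a frame, window length).

Bouts pair each ON onset (fitted 5% crossing) with the next OFF onset
(fitted 95% crossing). Duty ratio is summed bout time over trace time; a
trailing unpaired ON extends to the trace end and is flagged. The amplitude
entering the 5%/95% points is the fitted plateau amplitude; the raw maximum
is a config alternative that is more sensitive to drifting plateaus.

# Spectral analysis

Each neuron's PSD is the one-sided periodogram of the full mean-removed
trace: no Welch segmentation and no taper, so the frequency resolution of a
10-minute trial is 1/600 Hz and the estimator is exactly deterministic. The
DC bin is excluded (mean removal makes it meaningless and it would otherwise
dominate quantile-based summaries). The scaling satisfies Parseval: total
power times bin width equals the trace variance (denominator n).

Per-worm PSDs average the 120 per-neuron PSDs; condition means average
worms and are rescaled to unit total power, removing age-dependent
differences in absolute indicator brightness. The **40% spectral edge** is
the smallest grid frequency below which at least 40% of total power
resides, reported without interpolation (bin-resolved). Faster dynamics
move the edge up.

PSDs default to dF/F0 traces; a switch computes them on TV differentials
instead. The differential route whitens slow components and is retained
for sensitivity analyses; the trace route is the default reading of
"activity array" spectra.

# Total-variation regularized differentiation

Pairwise correlation analysis runs on time *differentials* of dF/F0, which
suppress co-drift and emphasize co-activation. Naive finite differences
amplify noise by sqrt(2)/dt, so the derivative u is estimated variationally:

$$J(u) = \tfrac{\Delta t}{2}\,\bigl\lVert \textstyle\int u - f \bigr\rVert^2
 + \alpha \sum_j \phi(u_{j+1} - u_j),$$

where the antiderivative is the cumulative-sum quadrature and $\phi$ is a
smoothed absolute value. The solver is a lagged-diffusivity fixed point
with conjugate-gradient inner iterations; the integration operator and its
adjoint are applied as running sums, so cost is linear per iteration
(compiled code). Defaults: $\alpha = 0.05$ (per-second units), 100 outer
iterations, convergence declared at a relative step below 1e-6;
non-convergence sets a flag and warns rather than failing.

The smoothing scale is a genuine design decision. With essentially exact
absolute value ($\epsilon \to 0$) the estimator is pure TV and imposes a
piecewise-constant (staircase) prior on the derivative; on smooth
oscillatory calcium signals this leaves a bias floor of about 0.03 dF/F0/s
regardless of $\alpha$ — we verified this across eight noise seeds and two
sampling rates. The default $\phi(s) = \sqrt{s^2 + \epsilon^2}$ with
$\epsilon = 0.05$ (derivative units per frame step) penalizes sub-threshold
wiggles quadratically, like a Huber loss: smooth dynamics are denoised
without staircasing (noisy-sinusoid derivative RMSE ~0.017 against the
analytic derivative at noise sd 0.05), while genuine state transitions
produce derivative jumps far above $\epsilon$ and still receive the sharp
TV treatment. Ramps are recovered exactly, constants give identically zero,
and the operator commutes with negation to solver precision.

# Correlation structure

The 40 most dynamically active neurons (largest dF/F0 standard deviation;
ties to the lower index; ranking on the trace, not its differential) enter
the pairwise analysis; the full-120 variant is available as a robustness
check. All zero-lag Pearson coefficients between the TV differentials of
selected pairs form the condensed vector (780 pairs for 40 neurons).

The **negative/positive correlation proportions** are the fractions of
pairs strictly below -0.2 and strictly above +0.2; boundary values count in
neither tail. Pairs involving a zero-variance differential are excluded and
counted. Pooled per-condition histograms (40 bins over [-1, 1]) weight each
worm by its pair count. The aging signature is a collapse of the negative
proportion with the positive proportion roughly preserved.

# State-space trajectories

PCA treats neurons as variables and frames as observations, on per-neuron
mean-centered dF/F0 — no variance scaling and no score whitening, so score
amplitude retains physical meaning. Component signs are fixed by making
each loading's largest-magnitude entry positive, which removes the
arbitrary sign flip between runs/platforms.

Trajectory smoothness is measured by the angular change: at each frame,
the angle between the past and future displacement vectors over ±3 s
(6 frames at 2 Hz) of the k = 3 score-space trajectory. Straight motion
gives 0°, reversals 180°, and independent isotropic displacements (the
stochastic limit) the sin(θ) law with mean 90°. Zero-norm displacements
(e.g. during quiescence) yield undefined angles that are excluded and
counted, rather than silently binned at 0°. Angle histograms use 18 bins
of 10° and pool trials by concatenation. Both displacement windows use the
plotted 3-D trajectory by default; k is configurable, and the choice of
symmetric discrete displacements (not spline tangents) keeps the operator
deterministic and assumption-free.

The time-time recurrence map is the Euclidean distance between every pair
of frames in full neuron space, normalized by the trial's maximal distance
(all-equal trials yield an all-zero map and a degenerate flag).

# Global quiescence

For each trial, a high-activity reference is the mean over the top 25% of
frames of the frame-mean dF/F0 (the per-neuron-reference reading of this
rule is available behind a flag); the quiescence cutoff is one third of the
reference; a neuron is quiescent at a frame when strictly below the cutoff;
a frame is globally quiescent when strictly more than 70% of neurons are
quiescent. Because all three constants are relative, the classification is
scale-invariant. Time in quiescence is the mean of the global indicator.
Subset extraction picks one contiguous 700-frame window per trial — either
the window maximizing time in quiescence (earliest on ties) or the
earliest window with none — so the effect of quiescence on downstream
metrics can be isolated; the deterministic rules replace an unstated manual
segment choice.

# Group statistics

Each metric is compared across conditions by one-way ANOVA followed by
pairwise contrasts using the pooled residual variance, with Sidak
adjustment $p_{adj} = 1-(1-p)^m$ over the m contrasts actually performed
(m = 1 leaves p unchanged). Group summaries report mean ± SEM of per-worm
values; neuron-level values are never pooled across worms for group means.
The contrast set is an explicit argument, since which families of
comparisons are of interest depends on the experimental design.

# The synthetic generator

`generate_population()` builds a recording from mechanisms chosen so each
aging knob maps to one observable:

* a semi-Markov latent cycle of 4 states (Gamma-shape-2 dwells around
  `dwell_mean`; with probability `transition_stochasticity` the next state
  is drawn uniformly instead of following the cycle);
* an excitatory group driven by the envelope of the first half-cycle with
  state-tuned gains (uniform 0.5-1.5, amplitude scale 2 in dF/F0 units);
* an inhibition-coupled group whose drive mixes the *anti-phase* of that
  envelope (weight `inhibition_scale`) with an independent second latent
  cycle (weight 1 - `inhibition_scale`): at full scale the two groups are
  strongly anti-correlated; at zero the anti-correlation vanishes while
  within-group co-activation persists — the loss-of-inhibition phenotype
  expressed as a single dial;
* per-neuron private slow fluctuations (timescale tied to `dwell_mean`) so
  within-group correlations are strong but not degenerate and the
  state-space trajectory keeps moving between transitions;
* background neurons (the other 80) with modest tonic activity
  (`background_drive` = 0.3) interrupted by sparse dips, so their observed
  minima — hence their dF/F0 baselines — lie well below their awake level;
* a difference-of-exponentials calcium kernel (1 s rise, 4 s decay,
  unit DC gain) approximating slow GCaMP6s kinetics; a 60 s lead-in is
  simulated and discarded so frame 1 is in kernel and latent steady state;
* global quiescence bouts (Poisson arrivals at `quiescence_rate`,
  exponential durations around `quiescence_dwell`) gating the convolved
  signal down to 5% with a 2 s exponential entry/exit, emulating gradual
  sleep-bout onset; the planted truth marks frames where the gate is at or
  below 0.12, i.e. where the signal is deeply suppressed — bout entry takes
  a few seconds, so those early frames are genuinely not yet quiescent and
  are not planted as such;
* additive Gaussian measurement noise (`hf_noise_sd`), and conversion to
  raw fluorescence `baseline_f * (1 + dff)` floored at zero.

All randomness flows from one seed through an isolated RNG scope; the
caller's RNG state is untouched and identical seeds give bit-identical
recordings.

## Age presets

The presets are qualitative emulations — documented constants, not fits to
any measured data set:

| knob | day 1 (young) | day 9 (aged) | expressed phenotype |
|---|---|---|---|
| `dwell_mean` (s) | 20 | 4 | faster, less persistent states |
| `transition_stochasticity` | 0.1 | 0.7 | erratic trajectories |
| `inhibition_scale` | 1.0 | 0.2 | loss of anti-correlation |
| `hf_noise_sd` (dF/F0) | 0.03 | 0.11 | high-frequency power |
| `quiescence_rate` (bouts/min) | 0.02 | 0.9 | sleep-like bouts |
| `quiescence_dwell` (s) | 30 | 6 | — |

The day-9 bout process (0.9/min x ~6 s, with ~2 s smooth entry) puts a few
percent of trial time in measured quiescence against essentially none for
day 1 — the right direction and order of magnitude for aged versus young
adults. Many short bouts rather than few long ones keep the seed-to-seed
variance of the quiescence load small, which in turn keeps the
quiescence-driven common-mode contribution to pairwise differential
correlations (a real phenomenon: concerted entry and exit transiently
co-activates everything) subordinate to ongoing dynamics — mirroring the
empirical observation that moderate quiescence does not measurably inflate
positive correlativity. Pushing the aged bout load toward ~10% of trial
time with long bouts makes that common mode dominate the differentials of
this generator's comparatively lean awake dynamics and inflates the
positive proportion, so the presets favor the stability of the
correlation signature over the exact quiescence percentage.

## What the generator does not emulate

Real recordings have graded, overlapping neuronal memberships across many
more behavioral states, photobleaching trends, motion residue, shot-noise
scaling with brightness, and bilateral neuron pairs with near-duplicate
signals. Passing the pipeline's tests on synthetic cohorts therefore
demonstrates correctness of the *metrics* under known ground truth and the
qualitative aging signature, not quantitative agreement with any real
data set.

# Problem sizes used in tests and the acceptance script

Synthetic cohorts use the full study geometry (120 neurons, 1200 frames at
2 Hz, 10 worms per preset in the acceptance script; fewer seeds in some
unit tests). The noisy tanh-recovery check uses 200 replicates in the
acceptance script and 60 in the default test suite; the inhibition-scale
monotonicity test uses 5 levels x 3 seeds at 5-minute trials. These sizes
put every Monte-Carlo estimate comfortably inside its tolerance band while
keeping the default suite quick.

# Known limitations

* The periodogram has the usual variance of an untapered estimator; the
  bin-resolved edge inherits it (one-bin granularity, 1/600 Hz).
* TV differentiation's Huberized penalty trades a small amount of edge
  sharpness for unbiased smooth-signal derivatives; heavily drifting
  baselines are the normalization's job, not the derivative's.
* The hysteresis detector assumes bistable traces with a meaningful
  dynamic range; "spikey" freely-moving dynamics are out of scope.
* `compare_groups` implements one-way ANOVA + Sidak only; repeated
  measures and mixed designs are out of scope.
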