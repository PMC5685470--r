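---
title: "Methods: reference-frame analysis of heading tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-frame analysis of heading tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refframe)
```

## The problem

Visual optic-flow signals enter the brain in an eye-centered (retinal)
coordinate frame; vestibular inertial signals are head-centered.  A neuron's
spatial reference frame can be diagnosed by measuring its heading tuning
curve while the animal fixates at different static eye positions: if the
tuning is eye-centered, the whole curve shifts with gaze; if head-centered,
it is gaze-invariant.  This package implements the standard analysis chain
for such experiments — displacement index, joint model fitting, pursuit
partial-shift analysis, gain fields, and heading-estimation behaviour —
together with a generator of synthetic trial tables in which the ground
truth is known, so every stage can be validated by parameter recovery.

## Displacement index

For a pair of tuning curves $R_i, R_j$ measured at eye positions $P_i, P_j$,
both curves are linearly interpolated on the circle at 1° resolution and
mean-subtracted, and the circular lag
$k^\* = \arg\max_k \operatorname{cov}[R_i(\theta), R_j(\theta + k)]$,
$k \in [-180°, 180°]$, is found by exhaustive search (computed via FFT; an
explicit brute-force oracle is kept in the test suite and asserted equal on
random instances).  The displacement index is $\mathrm{DI} = k^\*/(P_j -
P_i)$, oriented so that a tuning shift equal to the gaze displacement gives
+1 and no shift gives 0.  With three fixations (−20°, 0°, +20°), all pairs
of significantly tuned curves (p < 0.05, one-way ANOVA across headings)
contribute, and the pair DIs are averaged unweighted.  A 95% CI comes from
resampling repetitions with replacement within every (eye position ×
heading) cell, 1000 times by default; neurons are then categorised as
head-centered (CI covers 0 but not 1), eye-centered (1 but not 0),
intermediate (CI inside (0,1)) or unclassified.

Numerical choices worth knowing:

* **Circular shifting.** The lag search wraps around the circle rather than
  zero-padding; tuning is 360°-periodic, so wrap-around avoids edge
  artefacts.  Ties in the maximum are broken toward the smallest $|k|$,
  negative before positive — deterministic and conservative (biases toward
  "no shift").
* **Discretisation.** The 1° lag grid over a 20° gaze displacement limits
  DI resolution to 0.05 per pair.  Moreover, linear interpolation of curves
  sampled at 45° steps can move the argmax by ±1°: a true half-shift of 10°
  is recovered as 9° (DI 0.45, not 0.50).  This is a property of the
  published procedure itself, not of this implementation — the exhaustive
  oracle lands on the same lag — and it is why recovery tests use a ±0.05
  band.
* **Flat curves.** Zero-variance curves have no defined lag; they raise an
  error in the point estimate and are dropped (and counted) inside the
  bootstrap.  Bootstrap replicates reuse the eye positions selected by the
  point estimate rather than re-running the significance gate, so replicate
  DIs stay comparable.

## Joint wrapped-Gaussian models

Each tuning curve is modelled as a modified wrapped Gaussian
$$R(\theta) = A_1\!\left[e^{-2(1-\cos(\theta-\theta_p))/(\sigma^2\kappa)}
  + A_2\, e^{-2(1-\cos(\theta-\theta_p-180°))/\sigma^2}\right] + R_0,$$
with an optional second peak 180° out of phase ($A_2$) whose relative width
is set by $\kappa$ ($\kappa$ is placed in the first exponent's denominator;
the alternative reading of the typeset formula would make $\kappa$
redundant with $\sigma$ for single-peaked cells).  The three eye-position
curves are fit **simultaneously** with 16 free parameters: one shared peak
$\theta_0$ plus per-eye-position $(A_1, \sigma, \kappa, A_2, R_0)$.  The
eye-centered model places the peak at $\theta_0 + P$; the head-centered
model at $\theta_0$ throughout.  Fitting is bounded least squares
(L-BFGS-B with an analytic gradient), multi-started from each curve's best
heading and its antipode plus seeded random restarts (20 by default).
Bounds: $A_1 \in (0, 3\max r]$, $\sigma,\kappa \in [0.1, 10]$,
$A_2 \in [0,1]$, $R_0 \in [0, \max r]$ — wide enough not to bind for
realistic tuning, tight enough to keep the two peaks identifiable.

Model comparison uses partial correlations between the concatenated mean
rates and each model's predictions,
$R_e = (r_e - r_h r_{eh})/\sqrt{(1-r_h^2)(1-r_{eh}^2)}$ (and symmetrically
$R_h$), Fisher-transformed as $Z = \operatorname{atanh}(R)\sqrt{n-3}$ so
that the criterion $|Z_e - Z_h| \ge 1.645$ corresponds to one-tailed
p = 0.05 under the normal approximation.  The scaling by $\sqrt{n-3}$ is a
package decision: the source wording ("independent of the number of data
points") admits either reading, and the scaled form is the one for which
1.645 is a meaningful normal quantile.  The unscaled variant is available
(`fisher_z(..., scaled = FALSE)`).  Fits whose best model has
$r^2 < 0.6$ (squared Pearson correlation of fit vs data, boundary
inclusive) are excluded.  When the data equal one model's prediction
exactly the competing partial correlation is an algebraic 0/0; the limit
(0) is returned.

## Pursuit partial-shift analysis

Smooth pursuit rotates the eye continuously, distorting the retinal flow
field: a neuron that encodes the *resultant* flow shifts the two halves of
its tuning curve (headings [0°,180°) and [180°,360°)) in opposite
directions, by roughly 30° at the stimulus geometry emulated here.  The
3-step procedure: (1) the pursuit curves' peak-to-trough modulation is
linearly rescaled (about the curve mean) to match the no-pursuit curve;
(2) curves are interpolated to 1° and split into the two half ranges, each
required to be significantly tuned; (3) within each half the no-pursuit
curve is circularly shifted in 1° steps over ±90° to maximise the Pearson
correlation with the pursuit half.  The up-to-four shifts (2 directions ×
2 halves) are sign-aligned by a fixed table — leftward pursuit predicts a
positive shift of the first half and a negative shift of the second, and
the reverse for rightward — averaged, and divided by the predicted 30°
(a configurable constant, `predicted_shift_deg`).  DI 0 ⇒ complete
compensation, DI 1 ⇒ complete shift; bootstrap CIs classify neurons as
complete compensation / complete shift / partial / unclassified.

Two genuinely open choices are recorded here: the ±90° search bound (a
larger shift would leave the half's support) and the half-open boundary
ownership ([0,180) / [180,360)), which makes the halves a partition.  One
stated symmetry deserves a caveat: *swapping* the leftward and rightward
data reverses the chirality of the distortion, so any signed shift
statistic flips sign — magnitude, not sign, is the invariant.  The signed
DI is kept because over- and counter-compensation are physically distinct.

## The synthetic world

`neuron_spec()` describes a neuron by the wrapped-Gaussian parameters plus
three generative knobs:

* `lambda_frame` ∈ [−0.5, 1.5] — the peak at eye position $P$ sits at
  $\theta_p + \lambda P$; 0 = head-centered, 1 = eye-centered.
* `gain` — multiplicative eye-position gain: monotonic
  ($1 + s\,P/20°$) or non-monotonic ($1 \pm s\,|P|/20°$, strongest or
  weakest at central fixation), the minimal forms reproducing the observed
  gain-field phenomenology.
* `noise` — Gaussian with variance = Fano × mean (default Fano 1.5,
  typical cortical variability), clipped at zero; Poisson 1 s counts as an
  alternative; the underlying study does not state its simulation noise
  model, so it is exposed rather than asserted.

Defaults mirror the emulated experiments: 8 headings at 45° steps, three
fixations at −20/0/+20° (optionally ±10/±30°), 5 repetitions, 2 s stimuli
with a Gaussian velocity profile (0.11 m, peak 0.25 m/s).  The velocity
bell's width is derived from the printed peak velocity via
$V = D/(\sigma\sqrt{2\pi})$, giving σ ≈ 0.18 s; fitting ±3σ into the 2 s
window instead would contradict the stated peak velocity and acceleration,
so that variant is optional rather than default.

**Pursuit generation grid.**  `simulate_pursuit_block()` produces the
distortion *directly as half-range circular shifts* of the no-pursuit
tuning — the very quantity the analysis measures — on a 1° heading grid by
default.  A dense grid is the faithful realisation of that construct:
sampling the shifted halves at 45° and re-interpolating deforms the
half-curves enough to move the recovered shift by several degrees (measured
up to ~7°/30°), which is a property a user can opt into by passing a coarse
session-realistic grid, but it would silently break calibration tests if it
were the default.  Ray-traced resultant optic flow is deliberately out of
scope; the 30° predicted shift is a constant of the emulated stimulus
geometry.

What a green recovery test does establish: the analysis chain inverts the
generator across the frame-parameter range at realistic noise, without
systematic bias, and the bootstrap CIs have close-to-nominal coverage.
What it does not establish: anything about real neurons — the generator has
no response adaptation, no correlated noise across trials or headings, no
eye-position-dependent baseline shifts, and its pursuit distortion is the
idealised half-shift construct rather than flow geometry.

## Gain fields and behaviour

The evoked response of a curve is max − min of the mean rates — invariant
to additive offsets, so differences across eye positions indicate
multiplicative gain.  No canonical significance test exists for the
amplitude range across three eye positions, so a label-permutation test is
used (eye-position labels permuted within each heading; upper-tail p, since
only large ranges indicate modulation).  Significant neurons are
categorised monotonic vs non-monotonic from the amplitude pattern over
(−20°, 0°, +20°), with amplitudes within 5% treated as tied to avoid
knife-edge classification.  Because the significance criterion in the
source is unspecified, reported population proportions of gain-modulated
neurons are not reproduction targets.

Behavioural reports are decoded from saccade endpoints on a 20°-diameter
choice ring centred on the fixation point: the endpoint's polar angle (0° =
right, 90° = up) maps onto heading azimuth (0° = rightward, 90° = forward).
A 5 × 5° axis-aligned reward window scores correctness.  Estimates are
summarised per (heading × fixation) by circular mean and circular SD
($\sqrt{-2\ln \bar R}$), and the fixation-dependent error is the *signed*
circular difference (eccentric − central, taken in (−180°, 180°]) averaged
over matched headings — signed rather than absolute, so leftward and
rightward biases cancel only if they genuinely oppose.

## Worked example

```{r example, eval = FALSE}
spec <- neuron_spec(theta_p_deg = 77, lambda_frame = 0.63,
                    noise = list(kind = "gaussian_fano", fano = 1.5))
trials <- simulate_fixation_block(spec, reps = 5, seed = 42)
displacement_index(trials, "syn1", n_boot = 1000, seed = 1)
#> DI = 0.667 over 3 pair(s), 95% CI [0.433, 0.958] -> intermediate
```

## Known limitations

* DI resolution is bounded by the 1° lag grid (0.05 per pair at 20°
  eccentricity, 0.1 at 10°).
* The half-shift search assumes the distortion stays within ±90° of a half
  range; pathological curves with near-uniform halves are dropped.
* The permutation gain test requires ≥ 3 repetitions per cell and a
  balanced design (extra repetitions beyond the smallest cell count are
  ignored).
* Head- vs body-centered frames cannot be distinguished by this design;
  "head-centered" throughout means gaze-invariant.
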