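# refframe

Reference-frame analysis of visual and vestibular heading tuning.

## What this is for

Heading — the direction of self-motion — is signalled to cortex by visual
optic flow (arising on the retina, hence **eye-centered**) and by vestibular
inertial cues (arising in the inner ear, hence **head-centered**). Whether a
given neuron represents heading in an eye- or head-centered frame is
diagnosed by measuring its heading tuning curve while gaze is held at
different static eccentricities (e.g. −20°, 0°, +20°): an eye-centered curve
shifts with the eyes, a head-centered one does not. `refframe` packages the
full analysis chain used in such experiments, for anyone with trial-level
firing-rate tables:

* **Displacement index (DI).** For curves $R_i, R_j$ at eye positions
  $P_i, P_j$: interpolate to 1°, find the circular lag
  $k^\* = \arg\max_k \mathrm{cov}[R_i(\theta), R_j(\theta+k)]$, and take
  $\mathrm{DI} = k^\*/(P_j - P_i)$, so DI = 0 is head-centered and DI = 1
  eye-centered. Pair DIs are averaged over significantly tuned curves
  (one-way ANOVA, p < 0.05); a bootstrap over repetitions yields a 95% CI
  and a four-way classification (head / eye / intermediate / unclassified).
* **Joint model fitting.** Eye- and head-centered 16-parameter wrapped-
  Gaussian models fit across all three eye positions simultaneously,
  compared via partial correlations and Fisher Z with the 1.645 one-tailed
  criterion, after an $r^2 \ge 0.6$ goodness filter.
* **Pursuit partial-shift DI.** Under smooth pursuit (±16°/s) tuning halves
  [0°,180°) and [180°,360°) shift in opposite directions; the 3-step
  procedure (amplitude rescaling, half splitting, ±90° correlation search)
  yields up to four half-shifts, averaged and divided by the predicted 30°.
* **Gain fields.** Eye-position modulation of the evoked amplitude
  (max − min mean rate), permutation-tested and categorised
  monotonic / non-monotonic / none.
* **Behaviour.** Heading reports decoded from saccade endpoints on a
  fixation-centred choice ring; circular means/SDs and the signed
  fixation-dependent estimation error.
* **Synthetic data.** A generator with a continuous frame parameter
  `lambda_frame` (0 = head-, 1 = eye-centered), gain fields, Fano-factor
  noise and a pursuit-compensation parameter, so that every analysis stage
  is testable by parameter recovery.

## Worked example

```r
library(refframe)

## a synthetic neuron two-thirds of the way to eye-centered
spec <- neuron_spec(theta_p_deg = 77, lambda_frame = 0.63,
                    noise = list(kind = "gaussian_fano", fano = 1.5))
trials <- simulate_fixation_block(spec, reps = 5, seed = 42)

displacement_index(trials, "syn1", n_boot = 1000, seed = 1)
#> DI = 0.667 over 3 pair(s), 95% CI [0.433, 0.958] -> intermediate

curves <- lapply(c(-20, 0, 20), function(P)
  build_tuning(trials, "syn1", "visual", list(eye_pos_deg = P)))
compare_models(curves, eye_positions = c(-20, 0, 20), seed = 2)
#> Model comparison: Z_e = 5.63, Z_h = 2.86 (diff 2.76) -> eye
```

The DI of 0.667 sits within the 1°-lag resolution of the generating
`lambda_frame = 0.63`; the CI excludes both 0 and 1, so the neuron is
classified *intermediate*, while the (noisier) model-comparison route calls
it eye-centered — with 5 repetitions of Fano-1.5 noise both answers are
within expectation. A pursuit block works the same way:

```r
pspec <- neuron_spec(theta_p_deg = 77, pursuit_comp = 0.7,
                     noise = list(kind = "gaussian_fano", fano = 0.5))
pursuit_displacement(simulate_pursuit_block(pspec, reps = 5, seed = 42),
                     "syn1")
#> Pursuit DI = 0.325 from 4 half-shift(s)
```

(compensation 0.7 predicts a pursuit DI of 0.3).

## Command line

```sh
Rscript inst/cli/refframe.R simulate --lambda 1 --fano 0.5 --reps 5 \
    --seed 17 --out trials.csv
Rscript inst/cli/refframe.R di --in trials.csv --boot 1000 --seed 7 \
    --out di.json
```

Commands: `tuning`, `simulate`, `di`, `pursuit-di`, `fit-models`, `gain`,
`behavior`. Third-party CSVs with different column names are ingested via a
column-mapping `dialect` in `load_trial_table()`.

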