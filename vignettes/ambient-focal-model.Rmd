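---
title: "Modelling the ambient-to-focal switch in free-viewing eye movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the ambient-to-focal switch in free-viewing eye movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazemodes)
```

## The problem

When primates freely view a scene composed of discrete objects, their eye
movements show a reproducible temporal structure: early in viewing, large
saccades hop between many objects (ambient scanning); later, small saccades
repeatedly re-examine a single object (focal examination), while fixation
durations grow and saccade amplitudes shrink. `gazemodes` implements an
object-based account of this shift. Fixations are labelled by whether they
land on an object or on the background, saccades are classified by the
labels of their flanking fixations, and the trial-averaged evolution of the
five saccade types is explained by a stochastic generative model with a
single abrupt switch between two saccade-generation modes.

## The generative model

The model is a discrete-time Markov chain over four saccade-generation
states: an intra-object and a trans-object state in each of two modes
(early/ambient and late/focal). At every step it emits one saccade whose
type is given by the current state. Six probabilities parameterise it:

| parameter | meaning | default source |
|---|---|---|
| `p_sw` | per-step probability of the one-way early-to-late switch | fitted |
| `p_intra_e`, `p_trans_e` | stay probabilities of the intra/trans state in the early mode | fitted |
| `p_intra_l`, `p_trans_l` | the same for the late mode | fitted |
| `p_bg` | probability that a fixation is erroneously a background fixation | empirical background proportion |

The first state is drawn from the stationary distribution of the early-mode
chain, `P(intra) = (1 - p_trans_e) / (2 - p_intra_e - p_trans_e)`. At each
later step the chain switches to the late mode with probability `p_sw`; the
switch is absorbing, and the state occupied at the switch step is already
generated with the late-mode stay probabilities (so the earliest step that
can be governed by the late mode is step 2). The number of saccades
generated before the switch is therefore geometric with mean `1 / p_sw`:

```{r}
expected_switch_step(0.2)
```

State sequences are spatialised in a two-object world (intra keeps the
current object, trans toggles it), and each fixation is independently
flipped to a background fixation with probability `p_bg` - except the first
fixation, which is protected when the trial starts on an object (a stimulus
with an object at the centre) and forced to background when it starts on
the background. Saccade types are then re-derived from the flipped fixation
sequence exactly as empirical saccades are classified. Trials have a fixed
number of fixations `n_fix` (21 for the object-at-centre condition, 16 for
the background-start condition, the average empirical counts).

### Exact expected curves

`expected_ratio_curves()` propagates the joint (mode, state) distribution
step by step and combines the putative intra/trans probability at each
saccade order with the independent flip indicators of the flanking
fixations. This closed form replaces Monte Carlo simulation inside the
fitting loop, which removes simulation noise from the goodness-of-fit
surface and makes the grid-search arg-max deterministic given the data;
`simulate_ratio_curves()` retains the simulation route, and the two are
cross-checked against each other (and against exhaustive enumeration at
small trial lengths) in the test suite.

```{r}
p_h <- model_params(p_sw = 0.20, p_intra_e = 0, p_trans_e = 1,
                    p_intra_l = 0.90, p_trans_l = 0.55, p_bg = 0.23,
                    n_fix = 21)
q <- expected_ratio_curves(p_h)
round(unclass(q)[1:6, ], 3)
```

## Fitting

`p_bg` is fixed beforehand at the empirical proportion of background
fixations. The remaining five probabilities are fitted by exhaustive grid
search in steps of 0.05 (21^5 combinations, evaluated in compiled code),
maximising the goodness of fit

GoF = [ (1 / (N_fix - 1)) * sum_i | r_i_emp - r_i_model | ]^-1,

where `r_i` are the 5-vectors of saccade-type ratios at order `i`. The bare
absolute value of the vector difference is read as the L1 norm over the
five components (scale-consistent with ratio components; an L2 option is
exposed via `norm = "L2"`). Ties are broken lexicographically - smallest
`p_sw` first, then the remaining parameters in their listed order - and the
number of tied grid points is reported. Two numerical choices matter:

* at the degenerate grid point `p_intra_e = p_trans_e = 1` the early-mode
  stationary distribution is undefined; the grid evaluation uses the
  symmetric limit (0.5, 0.5) so the grid stays complete, while
  `initial_state_distribution()` refuses those parameters explicitly;
* mean deviations below 1e-12 are treated as exactly zero, so
  self-consistent inputs return the infinite-GoF sentinel instead of a
  rounding-noise-sized value.

The switch model is compared with a no-switch variant (`p_sw = 0`, a single
mode whose two stay probabilities are free) by AIC = 2k - 2 ln L with k = 5
versus k = 2 effective parameters. No likelihood is implied by the GoF
fit itself, so the package uses an independent-across-orders marginal
multinomial likelihood: each observed saccade type at order `i` contributes
`log q_i[type]` under the fitted model's expected curves. This is the
single largest interpretive choice in the package; it treats saccades, not
trials, as the observational unit and ignores within-trial dependence, but
it penalises both models identically and is used only for model
comparison, never for parameter estimation.

### Identifiability

Not all five parameters are equally constrained by ratio curves. When
`p_trans_e = 1` and the early stationary distribution puts no mass on the
intra state, `p_intra_e` has no effect at all (the fit reports the tie and
resolves it to the smallest value). Under the background-start condition
the early-mode parameters are weakly identified in general: neighbouring
early-mode grid vectors produce curves within < 0.01 max-abs of each
other, below the Monte Carlo noise of 10,000 trials, and the fitted switch
probability itself lands one grid step away from the generating value in
roughly one run in ten. The parameter-recovery tests assert recovery of
the parameters the data can identify.

### Single-trial switch inference

`infer_switch_posterior()` inverts the generative model for one observed
type sequence: the prior over the switch step is the geometric switch-time
mass (including the no-switch-within-trial remainder), and the likelihood
of each candidate switch step is computed exactly by a forward pass over
the joint hidden variable (putative state, flip status of the current
fixation). The forward pass is verified against brute-force enumeration of
all state and flip sequences in the tests.

## Event detection

Gaze traces are differentiated with Savitzky-Golay filters (window 10 ms -
199 samples at the 20 kHz coil sampling rate, scaled to the nearest odd
sample count at other rates; polynomial order 2). Saccade candidates are
maximal runs of speed above 30 deg/s; a candidate must also reach an
acceleration magnitude above 8000 deg/s^2. The acceleration requirement is
applied per segment rather than per sample for a structural reason: the
acceleration magnitude of any saccade passes through zero at peak
velocity, so demanding both criteria at every sample would split every
saccade in two. Candidates are discarded as artifacts when peak velocity
exceeds 1500 deg/s, peak acceleration exceeds 120,000 deg/s^2, duration
falls outside 5-100 ms, or the endpoint displacement is below 0.1 deg;
microsaccades are not treated separately. Inter-saccade intervals become
fixations unless the gaze shifts by more than 1 deg within them
(maximum pairwise sample distance, computed via the convex hull), and all
events starting within 150 ms of stimulus onset are discarded as
stimulus-unrelated. The interval between stimulus onset and the first
saccade is treated as a fixation when it satisfies the drift criterion -
and is then consumed by the 150 ms exclusion, which is why each trial
contributes one fewer classified saccade than it has saccades.

Fixations are labelled by the shortest object distance: an object fixation
iff the distance to the nearest object centre is strictly below 1.5 deg
(object radius of about 1 deg plus the foveal extent; results are robust
for thresholds between 1 and 2 deg, which the suite checks by comparing
ratio curves at 1.0 and 2.0 deg). Ties between equidistant objects resolve
to the lowest object id for reproducibility.

## The synthetic-data generator

No recordings ship with the package, so a generator stands in for them and
is itself first-class, tested code. It emulates: the two-mode Markov
structure of saccade targets; about 80% object fixations (via `p_bg` near
0.2); fixation durations drawn from a gamma distribution (shape 10) whose
mean rises linearly from 0.15 s at stimulus onset by 0.04 s per second of
viewing, matching the observed growth to roughly 0.35 s over a 5 s trial;
and saccade amplitudes that shrink over the trial as an emergent
consequence of the early-trans/late-intra structure (trans-object saccades
span >= 4 deg between object centres, intra-object saccades < 2 deg).
Layouts place five 1-deg-radius objects in a 34.8 x 26.1 deg image with
centres at least 4 deg apart, optionally with object 1 at the centre.

Rendering choices (the recorded traces' analogue):

* saccade trajectories use a raised-cosine velocity profile (smooth,
  closed-form peak velocity `2 * amplitude / duration`);
* saccade durations follow `0.010 s + 0.0018 s/deg * amplitude`. These
  constants keep every rendered saccade of 0.5-15 deg inside the
  detector's velocity and acceleration windows *and* keep the displacement
  accumulated outside the 30 deg/s threshold crossings below 0.05 deg, so
  detected endpoint amplitudes track the ground truth; a slower main
  sequence would make threshold-bounded amplitudes of large saccades
  systematically short;
* background relocations are rejection-sampled with shortest object
  distance in (1.5, 3] deg - unambiguously background yet spatially
  plausible as saccadic near-misses;
* consecutive fixation positions are kept at least 0.5 deg apart so every
  ground-truth saccade is detectable in principle;
* the first fixation lasts at least 0.2 s (a stand-in for saccadic
  response latency), and the pre-stimulus fixation is rendered at the
  first fixation's position - the subject is already fixating where the
  trial starts, so no spurious onset saccade is introduced.

What the generator does **not** emulate: saliency-driven target selection,
main-sequence variability, saccadic curvature, drift/tremor during
fixations beyond white position noise, blinks, or the natural-scene
background condition. Passing tests therefore demonstrate the internal
consistency of detection, classification and fitting under the model's own
assumptions - not detector performance on real coil recordings.

## Problem sizes and runtime choices

The test suite renders traces at 2 kHz (the 20 kHz default is exercised
where closed forms are checked); detector round trips span amplitudes
0.5-15 deg. Fits in the acceptance checks use 10,000 simulated trials and
the full 0.05 grid; oracle-equivalence checks use 100,000 trials per
parameter vector; the AIC selection check uses 20 replicates of 1,000
trials per direction. The switch-time Monte Carlo uses 100,000 sequences
of 60 steps, long enough that right-censoring of the geometric switch time
is negligible.

## Known limitations

* The AIC likelihood is a marginal construction (see above); absolute AIC
  values are not comparable to likelihoods from models with within-trial
  dependence.
* The GoF norm over the five ratio components is an interpretive choice
  (L1 default, L2 optional).
* The fitted `n_fix` is fixed per condition; trials shorter than `n_fix`
  simply contribute to fewer orders.
* Gradual-shift (time-inhomogeneous) alternatives to the abrupt switch are
  out of scope; the model family contains exactly two modes.
* Trace files are read and written as TSV with metadata headers; no
  proprietary tracker formats.
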