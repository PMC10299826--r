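---
title: "Accumulator models and choice statistics for honey bee foraging decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accumulator models and choice statistics for honey bee foraging decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beechoice)
```

## The paradigm

A foraging honey bee confronted with a coloured target makes one of two
responses: it lands and probes (an acceptance) or it flies on (a
rejection).  When colours differ in how often they have been rewarded,
every response against a two-colour pair is one of four outcomes: correct
acceptance (CA) of the higher-rewarded colour, incorrect acceptance (IA)
of the lower one, correct rejection (CR) of the lower one, incorrect
rejection (IR) of the higher one.  `beechoice` treats this four-outcome
table as the primitive of all analyses, and provides the machinery around
it: the training design that creates the reward asymmetry, statistics that
summarise the table, a circuit-level model that generates it, and a
trajectory classifier that extracts it from flight video tracks.

## Training design

The two shipped 18-trial protocols (`build_protocol("P1")`, `"P2"`)
present every unordered pair of five colours exactly twice — except the
(66 %, 33 %) pair, withheld so that it can probe generalisation after
training — with the higher-likelihood member of each pair rewarded and the
other punished.  The per-colour reward likelihoods that result are exactly
1, 4/6, 4/8, 2/6 and 0.  The package stores the trial tables and derives
likelihoods by counting, so `reward_likelihood(p1, "S66")` is exactly
`4/6` rather than a pre-rounded percentage.  The rewarded member is
generated by the rule *higher nominal likelihood wins*; `validate_protocol()`
checks the trial count, the pair coverage, the withheld pair, and that
rule, and reports violations rather than raising them, so user-supplied
protocols can be audited.  Colour-to-hue assignments of the two
counterbalanced bee groups are carried as display metadata only; all
computation keys on likelihood rank.

## Choice statistics

**MCC.**  The Matthews correlation coefficient condenses the four-outcome
table into one number in [−1, 1]; 0 is chance.  When a marginal of the
table is zero the coefficient is undefined and the package returns the
conventional 0 (with a notice attached in cohort summaries).  A useful
identity, exploited as a test oracle: the MCC equals the Pearson
correlation of the binary indicators *accepted* and *was the
higher-ranked colour* over the expanded table.

**Signal detection.**  Discriminability and criterion are computed from
the acceptance- and rejection-conditioned error rates: hit rate
= nCA/(nCA+nIA), false-positive rate = nIR/(nIR+nCR).  This conditioning
— the natural one when each encounter forces an accept or reject and both
response types are scored — differs from the textbook false-alarm rate
(nIA/(nIA+nCR)); the textbook variant is available via
`fp_definition = "noise_trials"` and outputs are labelled with the
definition used.  A rate of exactly 0 or 1 makes the inverse-normal
transform infinite, so an edge policy applies before Z: the default clamps
to 1/(2N) and 1−1/(2N) with N the relevant denominator; a log-linear
(+0.5 per cell) alternative is selectable; either marks the output
`edge_corrected`.  Bees (or model bees) with no acceptances or no
rejections have no defined rates and are excluded from SDT summaries with
an error naming the missing response type.

**Conditional accuracy functions.**  Response times of one response type
are binned into half-open, left-closed bins `[k·w, (k+1)·w)` from 0 s
(default width 0.5 s), and the proportion correct is computed per bin.
Half-open bins make boundary times deterministic.  Bins with fewer than
`min_count = 3` responses are reported with an undefined proportion and
excluded from the trend statistic; the curve itself is the deliverable —
any smooth drawn through it is presentation, not analysis.  The trend is
a Spearman rank correlation of bin mid-time against proportion correct;
constant proportions return 0 under the average-rank ties convention.

## The accumulator model

Evidence for accepting (P~a~) and rejecting (P~r~) accumulates in two
leaky integrators driven by a common sensory input *I* and integrated by
Euler–Maruyama with step `dt`:

$$dP_a = (-k P_a - w_{1a} r_{L1} - w_{2a} r_{L2} + I - v_r R)\,dt + \sigma\,dW_1$$
$$dP_r = (-k P_r - w_{1r} r_{L1} - w_{2r} r_{L2} + I - v_a A)\,dt + \sigma\,dW_2$$

with P~a~(0) = P~r~(0) = 0.  Command cells read the accumulators through a
floor at the baseline activity 0.1: A = max(0.1, P~a~), R = max(0.1, P~r~).
A decision fires when a command output reaches the threshold θ; if neither
crosses by the assessment deadline t~max~ the decision is forced to the
larger command output.  Four variants gate the terms: `race` (neither
learning nor feedback), `cross` (feedback only), `learning` (learning
only), `full` (both).

Design choices where the dynamics leave room:

* **Cross-inhibition as drift.**  The feedback terms −v·(command output)
  enter multiplied by `dt`, like every other drift term, rather than as an
  undiscounted per-step subtraction.  Only the drift form leaves the
  dynamics invariant as `dt` shrinks (halving `dt` changes a noiseless
  decision time by less than `dt`; this is a test).
* **Learning-cell convention.**  The low-rewarded-colour cell L1 projects
  mainly onto the accept accumulator (w~1a~ > w~2a~) and the
  high-rewarded-colour cell L2 mainly onto the reject accumulator
  (w~2r~ > w~1r~): a familiar low colour suppresses acceptance, a familiar
  high colour suppresses rejection.  This is the only assignment under
  which learning produces the intended bias, and the package enforces the
  weight orderings whenever learning is enabled.
* **Graded activation.**  Learning-cell drives scale with the presented
  colour's learned reward estimate q̂:
  r~L1~ = α·I·(1−q̂), r~L2~ = α·I·q̂, which reduces to the binary
  low/high scheme at the endpoints and lets blend stimuli and partially
  rewarded colours drive the cells proportionally.
* **Ties resolve to rejection.**  If both commands cross θ in one step the
  larger wins; an exact tie — and the all-quiescent forced case
  A = R = 0.1 — resolves to reject.  Rejection is the cheap, default
  action for a forager: flying on costs an opportunity, landing on the
  wrong target costs the error.
* **Forced decisions compare command outputs** (post-floor), not raw
  accumulator values, since the floor is what downstream motor circuitry
  sees.
* **Degenerate inputs.**  Parameter sets that blow up (non-finite state)
  raise an error naming the step; θ ≤ baseline is rejected at construction
  because every trial would end instantly.

### Parameters, units and defaults

| symbol | meaning | unit | default |
|---|---|---|---|
| k | accumulator leak | 1/s | 1 |
| I | sensory input | evidence/s | 1 |
| σ (`sigma`) | noise scale | evidence/√s | 0.6 |
| θ (`theta`) | command threshold | evidence | 1.5 |
| t_max | assessment deadline | s | 10 |
| dt | integration step | s | 0.01 |
| va, vr | cross-inhibition fractions | – | 0.2, 0.6 |
| α (`alpha`) | learning-cell rate | – | 0.8 |
| w1a, w2a | L1/L2 → accept weights | – | 0.8, 0.1 |
| w1r, w2r | L1/L2 → reject weights | – | 0.1, 0.8 |
| baseline | command floor | evidence | 0.1 |

The behavioural data constrain the *orderings* (vr > va, w~1a~ > w~2a~,
w~2r~ > w~1r~) but not the magnitudes of σ, θ, k, I or the weights; those
are free parameters.  The defaults were fixed by `calibrate_model()`, a
grid search over (σ, θ, vr) that accepts the first combination whose
full-variant easy-test signatures all hold: rejections outnumber
acceptances, incorrect rejections outnumber incorrect acceptances, and
correct acceptances are faster than incorrect ones.  The third signature
is the discriminating one.  With a low threshold relative to the noise,
erroneous acceptances of the low colour occur only as early noise
excursions — the fast competing rejection truncates late ones — so they
come out *faster* than correct acceptances.  A higher threshold
(θ = 1.5 at σ = 0.6) moves erroneous acceptances into the late,
low-confidence regime (many at the forced deadline), reproducing the
reversed speed–accuracy pattern in which fast acceptances are reliable
and slow ones are guesses.

### Training the model

The mushroom-body plasticity that tracks each colour's reinforcement
history is abstracted to a delta rule on a per-colour reward estimate:
q̂ ← q̂ + η(r − q̂) for each colour presented in a trial, r = 1 when that
colour was the rewarded member, starting from q̂ = 0.5.  The default
η = 0.1 is deliberately conservative: the estimate must integrate a
colour's whole reinforcement history, and larger rates over-weight the
final trials — at η = 0.3 the 50 %-rewarded colour ends *below* the
33 %-rewarded one under protocol P1, because its last two exposures are
punishments.  η = 0.1 is the largest round value that preserves the
likelihood rank ordering under both shipped protocols (a tested
invariant).  Blend stimuli inherit estimates by linear interpolation
between their anchors' estimates (`generalise()`), which is the simplest
scheme consistent with perceptual similarity driving generalisation.

### Tests, cohorts and ablations

`run_test()` presents each of 20 model bees with 25 stimuli drawn
uniformly at random from the test pair (easy: idealised q̂ = 1 vs 0;
reduced evidence: blends at similarities 0.7 and 0.3; reduced likelihood:
the trained 66 %/33 % estimates).  Bee *i* is seeded with
`master_seed + i`, so cohorts are exactly reproducible and bees differ
only in their noise streams; optional per-bee parameter variation is
deliberately not introduced.  Decision times are additionally reported
normalised to the cohort maximum (so the maximum is exactly 1), which
makes response-time comparisons across conditions scale-free.
`ablate()` silences learning (α = 0), feedback (va = vr = 0), or both.
The blend similarities 0.7/0.3 are configuration values, not measured
colourimetry.

## Trajectory classification

Visits are maximal runs of consecutive frames within 5 cm of a stimulus
centre; the hover time is the run's duration.  Classification uses the
mean within-radius flight speed (median selectable) against a threshold
from an *exact* one-dimensional two-means: every contiguous split of the
sorted speed samples is scored by within-cluster sum of squares and the
optimum taken, so there is no initialisation sensitivity and the result
equals brute-force partition search (a tested equivalence up to n = 200).
The threshold is fitted per bee and test by default — a dynamic threshold
tracks between-bee speed differences — with pooling available.

Brief grazes are excluded rather than classified: a segment shorter than
0.2 s whose first and last frames lie within 1 cm of the focal boundary is
a rim-clipping pass, not an inspection.  The 1 cm margin operationalises
"close to the edge" and is exposed as a parameter.  A 2-D track cannot
verify antennal contact or flight height; low-speed-cluster membership is
the implemented proxy for landing, which is exactly what an automated
counter over the same data can know.

## Synthetic data: what it does and does not show

`generate_choice_events()` draws per-bee encounter counts (Poisson),
stimuli (uniform from the pair), responses (Bernoulli by the colour's
acceptance probability) and response times (log-normal per category,
positive and right-skewed), truncated to a 120 s observation window.  The
default time parameters plant the qualitative pattern of trained bees —
correct acceptances faster than incorrect ones, rejection times
insensitive to correctness — so conditional-accuracy fixtures look
realistic; they are illustrative values, not measurements.
`generate_trajectory()` builds piecewise cruise/creep/hover paths at
240 FPS through a planted visit plan, with detours so that cruise legs
never clip an unintended focal area, and small Gaussian positional jitter.

What recovery tests on these generators demonstrate: the analysis
pipeline inverts its own generative model — rates within 3/√N, planted
labels at 100 % under separated speed modes, seeds reproduce tables
exactly.  What they do not demonstrate: robustness to real-data
pathologies (tracking dropouts, occlusions, varying motivation, satiation,
non-stationary speeds), none of which the generators emulate.

## Problem sizes and numerical tolerances

The signature checks in the test suite pool 20 master seeds × 500 trials
(20 bees × 25 trials) per condition — sizes chosen so that binomial error
on a frequency is ~0.5 % and every sign test is stable across seeds.
Chance-level MCC assertions use |MCC| < 0.05 against a Monte-Carlo
standard error of ~0.01; frequency-symmetry assertions use three binomial
standard errors.  The inverse-normal oracle values (d′ at hit 0.84 /
fp 0.16 = 1.988915766419506) were frozen from an independent
high-precision evaluation before the statistics were implemented.

## Known limitations

* In the calibrated full model, correct rejections (drift-driven) are
  systematically faster than incorrect rejections (noise-driven), i.e.
  rejection times are *not* insensitive to correctness; the model
  reproduces the acceptance-side time asymmetry but only attenuates, not
  eliminates, the rejection-side one.
* Count-based accuracy differences (nCA−nIA vs nCR−nIR) are uninformative
  under forced binary outcomes with balanced presentation — the difference
  reduces to the presentation imbalance — so error asymmetry is assessed
  as nIR vs nIA.
* The learning stage is an abstraction: a delta rule on reward estimates,
  not a circuit model of mushroom-body plasticity; fitting parameters to
  individual live-bee data is out of scope.
* The trajectory classifier has no altitude cue; genuine high fly-overs
  are separable only by speed.
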