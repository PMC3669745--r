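---
title: "Counting the ways extinction can happen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting the ways extinction can happen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearext)
```

## The scientific question

Extinction of conditioned fear requires endocannabinoid (CB1) signalling,
and the documented synaptic consequence of CB1 activation is LTD of the
GABAergic synapses that lateral-amygdala interneurons make onto projection
neurons. That LTD *disinhibits* the projection neurons that drive fear
output, so naively it should oppose extinction. `fearext` treats this as a
counting problem over two rate-coded circuit models of the amygdala: among
all integer synaptic-weight configurations reachable by legal plasticity
steps, how many complete extinction after conditioning, and how does that
number change when CB1-mediated LTD is required, or forbidden, or combined
with constraints from unit recordings (some lateral-amygdala neurons keep
their cue responses after extinction; none become cue-inhibited)?

The package's position is that the count of compatible configurations is a
useful proxy for the likelihood of an outcome when the plasticity mechanism
itself is unknown: an outcome that can be realised in many more ways is the
more probable one under any adaptive process with a stochastic component.

## The two circuits

`model1()` is the two-pathway architecture: a *Fear* chain (CS/US → LA2 →
BA2 → CEm) and a *No Fear* chain (CS → LA1 → BA1 → ITCm ⊣ CEm), each LA
projection neuron under constant inhibition from its own interneuron (LAi1,
LAi2). `model2()` is the single-pathway architecture: CS/US feed LAi, LA1
and LA2; LAi inhibits LA1 only; LA1 and LA2 excite ITCl, which inhibits
ITCm, which inhibits CEm; the infralimbic cortex input IL (active only
during extinction training) excites LAi, ITCl and ITCm. In both, PAG is a
binary gate on CEm activity and signals the fear response.

Biases are fixed by the published figure captions so that every element with
non-zero spontaneous activity rests at rate 1 when all inputs are off;
`activities(model1())` verifies this directly. All initial weight magnitudes
are 1 except the cue inputs (and model 2's IL inputs), which start at 0.

## Rewriting semantics

The state of a search is `(phase, weight magnitudes, records)`:

* **Conditioning.** Any schedule-allowed weight may take a unit LTP step,
  one weight (or tie group) at a time, in every possible order, subject to
  the 0–2 magnitude bounds. After each step the circuit is evaluated with
  the cue alone (CS = 1, US = 0, IL = 0); the first time PAG fires,
  conditioning ends and the record-tracked interneuron weights are
  snapshotted. Phase transition is immediate and deterministic — it is part
  of the step, not a separate nondeterministic rule.
* **Extinction.** Allowed weights step according to the extinction schedule
  (LTD for most; LTP for model 2's IL inputs and for the cue inputs in some
  model 1 variants), evaluated with the cue during extinction training
  (CS = 1, US = 0, IL = 1). The first time PAG goes silent the state is
  terminal. At the conditioning/extinction boundary the two test contexts
  coincide, because IL weights are still 0 there; the convention is
  therefore benign, and it is the extinction-training context that all
  post-extinction predicates use.
* **Identity and counting.** Configurations are distinct `(final weights,
  records)` pairs — never path counts. The records multiply the space by 2
  per tracked weight (stay at 1 or rise to 2 during conditioning), which is
  what makes the full spaces 3⁹·2² = 78,732 (model 1) and 3⁹·2 = 39,366
  (model 2).
* **Dead-ends.** A conditioning state with no moves left that never fired
  PAG (model 1 has exactly one: the fully saturated configuration), or an
  extinction state stuck with PAG active, is *not* a terminal configuration.
  Both kinds are counted and reported as attributes for diagnosis; neither
  baseline model has extinction dead-ends.

The engine exploits the fact that within a phase every dimension moves in a
single direction, so the signed digit sum is a potential that increases by
one per move: a sweep over potential levels is simultaneously a memoized
breadth-first traversal and a topological order for depth bookkeeping. Gate
activity for the whole 3^K cube is evaluated once, vectorised. An
independent all-sequences oracle (`enumerate_terminals_naive()`, built on
the exported single-step semantics `applicable_moves()`/`apply_move()`)
must agree exactly on every space small enough to walk; the test suite
checks sets *and* shortest-sequence depths on three registry rows and the
toy circuits.

## Activity semantics: the one calibrated choice

The published model definition makes each activity a weighted sum of inputs
plus a bias, and never states a floor. Whether intermediate activities may go
negative is invisible in model 1 (no activity except CEm can go below zero
there) but decisive in model 2, where strong inhibition can drive LA1 and
ITCl negative. The package therefore treats the printed configuration
counts as the arbiter between the two semantics:

* linear evaluation gives 7,354 / 4,381 for model 2's first two rows;
* flooring every non-input activity at zero gives exactly the published
  8,394 / 4,659.

Rectified evaluation (`rectify = TRUE`) is accordingly the package default;
it is also the physiologically sensible choice, since firing rates cannot be
negative. The linear variant remains one flag away for sensitivity analysis.
A scan over all per-element flooring subsets showed every subset that
reproduces the two counts yields the *same* terminal set, so the calibration
does not hide residual freedom.

## What reproduces, what does not, and why

With the calibrated semantics the package reproduces exactly: all of model
1's table except row 11 (observed 4 vs published 3), the configuration-space
sizes, model 2 rows 1, 2 and 6, and the headline percentages (58.7% of
model 1 outcomes and 55.5% of model 2 outcomes coexist with interneuron
LTD, the published "about 59%"/"about 56%").

The model 2 rows conditioned on cue-response predicates ("LA1 or LA2
excited by CS after extinction", "neither inhibited") do **not** reproduce,
and the package deliberately leaves them failing rather than curve-fitting
them. The reason is structural. In model 2, LA2 receives only the cue
weight wCStoLA2, the US weight and its bias; under *any* per-state reading,
"LA2 responding to the cue" reduces to a threshold on wCStoLA2. In the
terminal set that matches rows 1–2 exactly, 2,735 of the 4,659
LTD-conjoined configurations have wCStoLA2 > 0 and 1,219 have
wCStoLA2 = 2 — but the published "either LA1 or LA2 responding" count is
2,335, *below* the first and not assemblable from the second plus any LA1
predicate over any evaluation context (IL on or off, US on or off, floored
or linear, activity level or cue-evoked difference, at any integer
threshold). The original analysis must therefore have computed its response
predicates from state components that the text does not specify; no
faithful reconstruction from the published description can match those
rows, and the package reports its own strict-inequality response
differences (`cs_response()`, evaluated at the final weights in the
extinction context) instead. Model 1 row 11 is analogous in spirit: all
four configurations passing its equality filters are reachable by
hand-checkable move sequences, so the published 3 implies a restriction the
text does not state.

One published statement can be checked *against* another: under these
semantics some of the 19,273 model 1 terminal configurations are first
reached at rule-execution depth 20, so the printed count and the published
claim that every rule-execution series ended strictly before depth 20
cannot both hold; the package reports the true exhaustion depth (20 for
model 1, 19 for model 2).

## Constraint queries

Filters are pure predicates over terminal configurations, composed by
conjunction; adding one can never increase a count (a property the tests
assert along the published nested chains). `ltd_of(w)` is strict: final
magnitude < recorded magnitude. "Excited by CS" is a strictly positive cue
response, "inhibited" strictly negative; an exact zero is neither, which is
what lets "either excited" and "neither inhibited" coexist without
contradiction. Equality constraints appear in two forms, following the
published phrasing: model 1's "equal after extinction" rows are terminal
filters; model 2's "constrained to be equal" rows are tied joint updates
(one move changes all group members by the same amount). The terminal-filter
reading of the latter can be reproduced with `apply_filters()` and
`finals_equal` predicates if wanted.

## The directed-search cross-check

The real-valued cross-check asks whether restricting weights to integers
biased the conclusions. Each modifiable weight gets a conditioning change
and an extinction change, constrained so the weight stays in [0, 2] after
each phase. Starts are uniform over that feasible region (conditioning
change first, extinction change on its conditional interval). The search is
the classical coordinate pattern search: perturb each change in turn by ±Δ,
clip to the feasible region, take the best strictly-improving probe and
double Δ, otherwise halve Δ, stop below 10⁻⁶. Ties go to the earliest
parameter, +Δ before −Δ. The error is the sum over the unconditioned,
conditioned and extinguished cases of |desired − actual| PAG response, with
the PAG response taken as the binary activation indicator — a continuous
(clamped CEm) variant exists behind a flag but cannot reach exact zero
error in the conditioned case, so it is clearly not the published
procedure.

Two published details are under-specified and were fixed as follows:

* **Initial Δ**: 0.5 (a quarter of the weight range), configurable and
  echoed into every output.
* **Sign constraints**: off by default. The published description
  constrains only the 0–2 bounds, and the schedule-mirrored alternative
  (conditioning changes ≥ 0, extinction changes ≤ 0) makes the
  LTD-conditional percentage 100% by construction — every feasible start
  already has a negative extinction change on the interneuron weight —
  which contradicts the published comparison. Unconstrained signs
  reproduce its direction: the random real-valued sample is materially
  poorer in LTD-conjoined solutions than the exhaustive integer search.
  Exact published fractions (560/187, 743/113) are not reproducible from
  the description and are not targeted.

Structural zeros are respected in both modes: a weight with no conditioning
moves (model 2's IL inputs) has its conditioning change pinned at 0.

## Numerical and engineering choices

* Enumeration uses integer arithmetic throughout (states are base-3 codes);
  activities of integer configurations are integers, so no tolerance enters
  the phase tests. Real arithmetic appears only in the directed search.
* PAG firing is strict (input > 0); an input of exactly 0 is "off".
* Traversal order is fixed by connection declaration order, and the tests
  verify the terminal set is invariant under permutations of it.
* The per-configuration `depth` column is the length of the shortest rule
  sequence reaching that configuration — the depth at which a memoized
  breadth-first search discovers it; `max_depth` includes dead-ends.
* Degenerate inputs: removing elements that orphan the output pathway is
  allowed but messaged (it is the point of the basal-nucleus-removal
  variant, whose terminal set is empty); an experiment whose initial state
  already fires PAG under the cue is rejected.

## Limitations

The models are rate-coded, feedforward snapshots: no spiking, no time
course, no learning *mechanism* — LTP and LTD are assumed, not derived, and
their unit-step, 0–2-bounded parameterisation is inherited from the
published design. The terminal-set counts quantify *how many* weight
configurations are compatible with an outcome, not how a biological
trajectory selects among them. The cue-response table rows are reported
under this package's explicitly documented predicate definitions and
deviate from the published counts for the reasons given above; conclusions
that depend on those specific rows should be drawn with that caveat.
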