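---
title: "A ternary logical model of neuroendocrine-immune regulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A ternary logical model of neuroendocrine-immune regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternet)
```

## The model and its assumptions

`ternet` treats the male neuroendocrine-immune system as a discrete
dynamical system. Each entity — a hormone, a receptor pool, an immune cell
population, a cytokine group, a brain-compartment player — is a variable
on three levels: `-1` (downregulated relative to healthy controls), `0`
(nominal) and `+1` (upregulated). Only the *direction* and *type*
(activator/inhibitor) of each documented interaction enters the model;
magnitudes and kinetics do not. The modeling bet is that the qualitative
feedback structure alone determines which self-sustaining regimes the
system can occupy, even though it cannot say how fast the system moves
between them.

Three balanced ternary operators define a node's preferred next value (its
*image*): the OR of its activators is their maximum, the OR of its
inhibitors likewise; with both kinds present the HIGH/LOW PASS operator
`sign(activators - inhibitors)` balances them; with only inhibitors the
ternary NOT (sign flip) applies; with only activators the aggregate passes
through. The OR/NOT/PASS truth tables are this package's adopted
concretization of the operator family: they reproduce all three branches
of the update rule coherently, are closed and antisymmetric
(property-tested), and validate against the packaged six-state catalogue
(below). They sit behind the single `image_vector()` interface, so a
different table could be swapped in at one place.

Two further structural devices matter:

* **Conditional (gated) edges.** An edge may be active only while a gate
  node holds a required value. The packaged network uses exactly one gate:
  interactions crossing the blood-brain barrier exist only while
  `EndothelialCells` is `-1`, modeling signal leakage through a
  compromised barrier. Gates are evaluated on the *current* state when the
  image is computed, since the update rule is a function of time-t values
  only.
* **External drives.** Nodes tagged `external` (Stress, Toxin) have no
  regulatory inputs and are clamped — by default to 0, configurably — for
  the duration of a simulation. A clamped zero also serves as a floor
  inside OR aggregates, which the curated network exploits (below).

Dynamics are asynchronous: per timestep one node whose image differs from
its value, chosen uniformly, moves one step toward the image (a `-1` with
image `+1` passes through `0`). States equal to their image are stable and
absorbing. Limit cycles are not enumerated; they would surface as runs
that exhaust the step cap, and none do on the packaged network.

## The packaged network and how it was curated

The shipped 36-node model (`gwi_network()`) aggregates the HPA axis (CRH,
ACTH, cortisol, membrane GR and internalized dimerized GRD), the male HPG
axis (GnRH, LH/FSH, testosterone), eight immune cell populations, eleven
cytokine groups (CK1 = IL-2/IFNg/TNFa/TNFb, MK6 = IL-6, MK2 = IL-10/IL-22,
and so on), and a brain compartment (BBB endothelial cells, microglia,
pooled pro-inflammatory cytokines, IL-4, infiltrating T cells, IGF-1,
VEGF). The brain's IL-1b/IL-6/TNFa are one pooled node (`ProInflam_b`)
because the six-regime catalogue describes them as moving as a bloc.

The source description of the network is a figure plus prose; no
machine-readable edge list exists. The package therefore treats the
*stable-state catalogue* as the specification of record: the edge list was
curated so that each of the six described regimes is a fixed point of the
update logic, and so that Monte Carlo attractor search from random states
finds **exactly** those six. Edge directions follow the component biology
(cortisol suppresses GnRH, NK activity and induces IL-10; IL-6 and CK1
cytokines drive the HPA axis; IL-6/IL-10 context promotes Th2; IL-2
expands CTL and Treg; Th17 and Treg wings antagonize; androgens restrain
Th17; dendritic cells prime CTL; microglial activation is fed by
peripheral IL-1-family signals only across a leaky barrier and in turn
suppresses endothelial function). Where several biologically defensible
wirings existed, the one that eliminated spurious attractors was chosen —
for example NK antagonism of Th2 and DC priming of CTL both destabilize
"mirror" states in which an immune wing locks at `-1`; the clamped Stress
input on Treg and CK2 floors those OR aggregates at 0 so that transiently
negative inhibitors cannot disinhibit their targets into relapse.

One catalogue adjustment was made: the prose marks MK15 (IL-15) elevated
in SS5 and silent for SS4, yet blood measures alone are stated to be
unable to separate SS4 from SS5, and IL-15 is on both plasma panels. The
catalogue therefore sets MK15 = +1 in SS4 as well, reading the prose lists
as non-exhaustive. With that adjustment, blood-visible nodes merge SS0
with SS1 and SS4 with SS5 (four anchors), and adding the brain measures
separates SS4 from SS5 — both as described.

The fixed-point identity of all six states, and the exactness of the
six-attractor census from 10,000 random starts, are asserted in the test
suite; they are the acceptance test of the transcription, not edge-by-edge
fidelity, which the available sources cannot support.

## Alignment statistics

A measured condition profile is compared with a predicted state per mapped
variable by Welch two-sample t-tests against the control group: right- or
left-tailed where the state predicts `+1`/`-1`. For a predicted `0` the
package defaults to a Welch TOST equivalence test with a margin of 0.75
pooled standard deviations. The one-sided complement form
`1 - p_two-tail` is available (`zero_mode = "complement"`) and is the
classical description of this step, but it is exactly uniform on null
data, which makes a *confirmed* nominal prediction statistically
indistinguishable from an *unconfirmed* directional one; states whose
signatures nest inside another's (SS0 inside SS3 inside SS4, on blood)
then tie at chance. The TOST form is a valid p-value for the claim the
model actually makes ("this variable sits at nominal") and concentrates
near zero when the data support it; with it, cohorts generated around
every catalogued state are assigned to their generating state in
effectively all seeded replicates, and half-versus-half splits of a
healthy cohort align with SS0 in well over 90% of repeats. The margin
0.75 is half the moderate effect size the cohort generator imprints
(1.5 SD), the usual way an equivalence margin is set against the effect
one wants to rule out.

Per-variable p-values are combined with Brown's method: `T0 = -2 sum ln
p_i` referred to a scaled central chi-square with `2N/c` degrees of
freedom, `c = sigma^2/(4N)`, where `sigma^2 = 4N + 2 sum cov` and each
covariance term is the piecewise-polynomial approximation in the
control-group Pearson correlation (`rho(3.25 + 0.75 rho)` for
`rho >= 0`, `rho(3.27 + 0.71 rho)` for `-0.5 <= rho < 0`). Correlations
below `-0.5`, outside the approximation's domain, are clamped to `-0.5`
with a warning; degrees of freedom below 1 are floored at 1 with a
warning; with `rho = 0` everywhere the method is exactly Fisher's (tested
to 1e-10). State-to-state dissimilarities use the discrete agreement
coding — `p_i = 0.05` (the standard minimum significance, avoiding
`ln 0`) where two states agree on a variable, `p_i = 1` where they
disagree. That floor is *not* applied to measured p-values by default
(`p_floor = 0`): clipping real evidence at 0.05 erases most of the
contrast the ranking relies on; the flag restores it for users who want
the fully floored variant. Rankings are computed on the log scale
(`log_p`) so that deeply aligned states do not tie at the double floor.

Panel harmonization follows the two-multiplex design of the human assays:
each panel is z-scored per variable, the smaller panel's z-scores are
mapped back through the larger panel's mean and SD, and the combined table
is min-max normalized to [0, 1] per variable. Identical panels distorted
affinely recover each other exactly (tested); a zero-variance variable is
an error naming the variable.

## Topology comparison

The state/condition dissimilarities are embedded in 2-D by minimizing the
metric Kruskal stress normalized by the weighted sum of squared
dissimilarities, via SMACOF majorization. Entries involving condition
points carry 10% of the anchor-anchor weight — including
condition-condition entries, when several conditions are embedded at once
— which keeps the anchor geometry fixed to within 0.01 RMSD when
conditions are added (tested at exactly that tolerance). The minimization
is non-convex, so 20 seeded random restarts are run and the best final
stress kept; the achieved stress is attached to the layout. Iteration
stops when stress improves by less than 1e-10 or after 500 iterations.
Coincident points (distance 0) take a zero entry in the Guttman
transform.

Layouts are registered by a least-squares affine map fitted on at least
three non-collinear shared anchors (collinearity is a rank check and an
error) and scored by RMSD over identically labelled points. Cross-species
comparison regresses one species' anchor pairwise distances on the
other's, passes every dissimilarity through the fitted line (negative
values truncated at 0), and re-embeds. Reported RMSDs are computed after
affine alignment to the reference layout.

## Treatment simulation

An intervention is a single-target timed window `(target, effect,
t_start, t_stop)` with effect `+1` (supplement) or `-1` (inhibit). During
each timestep inside the window the target is set to the clipped sum of
its value and the effect — so it reaches the corresponding extreme within
two steps and is held there — and is pinned against the asynchronous
scheduler for that step; one untreated discrepant node still moves per
step. Overlapping windows on the same target are rejected as ill-formed.
After the last window the trajectory continues untreated to a fixed point
or the step cap (default 1000 steps, matching the simulation length used
for course evaluation). A course's outcome, %HHM, is the percentage of
Monte Carlo runs (default 1000) terminating exactly at the healthy
attractor SS0. Treatment windows in the packaged course fixtures occupy
the first ~100 steps; course time is counted in asynchronous update
steps.

The choice to pin treated nodes (rather than let the scheduler also move
them) reads the single-target-per-step constraint as the treatment
consuming the node's update; it makes window length meaningful and is the
package's resolution of an underdetermined point.

## Genetic-algorithm course search

The GA draws a population of random courses (uniform admissible target
and direction; window start uniform over timesteps not already occupied
by a same-target window, stop uniform up to the next obstruction),
evaluates each course's %HHM, carries the top 10% unchanged, and fills
the remainder by single-splice crossover of uniformly chosen pairs from
the whole generation, elites included: the child takes the first parent's
interventions starting before the splice time and the second's starting
at or after it, dropping inherited windows that would overlap a
same-target window (the tie-break keeping children well-formed). The
number of interventions can therefore grow or shrink across generations,
which is inherent to the splice rule; the admissible-target constraint is
enforced throughout. No mutation operator is used. Elites are re-executed
and re-evaluated each generation by default; `frozen_eval = TRUE`
memoizes fitness by course, under which the recorded best fitness is
non-decreasing (tested). `multi_run_best()` repeats the GA and keeps the
best final course, ties to the earliest run.

Admissible interventions for the packaged network are increases of
cortisol, ACTH and testosterone, inhibition of the glucocorticoid
receptor (either form), and bidirectional modulation of all peripheral
cytokine groups.

Configured full scale is population 1000, 1000 generations, 100 repeated
runs; the package's validation runs at desk scale — population 300, 20
generations, 20 evaluation runs per fitness call on the full network, and
a 20-course population on an exhaustively enumerable two-node toy space
where the GA's optimum is checked against brute force over all 42
candidate courses.

## The synthetic cohorts: what they emulate and what they do not

`gen_cohort()` emulates the *shape* of the study data: 51 condition
versus 38 control subjects (the human cohort's sizes), non-negative
right-skewed values (correlated Gaussian on a latent log scale,
exponentiated), equicorrelation 0.3 between variables, and a condition
group mean-shifted on the latent scale by 1.5 SD per blood-visible node
sign of a chosen catalogued state. `split_panels()` separates subjects
into two affinely distorted "multiplex panels" for harmonization tests;
`gen_mouse_counterpart()` emulates the cross-species scenario at the
dissimilarity level — mouse distances a noisy linear transform of the
human ones — because the Brown aggregate is a nonlinear functional of
cohort values, so an exact linear distance relation cannot be imposed
through generated measurements.

Passing recovery tests on these cohorts shows the pipeline is correct and
well-conditioned under its stated model: group shifts aligned with a
single regime's signature, homogeneous correlation, no batch effects, no
missingness, no heavy-tailed assay noise beyond log-normality. It does
not show that real plasma panels separate this cleanly: in practice
effect sizes vary per analyte, correlations are structured, and the
study-level numbers (the 94% hold-out maximum, the per-condition RMSDs)
depend on the measured tables, which users must supply to the same
readers to reproduce them.

## Problem sizes and numerical choices used in validation

The shipped validation uses: 100 random networks of 2-8 nodes for the
Monte-Carlo-versus-enumeration census (10 x 3^N starts each); 10,000
random starts on the 36-node network; 1000-run, 1000-step course
evaluations; 10 replicate cohorts per state for recovery; 50 hold-out
splits; 20 MDS restarts. These are the package's documented defaults for
a reproducible desk-scale run; all are parameters.

## Known limitations

* No kinetics: the model orders regimes, not time courses or doses; a
  course's windows are in update steps, not days.
* The curated network is an aggregate transcription validated against the
  six-regime catalogue, not a molecularly complete wiring; its treatment
  response rates are faithful to its own dynamics, not calibrated to any
  measured cohort, and are generally higher than those reported for the
  larger original wiring (less redundancy means optimal courses fail less
  often).
* Synchronous update, limit-cycle enumeration, network inference from
  data, multi-objective treatment optimization and pharmacokinetics are
  out of scope.
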