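# ternet

Ternary logical modeling of the neuroendocrine–immune network, for
researchers studying chronic multi-system illnesses — Gulf War Illness
(GWI) and related neuroinflammatory conditions — where the question is not
"which molecule is off" but "which self-sustaining regulatory regime is the
body stuck in, and what sequence of interventions moves it back".

## The model

Each signaling entity (hormones of the HPA and HPG axes, immune cell
populations, cytokine groups, brain-compartment players) is a variable
x_i ∈ {−1, 0, 1}: downregulated, nominal, upregulated. The system state is
x(t) = (x_1(t), …, x_N(t)). Interactions are signed edges; the image vector
x(t+1) — the state the system prefers to move toward — is computed per node
with balanced ternary operators:

    x_i(t+1) = ( x^A_i1 ∨ … ∨ x^A_iX ) ∇ ( x^I_i1 ∨ … ∨ x^I_iY )

where ∨ (ternary OR) is the maximum over the node's activators
(respectively inhibitors), ¬ is the sign flip used when only inhibitors are
present, and the HIGH/LOW PASS operator ∇(a, i) = sign(a − i) balances the
two aggregates. Edges may be *conditional*: in the packaged network,
signals cross the blood–brain barrier only while the `EndothelialCells`
node is at −1 (a compromised barrier). Dynamics are asynchronous in the
Thomas style: one discrepant node, chosen uniformly at random, moves one
step toward its image per timestep; a state equal to its image is a stable
state (attractor). Monte Carlo restarts from random states enumerate the
attractors and their basins.

Around this core the package provides:

* **Profile-to-state alignment.** Condition-vs-control panels (e.g. plasma
  cytokine multiplexes) are compared with each model-predicted state by
  directional Welch t-tests per variable — right-tailed where the state
  predicts +1, left-tailed for −1, an equivalence (TOST) test where it
  predicts 0 — combined across correlated variables with Brown's method:
  T0 = −2 Σ ln p_i is referred to a scaled χ² with 2N/c degrees of
  freedom, c = σ²/4N, with σ² picking up covariance terms from the
  control-group correlations. Small aggregate p = aligned.
* **Topology comparison.** The aggregate p-values form a dissimilarity
  matrix embedded in 2-D by weighted metric MDS (Kruskal stress normalized
  by Σd², SMACOF iterations, seeded restarts; condition points carry 10% of
  the anchor weight), registered across conditions or species by an affine
  fit on the stable-state anchors and scored by RMSD; mouse topologies are
  rescaled onto the human distance scale through the anchor-distance
  regression.
* **Treatment simulation and optimization.** Timed single-target
  interventions x(t+1) = x(t) + T(t) (clipped to the ternary range) are
  layered over the asynchronous dynamics; a course's value is the
  percentage of Monte Carlo runs that end in the healthy attractor (%HHM).
  A genetic algorithm (elitism, single-splice crossover) searches course
  space.
* **A curated 36-node network** whose six fixed points (SS0 = health,
  SS1–SS5 = alternate homeostatic regimes, SS5 with a broken blood–brain
  barrier) match the published qualitative state catalogue, plus synthetic
  cohort generators so the full pipeline is testable without any
  participant data.

## Worked example

```r
library(ternet)
net <- gwi_network()
net
#> ternet_network: 36 nodes, 71 edges (2 conditional), 2 external drive(s)

set.seed(1)
find_attractors(net, n_starts = 10000)
#> ternet_attractors: 6 fixed point(s) from 10000 random starts

# synthetic GWI-like cohort imprinted with the SS5 signature (51 ill vs
# 38 controls, blood panel), aligned to the catalogue
co <- gen_cohort(cohort_spec(target_state = "SS5", seed = 7))
al <- align_cohort(co, gwi_states())
signif(al$dissimilarity, 3)
#>  SS0/SS1      SS2      SS3  SS4/SS5
#> 1.86e-01 3.34e-07 1.55e-06 7.12e-15
al$best
#> [1] "SS4/SS5"

# the three-intervention course from the SS5 regime: raise testosterone,
# then inhibit the CK1 cytokines, then inhibit the glucocorticoid receptor
set.seed(1)
simulate_course(published_course("SS5"), setNames(gwi_states()[, "SS5"],
                rownames(gwi_states())), net, n_runs = 1000)
#> ternet_outcome: 83.2% return to health (832/1000 runs)
```

The attractor search finds exactly the six catalogued states. The cohort
generated around SS5 is closest to the merged SS4/SS5 anchor — blood
measures alone cannot separate those two regimes; adding brain measures
(`measured = "blood+brain"`) does. The treatment simulation reports the
fraction of stochastic trajectories that ended in full health (SS0).

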