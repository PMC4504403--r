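---
title: "Measuring potential spatial access: catchments, optimization, and user choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring potential spatial access: catchments, optimization, and user choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accessopt)
library(dplyr)
```

## The measurement problem

Potential spatial access asks what care is *available* to a population given
where people live, where providers are, and how far people are willing to
travel — as opposed to realized access, which is what people actually use.
`accessopt` implements two families of measures over a patient–provider
network and makes them directly comparable:

* **Floating catchment area methods** (gravity, E2SFCA, M2SFCA, 3SFCA).
  These count, for each facility $j$, the decay-weighted demand inside its
  catchment, form a supply-to-visits ratio
  $R_j = S_j / \sum_i V_i\, w(d_{ij})$, and score each community by the
  ratios it can reach: $A^E_i = \sum_j R_j\, w(d_{ij})$ (E2SFCA),
  $A^M_i = \sum_j R_j\, w(d_{ij})^2$ (M2SFCA). The three-step variant adds
  distance-based selection weights
  $G_{ij} = w(d_{ij}) / \sum_k w(d_{ik})$ in both steps, so a community in
  several overlapping catchments is not counted in full by each of them.

* **Assignment models.** The *centralized* model has a planner choose
  fractions $x_{ij}$ of each community's annual visits to minimize

  $$\sum_{ij} d_{ij}\, x_{ij} v_i \;+\; \sum_j \alpha_j \Big(\sum_i r_{ij}\Big)^{\!2},
  \qquad \sum_j x_{ij} = 1,\; x_{ij} \ge 0,$$

  a convex quadratic program whose second term is the total congestion at
  each facility (if $L$ visits share a facility, each experiences $L$ units
  of congestion). The *decentralized* model instead treats every visit as a
  unit player choosing the facility minimizing its own cost
  $d_{ij} + \alpha_j L_j$; the solution concept is a pure Nash equilibrium.

From either assignment the package computes per-community **distance**,
**congestion** (visit-weighted load per unit supply, $F_j = L_j / S_j$),
**coverage** (realized / needed visits), and the composites
$A^E = \text{coverage}/\text{congestion}$,
$A^M = \text{coverage}^2/\text{congestion}$, which sit on the same scale as
the catchment scores. On a single-facility ("circular") system the identity
$A^E = w(d)\,R$ and $A^M = w(d)^2 R$ holds exactly, which the test suite
checks to $10^{-12}$ over a grid of supplies, populations, and weights.

## Willingness to travel

All methods share a decay spec $w(d) \in [0,1]$, non-increasing, with a hard
cutoff (default 150 miles) beyond which a facility is unreachable and
ineligible. The default family is exponential, suited to rare-disease
specialty care where patients travel far; its default rate puts
$w(\text{cutoff}) = 0.01$, i.e. willingness has essentially vanished at the
cutoff. Gaussian, inverse-power, constant (classic 2SFCA), and step-zone
(classic E2SFCA, half-open zones $[D_{r-1}, D_r)$) families are available,
and `calibrate_congestion_weight()` provides the corresponding knob for the
congestion side: it bisects a uniform $\alpha$ until the solved model's
distance-to-congestion cost ratio matches a target, which is how one would
anchor $\alpha$ against observed utilization.

```{r}
autoplot(decay_exponential(cutoff = 150))
```

### Where the decay enters the assignment models

This is the one place the framework is genuinely underdetermined, and the
package's choice is deliberate:

* In the **centralized** model, realized visits are
  $r_{ij} = v_i\, w(d_{ij})\, x_{ij}$ (`decay_scaled = TRUE`, the default):
  willingness thins the visits actually made, so both the congestion load
  and coverage use realized visits and network coverage can fall below
  100%. The *distance* term keeps the raw assigned visits $v_i x_{ij}$.
  Splitting the terms this way preserves the two limit theorems of the base
  model — at $\alpha = 0$ every community is assigned wholly to its nearest
  eligible facility (ties split equally, the $\alpha \to 0^+$ limit), and as
  a uniform $\alpha \to \infty$ facility loads equalize (in the unscaled
  model) — while still reproducing the toy-system coverage and congestion
  table exactly. Scaling the distance term as well would reward sending
  fractions far away precisely because few of those visits happen, which
  breaks the nearest-assignment limit.
* In the **decentralized** model the equilibrium condition has no decay
  term, so each community enters with $\mathrm{round}(v_i\, w(d_{i,\text{nearest}}))$
  unit visits to place. A consequence worth knowing: adding a facility can
  only increase these entry counts, so *total coverage is monotone under
  interventions in the decentralized model*. In the centralized decay-scaled
  model it is not a theorem — on adversarial networks the planner may trade
  realized visits against congestion — which is why the intervention
  monotonicity checks in the test suite use the user-choice model for the
  aggregate claim, mirroring how the composite-measure maps of a case study
  would be produced.

## Solvers and numerical choices

**Centralized.** The QP is solved by exact block coordinate descent: each
community's subproblem (a convex quadratic over its simplex) is solved to
machine precision by bisection on the equalized marginal cost, with
zero-$\alpha$ facilities handled as constant-cost sinks; sweeps repeat until
the maximum complementarity residual, scaled by the largest marginal cost,
falls below `tol` ($10^{-8}$ by default). This exploits the problem's
block-separable constraints and one-rank-per-facility quadratic, so it
scales to networks with hundreds of communities where a dense QP would not.
Two independent oracles guard it: `brute_force_small()` enumerates every
joint active-set pattern on instances up to $3\times3$ and solves each KKT
equality system in closed form (exact for a convex QP — a plain grid search
cannot certify $10^{-6}$ agreement, which is why enumeration is the default
and the grid is kept as a secondary method), and a dense reference QP solver
confirms the objective on a small instance in the tests.

**Capacity.** Optional visit capacities are enforced by projected dual
ascent: a price $\beta_j$ on each capacitated facility is added to its
effective distance and updated by the constraint violation, with the
coordinate-descent solver re-run warm-started between updates. Strong
convexity is required for the dual step, so when every $\alpha$ is zero a
small internal regularization is applied during the capacity solve (the
reported objective always uses the true $\alpha$). Binding facilities are
reported; demand that cannot be placed is absorbed by an optional dummy
facility at twice the network diameter with $\alpha = 0$, which by
construction attracts demand only from communities with no eligible
facility, or from anyone when binding capacities force spillover.

**Decentralized.** Best-response dynamics sweep visits in a fixed order
(community id, then visit index); a visit moves only when it gains more
than $\varepsilon$ (default $10^{-9} \times$ the network diameter) and an
incumbent keeps its seat on ties, which makes the dynamics deterministic
and stable. Because this is a congestion game, each improving move under
equal weights strictly decreases the Rosenthal potential
$\sum d + \sum_j \alpha_j L_j (L_j+1)/2$, logged per sweep; termination at
a pure equilibrium is certified post hoc by `verify_equilibrium()`, and on
tiny instances the tests additionally enumerate *all* joint choice
profiles and confirm the dynamics land on a pure Nash profile.

## What the synthetic generators emulate

`toy_system(6:8)` are the fully specified single-community systems (100
people, one facility with 10, 10, 5 beds and distance weight 0.1, 0.2, 0.2):
they exist to show that the catchment composites collapse distinct
coverage/congestion combinations while the individual optimization measures
separate them. Systems 1–5 are *structural templates* — their geometry is
only described qualitatively in the source figures — so they require an
explicit weight matrix; distances are recovered by inverting the decay, so
weights and distances are always mutually consistent, and a weight of zero
encodes an unreachable pair (System 5's barrier). No invented numbers are
presented as reference values.

`cf_network()` emulates a sparse national specialty-care system for a rare
chronic disease: a county grid with lognormal populations, binomial patient
draws at a prevalence set to hit an expected national count, 10 visits per
patient per year, a 150-mile cutoff, a Medicaid-like subpopulation (default
share 0.3, a deliberate modelling choice — the source does not print one)
restricted to in-state facilities, and identical facilities (1500
visits/year, congestion weight 10, the specialty-care setting) placed
uniformly over populated counties. Defaults are a tenth of the real
system's scale (3000 expected patients, 20 facilities over a
$800\times600$-mile region), chosen once so that catchments overlap the
way the national network's do; the test suite and acceptance script run
further-reduced versions (400–1000 patients, 6–15 facilities) so the whole
analysis replays in minutes on one core. What the generator does *not*
emulate: road distances (euclidean or great-circle only — every analytic
comparison depends only on the $d_{ij}$ values), race/ethnicity-stratified
prevalence, or real facility locations; passing tests therefore certify the
measurement machinery and its orderings, not any real network's magnitudes.

## A known discrepancy, on purpose

For toy System 7 the formula chain gives
$A^M = R\,w^2 = (10/20)\times0.2^2 = 0.02$, while the printed comparison
table in the source literature lists 0.04. The package reproduces 0.02 —
the value its own stated formulas produce — and the tests document rather
than chase the printed number.

## Worked example

```{r}
net <- cf_network(seed = 7, expected_patients = 400, n_facilities = 8,
                  grid_dim = c(8, 6))
net

fit <- solve_access(net, dummy_unmet = TRUE)
glance(fit)

prof <- access_profile(net, fit)
head(prof, 3)

acc <- catchment_accessibility(net, "e2sfca") |>
  transmute(community_id, AE = accessibility)
compare_access(acc, prof, measure = "AE")
```

An intervention — say a new facility in an uncovered area — is a one-liner,
and `access_gain()` reports which communities improved or worsened:

```{r}
worst <- prof$community_id[which.max(prof$distance)]
xy <- net$communities[net$communities$id == worst, c("x", "y")]
net2 <- apply_intervention(net, add_facility("new", x = xy$x, y = xy$y,
                                             supply = 1500,
                                             congestion_weight = 10))
g <- access_gain(prof, access_profile(net2, solve_access(net2, dummy_unmet = TRUE)))
attr(g, "summary")
```

## Limitations

Distances are straight-line or great-circle, not road travel; all patients
share one transportation mode and one decay function; the centralized model
assumes a rational planner and the decentralized one perfectly informed
unit visits; capacities interact with the dual-ascent solver only under
strictly convex congestion; and the comparison statistics inherit the usual
caveats of paired tests on spatially correlated units. The equilibrium
solver guarantees termination only for equal congestion weights (the
general unequal-weight game need not admit a potential); in practice it
converges on all tested instances, and non-convergence is reported
explicitly rather than silently accepted.
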