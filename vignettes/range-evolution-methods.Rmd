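---
title: "Likelihood models of geographic range evolution with founder-event speciation and fossil node constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood models of geographic range evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladorange)
```

## The model

`cladorange` infers the geographic history of a clade on a rooted, dated,
binary phylogeny. Geography is discretized into a small set of **areas**
(for squamates, nine tectonic plates); the state of a lineage is its
**range**, a non-empty set of areas, encoded as a bitmask. Ranges are capped
at a maximum size (four areas in the squamate scheme), which keeps the state
space tractable: with nine areas and a cap of four there are

$$1 + \sum_{k=1}^{4}\binom{9}{k} = 256$$

states, the leading 1 being the null (empty) range, an absorbing extinction
state. States are ordered null-first, then by range size, then by ascending
bitmask, so indices are stable across runs.

Two processes act on ranges:

* **Anagenesis** (along branches): a continuous-time Markov chain with
  dispersal rate $d$ (per source area, per target area, per Myr) adding one
  area at a time while the cap allows, and extirpation rate $e$ (per area per
  Myr) removing one area at a time; a single-area range contracts to the null
  range. The generator $Q$ has rate
  $d \sum_{a \in R} m_{ab}$ for $R \to R \cup \{b\}$ (with $m$ an optional
  multiplier matrix, all ones by default) and $e$ for each $R \to
  R \setminus \{a\}$. Branch transition probabilities are
  $P(t) = e^{Qt}$.

* **Cladogenesis** (at nodes): the parent range is partitioned between the
  two daughters according to the model family. **DEC** allows sympatric
  copying of single-area ranges, subset sympatry (one daughter keeps the full
  range, the other one of its areas) and narrow vicariance (one daughter gets
  a single area, the other the rest). **DIVALIKE** allows copying of
  single-area ranges and every ordered disjoint bipartition of a widespread
  range (widespread daughters permitted), with no subset sympatry.
  **BAYAREALIKE** allows only the exact copy $(R, R)$. Each family
  optionally adds **founder-event (jump) speciation**: one daughter keeps
  $R$, the other colonizes a single area outside $R$, with per-event weight
  $j$.

Per-event weights follow the convention of weighting every non-jump event by
$(c - j)/c$, where $c$ is the number of non-jump event *types* the family
allows (3 for DEC, 2 for DIVALIKE, 1 for BAYAREALIKE), and every individual
ordered jump event by $j$; weights are then normalized to probabilities
within each parent state. Hence $0 \le j < c$, $j = 0$ reproduces the
jump-free family exactly, and raising $j$ strictly lowers the probability of
every non-jump event wherever a jump target exists. Ordered daughter pairs
are enumerated both ways; symmetric self-pairs once.

## Likelihood, constraints and marginals

The likelihood is computed by Felsenstein pruning over the state space. Tip
partials are indicators of the observed range; a child's contribution at its
parent is $P(t)^{\top}$ applied to its partial; the node partial sums the
cladogenetic event probabilities times the two daughter contributions. The
root receives a flat prior over non-null states, and cladogenesis applies at
the root as at any other node. Per-node rescaling with accumulated log
factors prevents underflow. The null range contributes nothing at tips and
no conditioning on survival is applied.

**Fossil node constraints** inject paleontological information: a fossil
assigned to a clade and found in some area forces that clade's ancestral
range to *include* the area. Operationally, the constrained node's partial is
masked to zero on every state lacking any required area, after the
cladogenetic combination. Constraints can only lower the likelihood; an
unsatisfiable constraint yields $-\infty$ (returned, not raised). The
package ships a miniature squamate backbone with the four Jurassic/early
Cretaceous constraints (Toxicofera, Iguania+Anguimorpha, Paleoanguimorpha,
Laterata), each requiring Eurasia, as `paper_constraint_fixture()`.

**Marginal ancestral ranges** are split-point marginals: the probability of
each range at the node immediately before its cladogenetic event, given all
data and parameters. They are computed by an up-pass/down-pass; the
implementation is validated in the tests against the defining identity
$P(v = R \mid \text{data}) = \exp(\ell_{v=R} - \ell)$, where $\ell_{v=R}$
constrains node $v$ to exactly $R$. Whether published node estimates of this
kind are split-point or per-branch ("corner") quantities is generally
ambiguous; this package computes and labels split-point marginals.

## Fitting and model selection

`fit_ml()` maximizes the likelihood over $(d, e)$ on a log scale and $j$
untransformed, by L-BFGS-B from a default start ($d = e = 0.01$,
$j = 0.01$) plus optional seeded random restarts; ties are broken by the
lowest start index. Default bounds are $d, e \in [10^{-12}, 5]$ per Myr and
$j \in [0, c - 10^{-5}]$. The lower bound of $10^{-12}$ is deliberately the
optimizer's floor: range data with no extirpation signal drive $\hat e$ to
the boundary, and reported values of $10^{-12}$ should be read as "at the
floor", not as a measured rate.

Models are compared with
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$, with $k = 2$ (or 3 with
jump) and $n$ the number of tips (the correction is negligible at thousands
of tips but the convention must be fixed), Akaike weights
$w_i \propto \exp(-\Delta_i/2)$, and likelihood-ratio tests for the nested
$j = 0$ comparison. The comparison table uses the fixed row order DEC,
DEC+J, DIVALIKE, DIVALIKE+J, BAYAREALIKE, BAYAREALIKE+J for diffability.

## Summaries

* **Per-area inclusion proportions** (`area_inclusion_proportions()`): the
  summed probability of all states containing an area — a node with 70%
  {Africa}, 25% {Africa+Arabia}, 5% {Arabia} has Africa proportion 0.95.
  Rows do not sum to 1 by construction.
* **Most-probable ranges** (`most_probable_ranges()`): the per-node argmax,
  ties broken by the lowest state index.
* **Event counts** (`count_events()`): comparing parent and child ranges
  along each branch, every area gained is one dispersal unit attributed
  fractionally ($1/|R_\text{parent}|$) to each parent source area, so each
  gained area contributes exactly one unit in total; every area lost
  increments that area's loss count. This operates on point estimates
  (most-probable ranges) and is a counting *convention*, not a stochastic
  mapping; losses conflate anagenetic extirpation with cladogenetic range
  subdivision and are labelled simply "losses".
* **Composite transitions** (`count_composite_transitions()`): ranges are
  classified as Laurasia (subset of the Laurasian areas), Gondwana (subset of
  the Gondwanan areas), Northern Pangaea (mixed ranges whose only Gondwanan
  member is the pivot area, Africa), or Pangaea (any other mixture), with
  Northern Pangaea taking precedence over Pangaea; label changes along
  branches are tallied.

## The forward simulator

`simulate_history()` evolves ranges forward under exactly the model used for
inference: exact stochastic simulation of the anagenetic chain along branches
(exponential waiting times, events proportional to rates) and one
cladogenetic draw per node from the same event table the likelihood uses.
Trees come from a seeded pure-birth (Yule) process (`ape::rphylo` with no
death), matching the extant-only inference setting. Replicates in which any
tip reaches the null range are rejected and redrawn with sub-seed
`seed + attempt * 1000003`; the rejection count is reported, and exhausting
the budget signals that $e$ is too high for the tree depth.

The simulator's full event log, together with the root state, determines the
entire history; the tests replay logs and require exact agreement with the
recorded node states. Cladogenetic draw frequencies are checked against the
event table by chi-square goodness of fit, and anagenetic event rates against
$Q$'s exit rates on long branches.

### Simulation design choices

* **Birth rate.** The generator's default speciation rate is the unit-rate
  Yule convention ($b = 1$ per lineage per Myr). Total tree length of an
  $n$-tip Yule tree is about $(n-1)/b$; at much lower birth rates the tree
  length grows so large that, with any appreciable extirpation rate, nearly
  every extant-tip replicate contains a lineage that passed through the null
  range, and rejection sampling becomes impractical. At $b = 1$ a 300-tip
  tree carries on the order of dozens of anagenetic events under
  $d = 0.02$, $e = 0.005$ — informative but feasible.
* **Recovery experiment scale.** The parameter-recovery tests simulate
  DEC+J histories at $d = 0.02$, $e = 0.005$, $j = 0.1$ on 300-tip trees
  over 5 areas (cap 3) for 10 replicate seeds, refit DEC and DEC+J, and
  require median $\hat d$ and $\hat j$ within a factor of 2 of truth with the
  LRT rejecting $j = 0$ in most replicates.
* **What the simulator does not emulate.** Real data feature extinct
  lineages (ghost ranges), fossil tips, non-Yule branching, area-specific and
  time-stratified dispersal, and coding error in tip ranges. Passing the
  recovery tests shows the inference machinery is self-consistent under its
  own generating model, not that the model is adequate for any particular
  empirical system.

## Numerical choices

* Branch transition matrices use the matrix exponential
  (`Matrix::expm`); inside the likelihood a per-parameter eigendecomposition
  propagator computes all branch matrices cheaply and is validated against
  `expm` at a probe time (falling back to `expm` whenever the generator is
  near-defective). Transition probabilities of magnitude near machine
  epsilon are only accurate in absolute terms — any matrix-exponential
  algorithm shares this limit — so likelihoods that hinge on such
  transitions carry relative error around $10^{-8}$.
* Event-table probabilities must sum to 1 per parent to $10^{-12}$;
  transition-matrix rows to 1 within $10^{-9}$; marginal vectors to 1 within
  $10^{-9}$.
* Node ids follow the `ape` numbering of the tree in memory and are **not**
  portable across Newick round-trips; all serialized per-node outputs
  therefore also carry a two-tip MRCA signature, and `read_true_states()`
  re-resolves a fixture's states onto a re-read tree.
* Degenerate inputs: polytomies, missing branch lengths, duplicate tips,
  null tip ranges and over-cap ranges without an override are rejected with
  named errors; an all-zero constraint mask propagates $-\infty$ rather than
  raising inside the likelihood.

## Known limitations

* No distance- or area-count-dependent dispersal ($x$, $n$ parameters), no
  trait-dependent dispersal, no time-stratified paleogeography; the
  dispersal-multiplier matrix is exposed only as a hook.
* No Bayesian sampling or stochastic mapping; event counts are conventions
  over point estimates.
* No fossilized birth–death trees or serially sampled tips; constraints are
  the only channel for paleontological information.
* The maximum-likelihood surface can be flat in $e$ on extant-only data;
  boundary estimates at the optimizer floor are expected and documented
  rather than suppressed.

## Worked example

```{r example, eval = FALSE}
fix <- paper_constraint_fixture()
geo <- read_geography(system.file("extdata", "synthetic_backbone_ranges.txt",
                                  package = "cladorange"))
fit <- fit_ml(fix$tree, geo$ranges, fix$space, model_family("DEC", TRUE),
              constraints = fix$constraints, seed = 7)
est <- marginal_ancestral_states(fix$tree, geo$ranges, fix$space,
                                 model_family("DEC", TRUE), fit$params,
                                 constraints = fix$constraints)
area_inclusion_proportions(est)
```

The analysis scripts under `analysis/` run this workflow end to end on
simulated data: `01_simulate.R` (data generation), `02_fit_models.R` (six
fits, AICc table, LRT), `03_ancestral_ranges.R` (constrained backbone
estimation, per-area proportions, most-probable ranges) and `04_events.R`
(dispersal/loss/composite-transition counts, including an exact cross-check
of counted dispersal against the simulator's event log).
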