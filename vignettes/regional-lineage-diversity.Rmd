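---
title: "Regional lineage diversity on time-calibrated phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional lineage diversity on time-calibrated phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regiodiv)
```

## The question and the quantity

Continental-island biotas assemble through two processes: immigration from
the mainland and in-situ diversification after isolation. Given a
time-calibrated phylogeny of a clade spanning an island system and its
source regions, one way to separate the two is to ask, for every divergence
event in the tree, *how many lineages already existed in the region where
that divergence most likely happened*. If island divergences consistently
occur against a backdrop of many same-region lineages, diversity is being
built within the island; if they occur when the region is nearly empty,
each island lineage traces back to an independent immigration.

`regiodiv` computes that quantity — the *lineage diversity at a node* — in
three steps on a rooted, ultrametric tree with node ages in million years
(My), over an ordered set of discrete regions (by default `I` Palearctic,
`II` Oriental, `III` Nearctic, `IV` Japanese Archipelago):

1. **Location probabilities.** Every internal node $v$ carries a
   probability vector $p_v$ over regions ($\sum_r p_{v,r} = 1$). These can
   be supplied (BEAST-style node comments or a sidecar table) or
   reconstructed here by continuous-time Markov-chain (CTMC) ancestral
   state estimation.
2. **Regional richness.** For an age $t$, the richness of region $r$ is the
   sum of $p_{v,r}$ over all divergences *older* than $t$, plus the root's
   vector once for the origin lineage:
   $R_r(t) = p_{\mathrm{root},r} + \sum_{v:\,a_v > t} (d_v - 1)\, p_{v,r}$,
   where $a_v$ is the node age and $d_v$ its number of children. This is the
   expected number of lineages attributable to $r$ at time $t$.
3. **Node diversity.** The diversity at a focal node $f$ is the dot product
   $D_f = \sum_r p_{f,r}\, R_r(a_f)$ — the richness the node's own region
   would have seen, averaged over where the node probably was.

Nodes whose *maximum* single-region probability falls below a reporting
threshold (default 0.70) are flagged unprocessed: their diversity is left
blank in table output, but they still contribute to every richness sum.

## Conventions the definition does not fix

The verbal definition of step 2 ("sum over all earlier nodes") leaves three
choices open. They are package settings, echoed in every output's metadata
header, because published tables may have used either alternative:

* **Origin lineage** (`include_origin`, default `TRUE`). Counting the stem
  lineage above the root once, attributed by the root's own vector, makes
  the regional richness sum to the exact lineage-through-time (LTT) count
  at every age: $\sum_r R_r(t) = \mathrm{LTT}(t)$, with value 1 above the
  root and the tip count at $t = 0$. This conservation identity is the
  package's primary invariant and the reason the switch defaults on.
* **Ties** (`strict_older`, default `TRUE`). "Earlier" means strictly
  greater age, so the focal node's own divergence is excluded and the
  richness step function is right-continuous in age. With continuous ages
  ties arise only in contrived input, but the inclusive variant is exposed.
* **Threshold semantics** (`threshold`, default 0.70). The filter reads as
  "maximum single-region probability below 0.70", it applies to *reporting
  only*: an uncertain node's probabilities are still estimates, and
  dropping them from the richness sums would undercount lineages at every
  younger age. Both the filtered flag and the underlying value are kept so
  either reporting convention is recoverable.

On a strictly binary tree with the strict-tie convention, richness and
diversity depend only on node ages and probability vectors — not topology —
which is why `diversity_from_node_table()` can work from a flat published
node summary. Multifurcating nodes count as $d - 1$ simultaneous
divergences, keeping the LTT identity intact.

## The ancestral-state model

The built-in reconstruction treats dispersal as a CTMC with rate matrix $Q$
over $K$ regions running along branches (durations in My). The likelihood
is computed by Felsenstein pruning with per-node rescaling; marginal node
probabilities come from an inside–outside pass, so each node's vector
conditions on *all* tips, not just its descendants.

Three structures are supported: equal-rates symmetric (`ER`, a single rate
$q$; the default and the only one the data in typical regional codings can
usually support), free symmetric (`SYM`), and all-rates-different (`ARD`).
The root prior defaults to the stationary distribution of $Q$ (uniform for
symmetric structures), the neutral choice when the process is assumed at
equilibrium at the origin; a user prior can be supplied. Ambiguous or
unsampled tips get an all-ones vector (standard missing-data treatment).

`fit_rate()` maximizes the likelihood over $q \in [10^{-8}, q_{\max}]$ with
`optimize()` at tolerance $10^{-8}$, deterministically; $q_{\max}$ defaults
to $1000/\mathrm{root\ age}$, far inside the plateau where $P(t)$ has
reached its ergodic limit, and the fit reports a `boundary` status rather
than silently returning an endpoint. Data observed in a single region
cannot identify a rate; the lower bound is returned with a warning and
status `not_identifiable`. For `SYM`/`ARD`, a fixed fan of three starting
points feeds L-BFGS-B on log rates — deterministic by construction, no
random restarts.

These are point-estimate (empirical Bayes) marginals on a fixed tree. They
are **not** a joint Bayesian tree-plus-state posterior: uncertainty in
topology and ages is ignored, and no attempt is made to match any
particular MCMC implementation's priors. For reproducing externally
published probabilities, attach those probabilities directly.

## Numerical choices

* **Matrix exponential.** Equal-rates chains use the exact closed form
  $P_{\mathrm{same}}(t) = \tfrac1K + \tfrac{K-1}{K} e^{-Kqt}$ (for $K = 2$,
  $\tfrac12(1 + e^{-2qt})$); general $Q$ goes through `Matrix::expm()`.
  Either way the result must be row-stochastic to $10^{-9}$ or the call
  errors rather than propagating drift.
* **Scaling.** Inside partials are rescaled at every node (log accumulator),
  so likelihoods of trees with hundreds of tips do not underflow; outside
  vectors are normalized per node, which cancels in the marginals.
* **Probability hygiene.** Input vectors are renormalized when their sum is
  within 0.05 of 1 (covering three-significant-figure rounding in published
  tables, where sums like 0.999 or 1.0006 are routine) and refused beyond
  that, loudly.
* **Ultrametricity.** Tip ages must be 0 within `1e-4` times the root age
  (configurable). Failing trees are refused, never repaired: stretching
  tips would silently shift every richness timing.
* **Clock scaling.** `scale_to_time()` divides substitution-scaled branch
  lengths by a strict clock rate in substitutions/site/My; an interval rate
  (such as the 0.0125–0.0206 band commonly used for invertebrate COI)
  yields an older tree (lower rate) and a younger tree (upper rate).

## What the generator emulates — and what it does not

`simulation_config()` fixes the study conditions for all seeded tests:

* **Tree**: a Yule (pure-birth) tree, grown from two lineages with
  exponential waiting times at total rate $k\lambda$ ($k$ current
  lineages) and a final $\mathrm{Exp}(n\lambda)$ wait to the present.
  Defaults `n_tips = 200`, `lambda = 1` per lineage per My: about the
  sampling depth of a densely sampled regional gastropod phylogeny, with a
  root age around 5 My so that divergences fall on the Plio-Pleistocene
  scale the method targets.
* **Dispersal**: an equal-rates CTMC at 0.1 events per lineage per My from
  a Palearctic (`I`) origin — a moderate rate giving trees that are neither
  monoregional nor fully mixed, the regime where ancestral states are
  estimable but not trivial.
* **Probabilities**: Dirichlet perturbations of the one-hot truth with
  concentration `kappa = 50` on the true region (mean mass
  $50/53 \approx 0.94$ with four regions, matching the sharply peaked node
  probabilities of well-supported empirical reconstructions);
  `kappa = Inf` gives exact one-hot vectors for identity tests.
* **Determinism**: every stage draws from its own substream derived from
  the master seed, so adding draws to one stage never perturbs another, and
  fixtures are byte-identical across runs.

Two integer oracles accompany the truth. `brute_force_region_counts()`
counts each lineage in the region of the divergence that created it —
exactly the estimator's attribution, read from the same convention switches,
so the one-hot identity test checks the arithmetic and cannot silently
re-decide the convention. `occupancy_region_counts()` instead counts the
region each branch *truly occupied* at the focal age (reconstructed from
the recorded jump chain); the difference between the two quantifies the
method's built-in approximation, namely that a lineage is booked to its
region of origin until its next divergence even if it moved in between.

The generator deliberately omits extinction (no birth–death trees),
range-inheritance biogeography (no DEC-style cladogenetic events),
rate variation among branches, and tree uncertainty. Passing tests
therefore demonstrate correctness of the computation under the stated
model, not robustness of the biological method to violations of it.

## Problem sizes

The test suite runs the enumeration cross-check on 200 random trees of up
to 6 tips (the largest size where exhaustive summation over $4^{5}$
internal-state assignments stays exact and instant), the one-hot identity
on 50- and 200-tip fixtures, conservation on 1000 random ages, and rate
recovery on twenty 300-tip simulations at a true rate of 0.1 per My,
accepting a median within [0.07, 0.14]. These sizes keep the full suite
under a minute while covering every code path at the scale of the intended
empirical inputs.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_tips = 60, seed = 7)
paths <- make_fixture(cfg, tempdir())
tt <- read_time_tree(file = paths[["tree"]])
probs <- attach_state_probabilities(
  tt, read.table(paths[["node_probs"]], header = TRUE, sep = "\t"))
tab <- diversity_table(tt, probs)
head(tab)
rtt <- richness_through_time(tt, probs, seq(0, max(tt$ages), length.out = 50))
plot_node_diversity(rtt$nodes, reference_age = 1.7)
```

The package ships, as `extdata/planorbid_node_table.tsv`, the printed
20-node summary of a planorbid snail divergence-time analysis (ages,
support, four-region probabilities, reported diversity).
`diversity_from_node_table()` runs directly on it; note that the reported
diversity column of such a summary is computed over *all* internal nodes of
the source tree, so it can only be reproduced from the full node table, not
from a printed excerpt.

## Known limitations

* Diversity values carry no credible intervals; that would require a
  posterior sample of trees, which the package consumes but does not
  produce.
* The CTMC reconstruction assumes a fixed tree, a homogeneous process and
  (by default) symmetric dispersal; none of these is tested against the
  data beyond the likelihood itself.
* Age point estimates (mean or median, whichever the input carries) drive
  all computations; CI columns are passthrough. The table metadata records
  which annotation key supplied the ages.
* Outgroup handling is the caller's responsibility: richness sums operate
  on whatever tree is supplied, and reproduction of ingroup-only analyses
  should use the pruned ingroup tree.
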