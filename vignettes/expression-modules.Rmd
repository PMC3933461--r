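---
title: "Detecting differential-expression hotspots in weighted interactomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential-expression hotspots in weighted interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expmods)
```

## The problem

Gene-by-gene differential-expression analysis of a case/control microarray
experiment ranks single genes, but coordinated, modest expression changes
spread over an interacting set of proteins are easy to miss. `expmods`
implements a network-level alternative: project per-gene evidence of
differential expression onto a protein-interaction network (PIN), and
search the weighted network for *expression modules* — subnetworks in
which an unusually large number of member genes are differentially
expressed ("hotspots"). The motivating application is transcriptomics of
acute Stanford type A aortic dissection (7 dissected aortas vs 5 donor
controls on a bead-array platform, validated in an independent 4 vs 4
cohort), where a JAK2-centered inflammatory module stood out, but every
stage is generic.

## The model, stage by stage

### Preprocessing

Raw probe intensities pass through the standard bead-array chain:

1. **Detection filtering.** A probe is kept when its detection p-value is
   strictly below `p_thresh` (default 0.05) in at least `min_samples`
   samples; the default generalizes the "5 of 12 samples" rule as
   `ceiling(5/12 * n_samples)`.
2. **Quantile normalization** (via `limma::normalizeQuantiles`), mapping
   every sample to the across-sample mean quantile vector; ties receive
   the mean of the reference quantiles they span.
3. **Flooring and log2.** Background correction can leave negative
   intensities; every value at or below zero is replaced by the global
   minimum positive value before log2. Zeros are floored too — the point
   of the rule is that log2 stays defined, and log2(0) is as undefined as
   log2 of a negative number.
4. **Probe-to-gene collapsing.** Unannotated probes are dropped; probes
   sharing a gene id are averaged per sample, on the log2 scale (the
   chain collapses after transformation, matching the order in which the
   steps are described for the reference analysis).

### Moderated t-statistics

For gene $g$ with pooled two-group variance $s_g^2$ on $d_g = n_1+n_2-2$
degrees of freedom, an empirical-Bayes prior $s_0^2$ with $d_0$ degrees
of freedom shrinks the variance,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad
t_g = \frac{\bar x_{g,\mathrm{case}} - \bar x_{g,\mathrm{control}}}
           {\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

with $t_g$ referred to a t law on $d_0 + d_g$ degrees of freedom.
$(d_0, s_0^2)$ are fitted by matching the mean and variance of
$\log s_g^2$ to the scaled-F model, inverting the trigamma function by
Newton iteration. `prior_df = 0` recovers the ordinary pooled t-test and
`prior_df = Inf` a shared-variance statistic; both limits are verified
against independent oracles in the test suite, and the estimated fit is
cross-checked against `limma::eBayes`, which is never used as the
implementation. Genes with zero sample variance keep $s_g^2 = 0$ and stay
finite through the prior; a non-finite $d_0$ estimate (which a perfectly
homoscedastic simulation legitimately produces) falls back to the
infinite prior with a warning.

False-discovery rates use Storey q-values: $\hat\pi_0(\lambda)$ is the
fraction of p-values above $\lambda$, inflated by $1/(1-\lambda)$,
smoothed by a running mean over the grid $\lambda \in \{0, 0.05, \dots,
0.90\}$ and read off at the largest $\lambda$; if the smoother
degenerates the most conservative (largest) grid estimate is used, and
`pi0 = 1` gives exactly Benjamini–Hochberg, which is how the q-value code
is tested.

### Edge weighting

Each interactome edge $g\!-\!h$ receives

$$w_{gh} = \frac{|t_g| + |t_h|}{2\, t_{\max}},$$

the average of the endpoints' absolute moderated statistics normalized by
$t_{\max}$, the maximum $|t|$ over network nodes, so $w_{gh} \in [0,1]$
with 1 attained exactly when both endpoints carry the maximal statistic;
non-interacting pairs carry no weight. The displayed formula is a
reconstruction from three constraints the reference description states —
combined strength of the two endpoint statistics, normalization by the
maximum absolute statistic, and the unit range — and the normalization is
pluggable (`normalize` argument of `weight_edges()`) for anyone wanting a
different combination rule. $t_{\max}$ is taken over network nodes rather
than all array genes because the normalization is defined on the network;
a flag switches to the all-genes convention.

### Seeded spin-glass module search

Seeds are the `n_seeds` (default 100) network genes with the largest
$|t|$ (ties broken lexicographically; ranking by average incident weight
is available but not default, since absolute-statistic ranking spreads
seeds across the network). Around each seed the community is found by
minimizing the weighted spin-glass (Potts) Hamiltonian

$$H = -\sum_{i<j}\left(w_{ij} - \gamma\,\frac{s_i s_j}{2W}\right)
  \delta(\sigma_i, \sigma_j),$$

where $s_i$ is the strength (weighted degree), $2W$ the total strength —
so $s_i s_j / 2W$ is the configuration-model expected weight of the pair
— and $\gamma$ (default 0.5) the resolution. Spins are restricted to two
states, in or out of the seed's community, over the seed's connected
component with the seed pinned "in". Both the in-group and the out-group
pair sums enter $H$: dropping the out-group term makes the optimum
degenerate (for $\gamma < 1$ the whole component always wins, because the
total weight grows linearly while the null term only grows with
$\gamma$), whereas the two-state form rewards cutting the
expected-but-absent weight between the hot module and the rest. Because
the search is seeded and local it deliberately does not force a mutually
exclusive partition of the whole network; overlapping modules from
different seeds are handled downstream. A 25-state Potts partition would
additionally split the out-group; for the seed's own community the
two-state restriction is what the exhaustive oracle in the test suite
verifies, exactly, on all graphs small enough to enumerate.

Optimization is simulated annealing over membership flips (geometric
cooling from `start_temp` 1.0 to `stop_temp` 0.01 with factor 0.99,
`sweeps` = 5 proposals per candidate node per temperature), followed by
basin hopping: greedy descent to a local minimum, then `hops` = 20 cycles
of kicking the state (each non-seed node flipped with probability
`hop_frac` = 0.25) and re-descending, keeping the best configuration.
The kicks matter: two near-degenerate basins separated by a multi-node
barrier defeat single-flip annealing roughly one restart in three, while
kick-and-descend crosses reliably; with the default 3 restarts the
consensus matches exhaustive enumeration on every ≤12-node test graph at
$\gamma \in \{0.25, 0.5, 1\}$. A seed with no positive-weight incident
edge yields no module ("isolated node of association"), as does a
community smaller than `min_module_size` (default 10).

### Permutation significance

The modularity $M$ of a module is the total weight of its internal edges
(`module_modularity()`, which also reports the average weight per
internal edge). Significance of $M$ is assessed by shuffling the node
statistics over the network with the topology fixed, recomputing the
weights with the same formula and the *same* $t_{\max}$ (immaterial under
pure relabeling, since the statistic multiset is unchanged — which is why
holding it fixed is the safe default), and recomputing $M$ on the fixed
member set; `n_perm` defaults to 1000. The empirical p-value uses the
add-one correction $p = (1 + \#\{M_{perm} \ge M_{obs}\})/(1 + n_{perm})$,
so ties count against the module and $p$ is never zero. Every distinct
grown module is tested and Bonferroni-adjusted across the tested count
(the conservative reading of "adjusted p-value"; `adjust = "none"`
reports the raw permutation p instead). Modules passing `alpha` (default
0.05) are then reported largely non-overlapping: a greedy pass drops the
sparser module of any pair with Jaccard overlap above `dedup_jaccard`
(default 0.5). Adjusting *before* de-duplication keeps the multiplicity
count honest — it reflects every hypothesis actually examined.

Retained modules are ranked by **average weight density** ($M$ divided by
the internal edge count), the size-free reading of "modularity": total
internal weight grows mechanically with module size, so ranking by it
would systematically prefer a hot module plus absorbed periphery over the
hot module itself. The permutation test, by contrast, uses total weight,
whose null distribution on a fixed member set is well defined.

### Downstream: validation concordance and enrichment

A module discovered in one cohort is validated in an independent one by
directional concordance: module genes scored in both datasets are
cross-classified by the sign of their statistics (a 2×2 sign table tested
two-sided by Fisher's exact test), and, under the nominal-significance
filter, counted as "same" or "opposite" when the validation p-value is
below `alpha`. Both readings are reported because published accounts mix
them — the sign table matches a scatter-quadrant reading, the filtered
counts match statements like "22 genes replicated, none opposite".
Gene-set enrichment of a module is the upper-tail hypergeometric test of
its overlap with each set inside a fixed universe, Benjamini–Hochberg
adjusted across sets (small set collections make $\pi_0$ estimation
unstable, so plain BH rather than q-values here).

## What the synthetic-data generator emulates

`simulate_expression()` draws log2 intensities i.i.d. normal around a
common baseline (default 8, noise 1 — typical post-normalization
bead-array scales), with the planted genes mean-shifted in cases; the
default design is 7 cases vs 5 controls. Effects are homoscedastic mean
shifts, matching the two-group t model; `heteroscedastic = TRUE` draws
per-gene variances from a scaled inverse-chi-square law (df 4) when
shrinkage behavior itself is under test. A separate raw-scale generator
(`simulate_raw_probes()`) produces lognormal intensities, detection
p-values, negative background-corrected values and partially annotated
multi-probe genes for exercising the preprocessing chain — the two
generators decouple the preprocessing tests from the network tests.

`simulate_interactome()` builds a preferential-attachment background by
default (real interactomes are heavy-tailed; a uniform-random background
is available), then plants a dense subnetwork: the planted members'
background edges are removed, internal pairs are added to reach at least
`planted_internal_density`, and the module is re-attached through
`planted_bridges` (default 3) bridge edges anchored at background hubs.
The weak coupling is deliberate and is the main caveat to carry over to
real data. Under the $w_{gh}$ formula a cross edge inherits half the hot
gene's weight, so every background neighbor of a strongly-embedded hot
module feels a pull of about $t_{\mathrm{planted}}/2t_{\max}$ per cross
edge; when members keep their full background degree, the recovered
community is the module *plus its absorbed neighborhood* — reproduced
with igraph's independent spin-glass implementation, not an artifact of
this one. Hub-anchored bridges emulate a module attached to the
well-connected core while keeping the ground truth recoverable, which is
what a recovery benchmark needs. Passing the planted-recovery tests
therefore demonstrates correct inference for weakly-coupled hotspots; on
real interactomes, where disease modules shade into their neighborhoods,
reported modules should be read as hotspot-plus-neighborhood, exactly as
the 112-gene module of the motivating study was.

`simulate_validation_stats()` emulates an independent validation cohort:
a `concordant_frac` fraction of module genes replicate (same sign,
magnitude beyond the nominal t threshold at `df` = 6, i.e. a 4 vs 4
design), the rest sit near zero.

## Numerical choices and degenerate inputs

* Ties in seed ranking break lexicographically by gene id; permutation
  ties count against the module; duplicate communities from different
  seeds are collapsed before testing.
* The Hamiltonian comparison tolerance is $10^{-12}$; modularity
  comparisons in the permutation test allow the same slack so that
  exchangeable statistics give $p = 1$ exactly.
* A zero-variance gene is legal input (its t is 0 when its fold-change
  is 0, finite otherwise, thanks to shrinkage); an all-zero statistic
  vector is not a weightable network and raises an error.
* All stochastic stages are pure functions of their seed: `detect_hotspots`
  derives one annealing stream per seed gene and one permutation stream
  per module from `rng_seed`, so reruns are bit-identical.
* Benchmark sizes used by the test suite and the acceptance script —
  300-node networks, 10-gene planted modules at internal density 0.9,
  effect 4 standard deviations, 20 seeded runs, 100 seeds per run, 1000
  permutations — are the package's chosen desk-scale study conditions
  (the seed count and permutation count are the method's defaults; the
  reference analysis applied them to a 6437-protein network, which the
  same code handles with proportionally more compute). Keeping the full
  seed count matters beyond fidelity: the Bonferroni span across tested
  modules is what holds the global-null detection rate down, and it is
  self-balancing — under a global null many mediocre distinct modules
  are tested (heavy correction), under real signal few strong ones are
  (light correction).

## Known limitations

* The two-group design is the only supported contrast (no multi-factor
  or paired designs), matching the scope of the method.
* At $\gamma = 0.5$ the spin-glass model has the usual resolution limit:
  strongly-embedded modules are recovered together with their
  neighborhood (see above), and no attempt is made to post-process
  overlapping communities beyond Jaccard reporting.
* The permutation null holds the member set fixed; modules selected by
  the optimizer for their observed weights carry a selection bias, which
  the Bonferroni adjustment across all tested modules compensates for
  empirically (the global-null detection rate stays at or below twice
  the nominal level in the calibration tests) but does not remove in
  principle.
* MSigDB or other curated gene-set collections are not bundled; any GMT
  file can be supplied.
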