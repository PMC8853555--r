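---
title: "Admixture inference with f-statistics and admixture graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture inference with f-statistics and admixture graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixkit)
```

## The model

All of admixkit rests on one statistical object: the allele frequency
$p_X$ of a biallelic SNP in population $X$, treated as the endpoint of a
random walk down a rooted admixture graph. A drift edge of length $\ell$
(in f2 units) perturbs the frequency with variance $\ell\,p(1-p)$; a pulse
admixture node mixes its two parents' frequencies as
$w\,p_A + (1-w)\,p_B$. Everything measurable then comes from three moments
of frequency differences:

* $f_2(A,B) = E[(p_A-p_B)^2]$ — additive along drift paths, the metric of
  the graph;
* $f_3(X;A,B) = E[(p_X-p_A)(p_X-p_B)]$ — as "outgroup f3" it measures the
  shared drift of $A$ and $B$ beyond an outgroup $X$; significantly
  negative values flag $X$ as admixed;
* $f_4(A,B;C,D) = E[(p_A-p_B)(p_C-p_D)]$ — zero whenever the $(A,B)$ and
  $(C,D)$ paths share no drift edge, which is what makes it the residual
  currency of all model tests here.

Sample allele frequencies are noisy versions of the $p_X$; the estimators
in `estimate_f2()` and `estimate_f3()` subtract the unbiased sampling term
$h/c$ with $h = p(1-p)\,c/(c-1)$ and $c$ the observed allele count, so the
linear identities

$$f_3(X;A,B) = \tfrac12\{f_2(X,A)+f_2(X,B)-f_2(A,B)\},\qquad
f_4(A,B;C,D) = \tfrac12\{f_2(A,D)+f_2(B,C)-f_2(A,C)-f_2(B,D)\}$$

hold *exactly* in the estimates, corrections included (this is asserted to
$10^{-12}$ in the test suite). $f_4$ needs no correction because its two
differences carry independent sampling errors.

Uncertainty comes from a weighted delete-one-block jackknife over
contiguous genomic blocks (default width 0.05 Morgans, never crossing a
chromosome), with block SNP counts as weights — robust to linkage without
modelling it.

## Rank tests and admixture proportions

`build_f4_system()` assembles $X_{ij} = f_4(l_0, l_i;\, r_0, r_j)$ for a
*left* set (a target and its candidate sources) against a *right* set of
reference populations, plus the jackknife covariance of $\mathrm{vec}(X)$.
If the left populations descend from $k$ ancestry streams (relative to the
rights), $E[X]$ has rank at most $k-1$. `rank_test()` fits the
rank-constrained mean by alternating generalized least squares and refers
$\chi^2 = \min_E (x - \mathrm{vec}\,E)^\top Q^{-1} (x - \mathrm{vec}\,E)$
to a chi-squared law with $(|L|-1-r)(|R|-1-r)$ degrees of freedom.
Cladality of a pair is the rank-0 test of its $1\times(|R|-1)$ system.

`fit_qpadm()` reads admixture proportions out of the same factorization:
with left = (target, sources), the model $p_t = \sum_m w_m p_{s_m}$,
$\sum w_m = 1$, forces $\sum_m w_m X_{m\cdot} = 0$, so the weights are the
left null vector of the fitted rank-$(k-1)$ factor, normalized to sum
to one. Negative weights are reported as-is; the filter is the
plausibility classifier (`classify_model()`): a model passes when its
p-value is at least the cutoff (default 0.05) *and* every weight ±2
standard errors lies inside $[0,1]$. Weight standard errors re-run the
full factorization with each block deleted — no linearization shortcut.
`sweep_models()` wraps the three model families used for Mainland
Southeast Asian targets (ESEA alone, ESEA + a deeply diverged
hunter-gatherer surrogate, plus a South Asian surrogate) across surrogate
panels, and averages weights over plausible models.

A practical caveat that the synthetic experiments make vivid: a source's
ancestry stream must be *visible* to the right set. In a clean simulated
graph, a hunter-gatherer stream is invisible unless some right population
is differentially related to that branch; the bundled tests therefore put
one East Asian-clade population and the Iranian-related leaf among the
rights. With real data the same logic governs outgroup choice.

## Graph fitting

`fit_graph()` fits a full admixture-graph topology. The observed side is a
basis of statistics — $f_2(\text{base},X)$ for every leaf $X$ and
$f_3(\text{base};X,Y)$ for every pair — with its jackknife covariance $Q$;
every other $f_2/f_3/f_4$ over the leaves is an exact linear functional of
this basis, which is how residual Z-scores for *all* statistics are
obtained from one covariance estimate. The expected side is linear in the
edge lengths at fixed admixture weights:
$C(X,Y) = \sum_e \ell_e\,a_e(X)\,a_e(Y)$, with $a_e(X)$ the probability
that a lineage from $X$ traverses edge $e$. Fitting alternates

1. an exact non-negative generalized least-squares solve for all lengths
   (an active-set solve on the normal equations, cross-checked against
   `pracma::lsqnonneg` in the tests), and
2. bounded quasi-Newton refinement of the free admixture weights from a
   deterministic lattice of starting points (one-dimensional problems use
   golden-section search). The lattice replaces seeded random restarts so
   that a whole mapping run is bit-reproducible without touching the RNG
   state of surrounding simulations.

The score is $-\tfrac12 d^\top Q^{-1} d$ with $d$ the basis misfit and $Q$
regularized by adding $10^{-4}\bar q$ to the diagonal ($\bar q$ = mean
diagonal). The *worst residual* is the largest $|Z|$ over all leaf
$f_2/f_3/f_4$ statistics.

Identifiability: the two edges meeting at the root are identified only
through their sum (any split of basal drift between them yields identical
statistics), so the self-consistency test checks their sum, and the
trifurcation rule below deliberately ignores them. Edges traversed by no
sampled lineage are reported as zero with a warning.

`compare_fits()` implements the selection rules used throughout: with
different admixture counts the more complex model must gain more than 10
log-units of score *or* drop the worst residual by more than 0.5 SE;
with equal counts, fits within 3 log-units are tied; a fit with a
zero-length internal ("backbone") edge — an unresolved trifurcation — is
discarded before comparison.

## Exhaustive target mapping

`enumerate_attachments()` generates every way of hanging a target on a
skeleton: an unordered set of 1–3 candidate drift edges (the root's child
edges are excluded — attaching there is indistinguishable from attaching
to the basal split). Each chosen edge is split by a new node; two or three
chosen edges feed a cascade of admixture nodes. With $E$ candidate edges
this yields exactly $E + \binom{E}{2} + \binom{E}{3}$ models — for
$E = 33$: $33 + 528 + 5456 = 6017$.

`map_target()` fits them all against one shared observed basis, filters
trifurcations, picks a champion admixture count by the 10/0.5 rules
(walking from simpler to more complex), and returns every model of the
champion count within 3 log-units. Branch lengths are refit for every
candidate; the skeleton's own admixture weights are held at their fitted
values by default (`refit_skeleton_weights = FALSE`) because they are
pinned by the skeleton populations, not the target — the search fits
hundreds of models, and freeing those weights roughly triples the cost for
no measurable change in the selected model in our experiments. Fixed
weights (e.g. an archaic admixture proportion pinned at 3%) are never
re-optimized anywhere.

`build_skeleton()` iterates map-and-adopt one population at a time, and
*halts* on an unresolved tie rather than guessing — adjudicating a tie is
an analyst's decision.

## The synthetic-data generator

`simulate_graph_freqs()` draws the ancestral frequency of each SNP
uniformly (default $U(0.05, 0.95)$), walks it down the graph with
normal increments of variance $\ell\,p(1-p)$ clamped to $[0,1]$, and mixes
at admixture nodes. `sample_genotypes()` then draws diploid calls
binomially with independent missingness (default 2%) and lays SNPs
uniformly over a synthetic genetic map (default 22 chromosomes × 1.5
Morgans, so jackknife blocks have near-equal SNP counts). Defaults mirror
the input class of a Human Origins-style genotyping study: $10^5$ SNPs and
10 diploid samples per population.

Two scales coexist and `truth_stats()` returns both. Graph branch lengths
are in drift units (f2 of parent and child per unit $p(1-p)$); the *data*
produced by the simulator live on the raw frequency scale, smaller by the
root law's mean heterozygosity with exact drift-decay corrections.
`truth_stats()$drift` is the pure graph algebra (delegating to
`expected_stats()`); `$expectation` is an exact second-moment recursion on
the raw scale, and `$effective_lengths` gives each edge's raw-scale
length — the quantity a fit to simulated data estimates. Clamping at the
frequency boundaries is *not* modelled in the recursion: with the default
root law and the bundled graph's edge lengths its bias is at the percent
level on the deepest paths, so tests that compare estimates to the closed
form either use an interior root law ($U(0.2, 0.8)$) or tolerate a few
standard errors. Fitting, rank tests and proportion estimates are
internally consistent on either scale, and no test relies on matching the
absolute statistic values of array-ascertained real data — ascertainment
is deliberately out of the generator's scope.

The normal-increment model was chosen over a Beta (Balding–Nichols) walk
because its first two moments are available in closed form along an
arbitrary graph, which is what turns the generator into an oracle.
Monomorphic post-clamp sites are retained by default (estimators must
tolerate them); `drop_monomorphic = TRUE` removes them.

### The bundled preset

`preset_graph()` builds an 11-leaf graph shaped like the study system:
two deep archaic-like outgroups, an African-like leaf, a West Eurasian
leaf and an Iranian-like leaf, a South Asian-like leaf modelled as an even
mixture of the Iranian-related branch and a deep East Eurasian branch, an
Andamanese-like hunter-gatherer leaf, a Papuan-like deep leaf, and a
three-leaf East/Southeast Asian clade. `preset_graph(target_mix = ...)`
attaches a target carrying any chosen blend of ESEA, hunter-gatherer and
South Asian-related ancestry — the three-way model space used for
Mainland Southeast Asian populations. Branch lengths were set once to
plausible magnitudes (deep splits near 0.1, within-clade splits
0.01–0.03) and are not tuned per test.

## Problem sizes used in the validation suite

The acceptance tests run at desk scale, chosen once: jackknife
calibration on 200 simulations of $10^4$ SNPs in 20 blocks; rank-test
type-I error on 500 null replicates of $10^4$ SNPs; weight recovery
(truth 0.7) on 200 replicates of $2\times10^4$ SNPs with 10 diploids per
population; placement recovery on 50 replicates of $2\times10^4$ SNPs —
20 unadmixed, 20 one-wave (10% South Asian-like), 10 two-wave — against
candidate sets of 10 and 6 edges respectively. At these sizes the
one-wave signal is unambiguous ($\gg$10 log-units) and recovery is
expected to exceed 90%.

## Known limitations

* No linkage, selection, sequencing error or ascertainment in the
  generator; jackknife blocks exist to absorb linkage in real data, but
  the calibration checks here run on exchangeable SNPs.
* The drift approximation degrades above $\ell \approx 0.1$ per edge
  (warned at construction) and boundary clamping biases deep-path
  statistics slightly downward.
* qpAdm-style weights are only as identifiable as the right set makes
  them; the package reports large standard errors rather than refusing,
  and the plausibility classifier is the intended filter.
* `rank_gls()` alternation is monotone and in practice converges in a
  handful of iterations, but it targets a local minimum of a biconvex
  problem; the SVD warm start makes the global optimum the practical
  outcome in all tested systems.
* Branch lengths returned by `fit_graph()` on simulated data are on the
  raw data scale, not the generator's drift-unit scale (see
  `truth_stats()$effective_lengths`).
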