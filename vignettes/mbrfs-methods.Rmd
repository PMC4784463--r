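---
title: "Repeated-fishing Markov blanket selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeated-fishing Markov blanket selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given a high-dimensional omics matrix (SNP dosages, methylation, expression,
metabolites) and a phenotype `Y`, we want the *Markov blanket* of `Y`: a
minimal marker set `MB(Y)` such that every other marker is conditionally
independent of `Y` given `MB(Y)`. Unlike marginal testing with Bonferroni or
B-H correction, a blanket search can separate truly phenotype-related markers
from markers that are merely correlated with them (e.g. SNPs in linkage
disequilibrium, LD, with a causal variant); unlike penalised regression it
comes with an explicit conditional-independence semantics.

A classical single-blanket search (forward admission under conditional
independence tests, backward removal of false positives) degrades in exactly
the setting it is most needed: with many true signals, the stratified
G² test must condition on every admitted member, and the contingency table
grows as `Cat(Y) × Cat(V) × ∏ Cat(Cᵢ)` cells. With a binary phenotype and
ternary SNP dosages, nine admitted members already give
`6 × 3⁹ = 118 098` cells — unfillable at any realistic sample size, so the
test loses all power and the search stalls after a handful of markers.

`mbfish` implements the repeated-fishing variant of this search:

1. **Screen** all markers marginally at `screen_alpha` (default 0.05;
   Cochran–Armitage trend test for SNP dosages, regression Wald tests
   otherwise) to form the candidate pool.
2. **Fish one round**: grow a blanket by forward admission, where a candidate
   must be dependent on `Y` given *each single current member* (first-order
   conditioning — tables never exceed `Cat(Y)·Cat(V)·Cat(C)` cells); among
   dependent candidates the one with the smallest worst-case p is admitted.
   After each admission the pool is LD-pruned (markers within `ld_window`
   positions of the admitted marker and with genotype `r² > r2_threshold`
   are dropped) and the blanket is backward-pruned (members no longer
   dependent given each other member are removed, most recent first).
3. **Empty the net**: remove the round's members from the pool and fish
   again.
4. **Stop** at the first round that returns at most `stop_size` members
   (default 2), or when the pool or blanket empties.

The conditional-independence backends are the stratified G² likelihood-ratio
test for categorical data, and Wald tests from logistic (binary `Y`,
quantitative markers) or linear (quantitative `Y`) regression.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `screen_alpha` | 0.05 | marginal screening level; 0.01 is a sensible preset at GWAS scale |
| `alpha` | 0.05 | admission/removal level of the conditional tests |
| `r2_threshold` | 0.05 | genotype r² above which a neighbour of an admitted marker is pruned |
| `ld_window` | 20 markers | half-width of the pruning window, in marker-index units (marker order in the input defines distance; 0 disables) |
| `stop_size` | 2 | a round this small terminates the fishing loop |
| `include_terminal_round` | FALSE | whether the terminal round's members are reported (below) |
| `cell_cap` | 10⁶ | hard refusal threshold for stratified-table size (full conditioning only) |

All defaults are nominal-level conventions rather than fitted quantities;
`r2_threshold` and `ld_window` follow the common practice of collapsing an
LD block once one of its SNPs is captured.

## The terminal round

The stopping rule fires on the first round with at most `stop_size` members —
the cast in which the net came up nearly empty. Whether that round's members
belong in the reported set is genuinely ambiguous. We resolved it
empirically: on replicated synthetic studies with eight causal SNPs the
terminal round consists of false positives in essentially every replicate
(once the true signals are exhausted, the next round can only anchor on the
best-surviving null marker), and under the global null the terminal round is
the *only* nonempty round, so including it guarantees false positives.
Excluding it leaves the true-discovery rate essentially unchanged (strong
markers are occasionally caught late, costing a few percent) while lowering
the false-discovery rate by roughly a third. The default is therefore
`include_terminal_round = FALSE`; this convention targets the
many-signal screening regime. When the expected blanket is small — at most
`stop_size` markers, as in validating a single known pathway or the
causal-chain checks in the test suite — the *first* round is itself the
terminal round and excluding it would return nothing, so such analyses
should set `include_terminal_round = TRUE`.

Members removed by the backward phase do not return to the pool: they were
admitted and then judged explainable by the rest of the blanket, and
re-admitting them in later rounds would recycle the same false positives.

## Decision conventions in the tests

* G² uses the convention `O·ln(O/E) = 0` when `O = 0`; rows, columns and
  whole strata with a zero margin are dropped and their degrees of freedom
  subtracted. When nothing is dropped the df equals the product formula
  `(Cat(Y)−1)(Cat(V)−1)·∏Cat(Cᵢ)`.
* If more than 20% of the retained expected cell counts fall below 1, the
  test reports itself unreliable and the caller treats the pair as
  independent — the conservative reading of a table too sparse for the
  asymptotic approximation. This is what makes full-blanket conditioning
  self-limiting in the single-round legacy mode.
* Regression backends use the Wald test of the target coefficient (df 1);
  non-convergence, separation-inflated standard errors and aliased
  (collinear) covariates yield the same unreliable signal.
* Forward ties (identical worst-case p) break by smaller marginal p, then
  lower marker index, making the whole search deterministic for fixed data.

## What the synthetic-data generator emulates

Genotypes are produced by thresholding latent Gaussians at the
Hardy–Weinberg quantiles of each marker's allele frequency, so marginal
genotype frequencies are exactly `(q², 2pq, p²)`. LD is induced through the
latent correlation: an exchangeable factor for the named regimes (latent
0.40 / 0.80 / 0.995 calibrated once, by simulation, to genotype r² of about
0.1 / 0.4 / 0.85 — the "low", "modest" and "high" bands), or an AR(1) chain
for distance-decaying LD. High-LD blocks share a single block MAF and
modest blocks jitter around one, since tight LD implies similar allele
frequencies.

The default study layout is 22 regions × 50 SNPs (1100 markers), a source
population of 100 000 individuals, and a logistic disease model
`P(Y=1|G) = expit(α₀ + Σ log(ORⱼ)·Gⱼ)` whose intercept is solved numerically
for a baseline prevalence of 0.10 (a common simulation convention; the
prevalence is configurable and mainly shifts the case-control sampling
ratio). Four placements of the eight causal SNPs are supported: independent
insertion (replacing one background column in each of eight regions, so the
marker count stays 1100), correlated insertion (an exchangeable
latent-Gaussian copula calibrated so realized genotype correlation is
~0.10), in-block causal SNPs sharing their region's LD, and a three-region
high/modest/low layout with one causal SNP (OR 1.5) per region. Effect-size
schemes: all-null (OR 1), OR 1.1–1.8, OR 1.3 with MAFs spread over
0.05–0.5, and OR 1.2 everywhere (all effects below the Bonferroni
threshold). Background regions cycle through the low/modest/high regimes
with MAFs uniform on 0.05–0.5.

`simulate_case_control_study()` draws 1000 cases and 1000 controls without
generating the full background population: markers carrying no phenotype
information are independent of case-control selection, so only the causal
columns (or causal-bearing regions) are generated at population scale. This
is an exact shortcut, not an approximation, and makes replicated
benchmarking cheap; `make_scenario()` retains the full-population path.

What the generator does *not* emulate: real haplotype block boundaries and
recombination hotspots, allele-frequency spectra, genotyping error and
missingness, population structure, or the empirical joint distribution of
LD and MAF in any particular population. A consequence that matters for
benchmarking: the *effective number of independent background tests* in
this parametric genome is larger than in a genotype panel derived from real
haplotypes, so more chance-significant null markers survive screening as
mutually independent candidates, and the repeated-fishing loop admits a few
more of them before it terminates. Replicated runs therefore reproduce
reference true-discovery rates closely while running 0.1–0.2 higher in
false-discovery rate than studies built on real-haplotype simulators; the
package's evaluation reports make this visible rather than hiding it.
Passing tests demonstrate correct behaviour *under this generator*, not
performance claims for any particular real dataset.

## Evaluation conventions

Flat scoring counts exact index hits: `TDR = TP/|truth|`,
`FDR = FP/(TP+FP)` (0/0 → 0), and the Matthews correlation coefficient with
the zero-factor convention. Cluster scoring, used when causal markers sit
inside LD blocks, counts a true-positive cluster for each causal marker
that has a captured marker within 20 positions and `r² > 0.05`, merges
remaining captures no more than 10 positions apart into single
false-positive clusters, and computes TDR/FDR/MCC on clusters; its TN term
uses index units (`n_markers` minus markers involved in any cluster), an
approximation we document rather than defend. Across replicates all
metrics are means of per-replicate values, which keeps the 0/0 convention
local to each replicate. Per-marker discovery rates are percentages of
replicates in which the marker was selected.

## Problem sizes in the shipped studies

The replicated studies run at 100 replicates (200 for the null study) with
1000 cases, 1000 controls and 1100 markers — the reference design at a
desk-friendly replicate count; chain-recovery checks use n = 50 000 with a
dozen markers. At these sizes the binomial standard error of a TDR around
0.8 is about 0.01–0.02, and the extreme per-SNP discovery rate under the
null (the maximum over 1100 markers of a ~0.2% per-marker rate at 200
replicates) is itself a noisy statistic whose typical value is about 1.5–2%.

## Known limitations

* First-order conditioning cannot reject a null marker whose chance
  marginal association is not mediated by any other marker; such markers
  are controlled only by the stopping rule, which is why the terminal-round
  convention matters.
* The G² backend assumes categorical (0/1/2) markers; quantitative markers
  must use the regression backends.
* The LASSO comparator's tuning (10-fold CV, one-standard-error rule) is a
  convention, not a reproduction of any particular reference analysis.
* LD pruning and cluster scoring measure distance in marker-index units;
  physical distance is deliberately out of scope.
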