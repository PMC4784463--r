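# mbfish — repeated-fishing Markov blanket selection for omics data

`mbfish` selects phenotype-related biomarkers from high-dimensional omics
data (SNP dosages, methylation, expression, metabolites) by repeatedly
constructing Markov blankets of the phenotype. It is aimed at
biostatisticians and genetic epidemiologists who want conditional-
independence-based feature selection — markers that carry information about
the phenotype *given* the other selected markers — rather than marginal
test lists or penalised-regression support sets.

## The method

The Markov blanket `MB(Y)` of a phenotype `Y` is a minimal marker set such
that `V ⊥ Y | MB(Y)` for every other marker `V`. A single blanket is grown
by forward admission and backward pruning, with two modifications that keep
the conditional-independence tests powered in high dimensions:

* **First-order conditioning.** A candidate must be dependent on `Y` given
  each *single* current member, instead of given all members jointly. The
  stratified G² likelihood-ratio statistic
  `G² = 2 Σ Oᵢ ln(Oᵢ/Eᵢ)` (asymptotically χ² with
  `df = (Cat(Y)−1)(Cat(V)−1)·∏Cat(Cᵢ)`) then never faces more than
  `Cat(Y)·Cat(V)·Cat(C)` cells — whereas full conditioning on nine ternary
  members would already require `6 × 3⁹ = 118 098` cells.
* **Repeated fishing.** After a blanket is built, its members are removed
  from the candidate pool and the search restarts on what is left, so each
  round's conditioning sets stay small. The loop stops at the first round
  that returns at most two markers.

Marginal screening (Cochran–Armitage trend test for SNPs, regression Wald
tests otherwise) forms the initial pool; LD pruning removes markers with
`r² > 0.05` within 20 positions of each admitted marker. Logistic and
linear regression backends extend the conditional tests to quantitative
markers and phenotypes. The package also ships the comparison methods
(trend test with Bonferroni or Benjamini–Hochberg correction, L1-penalised
logistic regression, single-round blanket search with full conditioning), a
block-LD genotype simulator with a logistic disease model, and TDR/FDR/MCC
benchmarking with cluster-based scoring for markers inside LD blocks.

## Worked example

Simulate a case-control study with eight independent causal SNPs
(odds ratios 1.1–1.8, MAF 0.3) hidden among 1100 SNPs, and fish:

```r
library(mbfish)
spec <- scenario_spec(1, 2, seed = 42)   # scenario 1, effect scheme 2
d <- simulate_case_control_study(spec)
d
#> genotype_dataset: 2000 samples x 1100 markers (binary phenotype)
#>   cases: 1000, controls: 1000
#>   causal markers: r01_s24, r04_s07, r05_s36, r10_s25, r15_s37, r16_s46, r17_s20, r22_s26

res <- run_mbrfs(d)
res
#> MBRFS: 2 round(s), 5 marker(s) selected
#>   round 1: 820, 796, 1076, 737, 475
#>   round 2: 236, 678
#>   pool trace: 68 -> 63 -> 60
#>   selected: r10_s25, r15_s37, r16_s46, r17_s20, r22_s26

ev <- evaluate_flat(res$final_set, d$truth, ncol(d$genotypes))
sprintf("TDR %.2f  FDR %.2f  MCC %.2f", ev$tdr, ev$fdr, ev$mcc)
#> "TDR 0.62  FDR 0.00  MCC 0.79"
```

Round 1 captured the five strongest causal SNPs (odds ratios 1.4–1.8); the
pool trace shows the candidate pool shrinking as members and their LD
neighbours are removed. The terminal two-marker round — the cast in which
the net came up nearly empty — is not reported by default (see the methods
vignette). The three weakest causal SNPs (OR 1.1–1.3) were missed in this
replicate: at this sample size their discovery is probabilistic, which is
why method comparisons are run over replicates with
`run_simulation_study()`.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/mbfish.R simulate --scenario 1 --scheme 2 --seed 1 --out data.raw
Rscript inst/cli/mbfish.R run --genotypes data.raw --format plink_raw --out hits.tsv
Rscript inst/cli/mbfish.R bench --config study.yaml --reps 100 --seed 1
```

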