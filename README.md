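# trajFPC

Trajectory differential expression testing for single-cell RNA-seq via
functional principal components.

## The problem

After trajectory inference, each cell carries a pseudotime value ordering
it along a developmental process. A *temporally differentially expressed
gene* (TDEG) is a gene whose mean expression varies along that ordering.
Existing per-gene GAM-style tests lose type-I-error control under the
heavy zero inflation of scRNA-seq dropout, and they ignore the covariance
structure genes share along the trajectory. trajFPC is for analysts who
already have a pseudotime ordering (e.g. from Monocle3) and want a
calibrated, covariance-aware TDEG test.

## The method

Each gene's log-transformed, centered expression is smoothed as a function
of pseudotime with roughness-penalized B-splines. The across-gene
covariance operator C(s,t) is eigendecomposed,

    ∫ C(s,t) Φ_k(s) ds = λ_k Φ_k(t),

and gene *i* is scored by the squared norm of its functional principal
component (FPC) scores

    D_i = Σ_k ξ_ik²,   ξ_ik = ∫ f_i(t) Φ_k(t) dt,

the squared L² distance between the zero function and the gene's
projection onto the retained eigenspace — a projection norm, not a
variance ratio, so it stays stable when profiles are mostly zeros.
Significance comes from a pooled permutation null (pseudotime labels
shuffled across cells, eigenbasis held fixed):

    p_i = (1 / BG) Σ_b Σ_g I{ D_g^(b) ≥ D_i }.

A two-stage refinement re-estimates the eigenbasis from the top 25% of
genes ranked by D (trajectory-informative genes) before the final
projection, protecting the basis from dilution by flat, zero-inflated
profiles. TDEGs are called on BH-FDR q-values. A seeded zero-inflated
negative-binomial trajectory simulator with ground-truth labels and a
benchmark harness (type-I error, power, ROC-AUC) are included.

## Worked example

```r
library(trajFPC)

sim <- simulateTrajectoryData(trajSimConfig(
  nGenes = 1000, nTdeg = 150, nCells = 300, seed = 1))
res <- runTrajFpcTest(sim, permutations = 100, seed = 2)
res
#> TrajFpcResult: 1000 genes
#>   components retained: 2 | lambda = 0.4641589 | B = 100
#>   TIGs: 250 | TDEGs ( q < 0.05 ): 13

tab <- resultTable(res)
head(tab[order(tab$p), c("gene_id", "D", "p", "q", "is_tdeg")], 5)
#>      gene_id           D     p     q is_tdeg
#> 53  gene0053 0.017331159 0e+00 0.000    TRUE
#> 95  gene0095 0.027184116 0e+00 0.000    TRUE
#> 106 gene0106 0.015130217 0e+00 0.000    TRUE
#> 126 gene0126 0.010521140 0e+00 0.000    TRUE
#> 107 gene0107 0.008524202 3e-05 0.006    TRUE

truth <- SummarizedExperiment::rowData(sim)$isTDEG
rocAuc(tab$p, truth)
#> [1] 0.8605412
typeIErrorPower(tab$p, truth)
#>   alpha        tier     power
#> 1  0.01 0.008235294 0.2800000
#> 2  0.05 0.028235294 0.4666667
#> 3  0.10 0.074117647 0.5933333
```

Reading the output: two eigenfunctions carried ≥90% of the functional
variance; the GCV-selected penalty was λ ≈ 0.46; 13 genes pass FDR 0.05,
all true simulated TDEGs here. `D` is the per-gene distance statistic,
`p` the pooled permutation p-value (resolution 1/BG; exact zeros are
possible under the literal pooled estimator), `q` its BH adjustment.
Observed type-I error sits at or below each nominal level while the
p-value ranking separates true TDEGs from nulls (AUC 0.86 at this reduced
size). For real data, replace the simulated object with
`readExpressionMatrix()` + `readPseudotime()` input, or any
`SingleCellExperiment` with a `pseudotime` column in its `colData`.

A command-line wrapper with `simulate`, `test`, `benchmark` and `embed`
subcommands ships at `inst/scripts/trajfpc-cli.R`; the methods vignette
(`vignettes/trajectory-fpc-methods.Rmd`) documents the model, the
parameter defaults, and the simulator's scope.

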