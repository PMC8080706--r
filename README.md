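# ragnmf

Prioritization of candidate cancer **driver genes** from a binary
samples × genes somatic mutation matrix, without tumor subtype labels.

Cancer cohorts are heterogeneous: each latent subtype carries its own
drivers, mutated in only a fraction of patients, while most mutated genes
are passengers. `ragnmf` separates the two by embedding every gene's
mutation profile in a low-dimensional non-negative subspace with a robust,
adaptive, graph-regularized non-negative matrix factorization:

```
min over U, Z, W, M ≥ 0 of
    Σ_{s,g} M_s W_g (X − U Zᵀ)²_{sg}  +  λ Tr(Zᵀ L Z)  +  α‖W‖² + β‖M‖²
    subject to  Σ_g W_g = C_w,  Σ_s M_s = C_m
```

where `U` (samples × k) is the basis, `Z` (genes × k) the gene
coefficients, `L = D − S` the Laplacian of a Gaussian-kernel gene
similarity graph under a sample-weighted metric, and `W`, `M` diagonal
robustness weights on genes and samples that adaptively down-weight noisy
genes and outlier samples (solved exactly on a scaled simplex each
iteration). A gene's **mutation score** is the maximal coordinate of its
coefficient vector, its **subgroup** the argmax; ranked candidates are
evaluated against benchmark gene sets (GMT/MSigDB format) with upper-tail
hypergeometric overlap tests.

The package covers the full pipeline: MAF binarization and matrix/GMT I/O,
the solver (with plain GNMF and sparse "driversub" modes as degenerate
cases), gene scoring/ranking/subgrouping, enrichment reporting, a
synthetic heterogeneous-cohort generator with planted ground truth, and a
command-line interface.

## Worked example

Simulate a 120 × 400 cohort with 4 subgroups of 10 planted drivers each
(driver rate 0.5 within subgroup vs 0.02 background, plus 5% noisy genes
and 5% outlier samples), fit, rank, and evaluate:

```r
library(ragnmf)

cohort <- simulate_cohort(cohort_spec(seed = 1))
X <- filter_genes(cohort$matrix)
#> filter_genes: dropped 7 of 400 genes with < 1 mutated samples

fit <- ragnmf_fit(X, ragnmf_config(seed = 1))
fit
#> ragnmf_fit (mode = ragnmf): 120 samples x 393 genes, k = 4
#>   201 iteration(s), converged, final objective 9938.24

ranking <- rank_genes(fit$genes, gene_scores(fit$Z), assign_subgroups(fit$Z))
head(ranking, 5)
#>    gene     score rank subgroup
#> 1 G0029 0.2941595    1        1
#> 2 G0016 0.2633914    2        3
#> 3 G0018 0.2612421    3        3
#> 4 G0015 0.2491468    4        3
#> 5 G0039 0.2352504    5        4

met <- recovery_metrics(ranking, cohort$truth, 40)
cat(sprintf("precision@40 = %.3f, recall@40 = %.3f, ARI = %.2f\n",
            met$precision, met$recall, met$ari))
#> precision@40 = 0.975, recall@40 = 0.975, ARI = 1.00
```

The top of the ranking is almost exactly the 40 planted drivers
(precision/recall 0.975), and their subgroup labels reproduce the planted
subgroup structure perfectly (adjusted Rand index 1.0). Testing the top-40
candidates against the planted driver sets, written as a GMT file, gives
one upper-tail hypergeometric result per set:

```r
gmt <- tempfile(fileext = ".gmt")
write_gene_sets(cohort$truth$driver_genes, gmt)
report <- benchmark_report(top_candidates(ranking, 40),
                           read_gene_sets(gmt), fit$genes)
report$results[, c("set_name", "set_size", "overlap", "p_value")]
#>    set_name set_size overlap      p_value
#> 1 subgroup1       10      10 3.928199e-11
#> 2 subgroup2       10      10 3.928199e-11
#> 3 subgroup3       10       9 4.512360e-09
#> 4 subgroup4       10      10 3.928199e-11
report$summary$mean_p
#> [1] 1.16e-09
```

The adaptive weights do the robustness work: after this fit the planted
noisy genes carry mean weight 0.094 while planted drivers keep 0.833, and
with the weights disabled (`mode = "gnmf"`) precision@40 drops to about
0.5 because hypermutated noise floods the top of the ranking.

For real data, start from a MAF instead: `maf_to_matrix("cohort.maf")`
binarizes nonsilent coding variants (configurable), and
`read_gene_sets("c2.all.vX.symbols.gmt")` loads MSigDB benchmarks. The
default configuration (`k = 4`, top-500 candidates) matches the standard
breast-cancer pipeline setting.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ragnmf", package = "ragnmf"))')
$CLI simulate --out cohort/ --seed 7
$CLI fit      --matrix cohort/mutation_matrix.tsv --out model/ --k 4 --seed 7
$CLI rank     --model model/ --out ranking.tsv --top 500 --candidates-out top.txt
$CLI enrich   --candidates top.txt --gmt cohort/driver_sets.gmt \
              --universe universe.txt --out report.tsv
```

Exit codes: 0 success, 2 usage/format error, 3 numerical failure. Every
command logs its resolved configuration and seed to stderr.

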