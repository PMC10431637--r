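# nablafuse

Gradient-domain fusion of co-registered multimodal medical images (CT/MR
and similar), with objective fusion-quality metrics and the full
rank-based statistical protocol for comparing fusion methods.

## What it does

Complementary modalities show different structure: CT renders bone and
dense lesions, MR renders soft tissue. `nablafuse` merges such images in
the **gradient domain**:

1. each image `U` becomes a vector field by the discrete Nabla operator
   (central differences, unit step):
   `P(x,y) = (U(x+1,y) − U(x−1,y))/2`, `Q(x,y) = (U(x,y+1) − U(x,y−1))/2`;
2. the fields are fused pixelwise by **weighted averaging**
   (`P̄ = Σ wᵢPᵢ / Σ wᵢ`), **pointwise maximum**, or **PCA weighting**
   (leading eigenvector of the per-component covariance across pixels,
   absolute-normalized to sum 1);
3. the fused image is recovered by solving the discrete Poisson equation
   `4U(i,j) − U(i±2,j) − U(i,j±2) = b` (the stride-2 stencil arising from
   composed central differences; a standard 5-point stencil is optional)
   with synchronous Jacobi iteration under zero Dirichlet boundaries —
   contraction factor `cos(π/(n+1))`, a-priori sweep bound
   `m > 2(1−α)((n+1)/π)²` — followed by DC (mean) restoration.

The package also provides the evaluation stack used to *compare* fusion
methods: entropy, STD, average gradient, edge intensity, mutual
information, SSIM and the Qabf edge-transfer measure; and a statistics
suite — Friedman test (`χ²_F`, its F form, and the `SSt/SSe` form),
critical-difference post hocs (Siegel–Castellan and Bonferroni–Dunn), and
Holm/Hochberg step procedures against the best-ranked method. A seeded
phantom generator produces CT-like/MR-like complementary pairs so the
whole pipeline is testable without any external data.

## Worked example

```r
library(nablafuse)

ph <- make_phantom_pair(size = 64, kind = "ct_mr", seed = 20230816)
fz <- nabla_fuse(list(ph$A, ph$B), rule = "pca", max_iter = 3000)
fz
#> <nabla_fusion 64x64> rule = pca, 1990 Jacobi sweeps (converged)
round(fz$weights$P, 3)
#> [1] 0.957 0.043

evaluate_fusion(fz$image, list(ph$A, ph$B))
#>               metric      value   orientation
#> 1            entropy 2.70915019 higher_better
#> 2                std 0.19888854 higher_better
#> 3   average_gradient 0.04101626 higher_better
#> 4     edge_intensity 0.40274461 higher_better
#> 5 mutual_information 3.34604185 higher_better
#> 6               ssim 0.63377641 higher_better
#> 7               qabf 0.75905423 higher_better

# gradient-domain fusion transfers far more edge information than naive
# pixel averaging of the same pair:
qabf((ph$A + ph$B) / 2, ph$A, ph$B)
#> [1] 0.4761307
```

The PCA weights (0.957/0.043 here) show the rule siding with the
gradient-dominant CT-like source; Qabf 0.759 vs 0.476 for naive averaging
quantifies the edge information preserved by fusing in the gradient domain.

Statistical comparison from a printed mean-rank table (9 methods, N = 36
samples = 9 metrics × 4 experiments):

```r
tab <- read.csv(system.file("extdata", "table1_mean_ranks.csv",
                            package = "nablafuse"))
cmp <- compare_methods(setNames(tab$mean_rank, tab$method), N = 36)
cmp$friedman$chi2   #> 75.74496
cmp$friedman$F      #> 12.49004
cmp$holm$labels[cmp$holm$rejected]
#> [1] "NSCT" "PCNN-NSCT" "NSCT-SR" "m-PCNN" "SCM-F" "SCM-M"
```

The Friedman test rejects method equivalence (χ²_F = 75.74, F = 12.49),
and Holm (Hochberg agrees) finds every competitor except the two other
gradient-domain rules significantly worse than the best-ranked method.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "nablafuse", package = "nablafuse"))')
Rscript $CLI phantom --dir fixtures --size 64 --format pgm
Rscript $CLI fuse fixtures/ct_mr_A.pgm fixtures/ct_mr_B.pgm \
        --rule pca --output fused.pgm --report run.json
Rscript $CLI evaluate fused.pgm fixtures/ct_mr_A.pgm fixtures/ct_mr_B.pgm \
        --output metrics.csv
Rscript $CLI compare scores.csv --out-prefix results/cmp
```

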