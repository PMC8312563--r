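# wmnet

Graph-theoretic analysis of white-matter structural connectomes for
case-control studies, built for the setting where each subject is
summarized by a streamline-count matrix over the 90-region AAL
parcellation (deterministic tractography counts between region pairs) and
the scientific question is whether a patient group's network topology
differs from matched controls.

The pipeline implements:

* **Binary network construction** — an edge exists between two regions
  when at least *FN* streamlines connect them (primary threshold FN = 3,
  sweep 1–5 for robustness).
* **Global parameters** — clustering coefficient Cp, characteristic path
  length Lp, local efficiency locE, global efficiency gE, and their
  degree-matched-null normalizations γ = Cp/⟨Cp_null⟩, λ = Lp/⟨Lp_null⟩,
  and small-worldness σ = γ/λ, with nulls built by Maslov–Sneppen
  double-edge swaps that preserve the degree sequence exactly.
* **Nodal centralities** — degree D(i), nodal efficiency E(i) (mean
  inverse distance), betweenness B(i) (Brandes' algorithm), plus nodal
  clustering and path length.
* **Hub identification** — a 0–4 hubness score (one point each for top
  20% D(i), top 20% B(i), bottom 20% nodal clustering, bottom 20% nodal
  path length); score ≥ 2 flags a hub; group hub sets are compared as
  shared / group-specific.
* **Group statistics** — demographics by pooled t-test and χ²,
  covariate-adjusted general linear models (age, gender, education
  regressed) for every global and nodal metric, Bonferroni correction
  over the 90-node family, and confound-adjusted Pearson correlations
  with clinical variables.
* **A synthetic cohort generator** — a first-class, tested module that
  simulates the full two-group study (small-world substrate, planted
  hubs, patient randomization shift plus regional deficits, Poisson
  streamline counts, covariates and rank-coupled clinical scores), so
  the entire pipeline is exercisable without imaging data.

Graph kernels (BFS distances, Brandes betweenness, double-edge swaps) are
implemented in C++ via Rcpp; everything else is tidyverse-style R with
tibbles in and out, `tidy()`/`glance()` accessors and `autoplot()`
figures.

## Worked example

```r
library(wmnet)

coh <- generate_cohort(cohort_config(n_controls = 15, n_patients = 15,
                                     seed = 7))
an <- analyze_cohort(coh$counts, coh$cohort, fn_thresholds = 1:5,
                     primary_fn = 3, m = 50, seed = 7)

tidy(an)[, c("metric", "t", "p")]
#> # A tibble: 7 × 3
#>   metric      t        p
#>   <chr>   <dbl>    <dbl>
#> 1 gamma  19.8   8.57e-17
#> 2 lambda 15.4   3.02e-14
#> 3 sigma  19.2   1.73e-16
#> 4 cp     31.5   1.26e-21
#> 5 lp     -0.746 4.63e- 1
#> 6 loce   33.9   2.03e-22
#> 7 ge      2.70  1.23e- 2
```

Positive t means the adjusted control mean exceeds the patient mean: at
this toy size the planted patient effects on segregation (γ, σ, Cp, locE)
and global efficiency are already detected, while the path-length
difference is not yet significant at n = 15 + 15. Both groups remain
small-world (group-mean σ of 3.27 vs 1.82 at FN = 3, from `glance(an)`).

```r
an$hubs$comparison
#> <wmnet_hub_comparison>
#>   shared:           PreCG.L, PreCG.R, ROL.R, REC.R, DCG.R, AMYG.R, CUN.L,
#>                     SPG.L, PCUN.L, PCUN.R, CAU.L, CAU.R
#>   group-1 specific: IFGtriang.R, LING.R, MOG.R, IPL.L, PUT.L, PUT.R
#>   group-2 specific: SFGdor.L, ORBsup.L, ORBmid.R, SMA.L, PCG.R, ANG.L
```

The planted putamen deficit removes PUT.L/PUT.R from the patient hub set
(they stay hubs in controls), and the strongest Bonferroni-corrected
nodal differences land on exactly those regions:

```r
head(dplyr::arrange(tidy(an, "nodal"), p), 3)[, c("metric", "label", "t", "p_bonferroni")]
#> # A tibble: 3 × 4
#>   metric label     t p_bonferroni
#>   <chr>  <chr> <dbl>        <dbl>
#> 1 di     PUT.R  23.0     2.32e-16
#> 2 ei     PUT.R  21.8     8.02e-16
#> 3 di     PUT.L  21.6     1.04e-15
```

A shell front end with `simulate`, `analyze` and `report` subcommands
lives at `inst/scripts/wmnet.R`; `run_pipeline()` writes the full set of
report tables (threshold sweep, global/nodal comparisons, hub tables,
correlations, demographics) as TSV plus a JSON run summary.

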