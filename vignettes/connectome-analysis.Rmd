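---
title: "Graph-theoretic analysis of binary white-matter connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic analysis of binary white-matter connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis

`wmnet` implements a case-control analysis of structural brain networks
built from deterministic-tractography streamline counts over a 90-region
anatomical parcellation (the AAL single-subject atlas, odd indices left,
even indices right). The pipeline has five stages:

1. **Network construction.** For each subject, two regions are connected
   when at least `fn` streamlines join them (the fiber-number threshold).
   The primary analysis uses `fn = 3`; thresholds 1–5 are swept to show
   robustness. The result is an unweighted, undirected, binary 90 × 90
   adjacency matrix per subject per threshold. Asymmetric count matrices
   are rejected rather than silently symmetrized, and isolated nodes are
   retained.

2. **Global parameters.** Clustering coefficient Cp (Watts–Strogatz nodal
   clustering averaged over all nodes, isolated nodes contributing 0),
   characteristic path length Lp, local efficiency locE (mean
   neighbor-subgraph efficiency), and global efficiency gE (mean inverse
   distance over ordered pairs).

3. **Null normalization.** γ = Cp/⟨Cp_null⟩ and λ = Lp/⟨Lp_null⟩, with the
   null ensemble built by Maslov–Sneppen double-edge swaps that preserve
   each node's degree exactly; σ = γ/λ, with σ > 1 the small-world
   signature. Defaults: `m = 100` ensemble members, 10 attempted swaps per
   edge, per-member seeds `seed + i` for auditability. Connectivity is not
   enforced during rewiring — forcing connectedness biases the null — so a
   disconnected member simply contributes its finite-distance Lp and is
   counted.

4. **Hub identification.** Each node scores one point per criterion met:
   top 20% by degree Di, top 20% by betweenness Bi, bottom 20% by nodal
   clustering, bottom 20% by nodal path length; a score of at least 2
   flags a hub. Group-level hub tables are computed from subject-averaged
   nodal metrics (the criteria are defined on nodal metrics, so averaging
   metrics rather than averaging networks keeps the ranking meaningful for
   every subject's topology).

5. **Group statistics.** Demographics by pooled t-test and χ² (no
   continuity correction); metric comparisons by ordinary least squares on
   `[intercept, group, age, gender, education]`, reporting the group term's
   t (positive when the adjusted control mean exceeds the patient mean);
   Bonferroni correction over the 90-node family, applied separately per
   centrality type; and confound-adjusted Pearson correlations between
   global parameters and the patients' clinical variables (pure-tone
   average, tinnitus handicap score, hearing-loss duration), with p from
   `t = r√(df/(1−r²))`, `df = n − 2 − k`.

```{r example}
library(wmnet)
coh <- generate_cohort(cohort_config(n_controls = 20, n_patients = 20,
                                     seed = 1))
an <- analyze_cohort(coh$counts, coh$cohort, m = 100, seed = 1)
glance(an)        # group sizes, group-mean sigma, significant tests
tidy(an)          # covariate-adjusted global comparisons
autoplot(an)      # threshold-sweep figure
```

## Conventions for disconnected graphs

The single most consequential numerical choice is the treatment of
unreachable node pairs. `wmnet` averages **finite distances only** for Lp
and nodal path length, and reports the disconnected-pair fraction
alongside so the convention is always visible. Efficiency-based metrics
are unaffected (1/∞ = 0 is exact). Nodal path length is undefined (`NA`)
for isolated nodes; an undefined value ranks *last* in the low-Lp hub
criterion, so an isolated node can never be selected as "well
integrated". Nodes with fewer than two neighbors have clustering 0 and
local-efficiency contribution 0 (the convention used by the standard
connectome toolboxes). Betweenness is left unnormalized: normalization
cancels in rank-based hub criteria and only rescales group contrasts.

Ties at a hub-criterion selection boundary are broken by lower node
index after sorting by metric value, which makes hub tables deterministic.

## What the synthetic cohort emulates

Because no raw imaging data are distributed, the package ships a
first-class generator that reproduces the *statistical structure* the
analysis assumes, with defaults fixed at study-like conditions:

* **Substrate.** A Watts–Strogatz-style rewired ring lattice (90 nodes,
  mean degree 6, rewiring probability 0.1) — the minimal generator with
  tunable clustering and path length, consistent with the small-world
  organization reported for both groups. Eight hub regions (bilateral
  precentral gyrus, precuneus, caudate, putamen) receive 8 extra edges
  each so a stable hub set exists to recover.
* **Subjects.** Each subject perturbs the shared substrate with
  independent edge flips at rate 0.01 per node pair, emulating
  tractography variability (~35 spurious/missed connections per subject).
* **Patients.** Two planted disease effects: (i) rewiring of 30% of
  edges — the shift toward randomization, which destroys triangles and
  lowers clustering and local efficiency; and (ii) removal of 80% of the
  edges at eight affected regions (bilateral inferior frontal operculum,
  right triangular inferior frontal gyrus, right medial superior frontal
  gyrus, right superior occipital gyrus, bilateral putamen, right
  superior temporal pole). The severe deficit fraction is deliberate: in
  a small-world substrate uniform rewiring *shortens* paths (it creates
  shortcuts), so a pure randomization shift would lower Lp; the
  disconnection component must dominate for the patient group to show the
  clinically observed pattern of longer paths and lower global efficiency
  together with lower clustering. Effect sizes are configuration knobs,
  not claims about effect magnitude in any real population.
* **Counts.** Streamline counts are Poisson: mean 20 on true edges, 0.3
  elsewhere. At `fn = 3` this makes thresholding a high-fidelity edge
  detector (miss probability ≈ 1e-6, false-edge probability ≈ 3.6e-3),
  so construction-stage tests stay sharp. At `fn = 1` the spurious tail
  (P ≈ 0.26 per pair) admits several hundred noise edges and drives σ
  toward 1 — the expected behavior of the most lenient threshold, and the
  reason the threshold sweep's σ minimum sits at `fn = 1`.
* **Covariates and clinical scores.** Age ~ N(38.5, 12²) truncated to
  [18, 80]; education ~ N(13, 3.5²); gender Bernoulli(0.5) encoded 0/1 in
  the model; pure-tone averages N(12.08, 4.04²) for controls and
  N(78.17, 28.56²) truncated at the 30 dB inclusion bound for patients;
  tinnitus scores N(45.57, 24.88²) on [0, 100]; duration N(8.44, 4.17²)
  truncated to the 1–14 day acute window. Tinnitus score and duration are
  **rank-coupled** to each patient's realized characteristic path length
  (targets +0.18 and −0.18): scores are generated marginally, then
  reordered along a latent blend of the surrogate's normal scores and
  noise, guaranteeing a monotone association without distributional
  commitments.

What passing tests on this cohort do *not* show: the generator has no
spatial embedding, no distance-dependent connection probability, no
hemispheric symmetry structure, and no realistic degree heterogeneity
beyond the planted hubs, so recovery results speak to the pipeline's
statistical machinery, not to tractography fidelity or anatomical truth.

## Problem sizes and reproducibility

Every stochastic step is driven by explicit integer seeds (subject i uses
`seed + i`, null member j uses `seed + j`, covariates `seed + 9e5`), so a
cohort, an ensemble, and a full run are byte-reproducible. The shipped
test suite exercises oracle equivalence on 200 random graphs (n ≤ 8)
against brute-force Floyd–Warshall, triangle-enumeration and
geodesic-enumeration oracles; calibration at 5,000 null replicates for
the adjusted group test and χ²; family-wise error over 500 90-node null
families; and planted-effect recovery over 50 full-size (91 + 145)
cohorts. The small-world check uses 20 + 20 subjects with m = 100 nulls
per subject per threshold; these sizes were chosen so the whole suite
runs comfortably on a laptop while keeping Monte-Carlo error well inside
the asserted bounds.

## Known limitations

* Weighted-network variants, modularity, and rich-club metrics are out of
  scope; the analysis substrate is strictly the binary network.
* Lp's finite-only convention means heavily fragmented networks (very
  high thresholds) can show *shorter* Lp as pairs drop out; always read
  Lp next to the reported disconnected-pair fraction.
* The GLM assumes homoscedastic residuals and main effects only; no
  interaction terms are fitted.
* Bonferroni is applied per centrality family (90 tests each for degree,
  efficiency, betweenness), the most literal reading of a 90-node
  correction; a joint 270-test family would be more conservative.
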