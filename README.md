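# dcisatlas

Analysis toolkit for multi-region molecular profiling of breast ductal
carcinoma in situ (DCIS) and related pre-invasive lesions. Studies of DCIS
microdissect several regions per specimen and profile each separately; this
package implements the downstream analytical core for such designs, for
bioinformaticians working from caller output (bin-level log2 copy ratios,
variant tables, mIHC cell tables) rather than raw reads:

- **Joint multi-region segmentation** — exact minimization of
  `SSE + gamma * breakpoints` across all regions of a sample on shared
  breakpoints, by dynamic programming (`joint_segment`).
- **Copy-number divergence** — the bin-weighted L1 distance between two
  regions' segment profiles, `D(a,b) = sum_k |a_k - b_k| * bins_k / total_bins`
  (`pairwise_divergence`, `sample_divergence`), plus CNA burden
  (`cna_burden`) and ternary discretization into parsimony characters
  (`discretize`: loss below -0.6, neutral in [-0.4, 0.3], else undetermined,
  12-bin minimum).
- **Maximum-parsimony clonal trees** — exhaustive rooted-topology search with
  a diploid (all-neutral) ancestor, Sankoff-scored with missing data as
  wildcards, Hamming branch lengths, per-branch event placement and co-optimal
  tree counting (`build_mp_tree`, `parsimony_score`, `assign_branch_events`).
- **Tumor-only variant filtering** — the quality / common-germline /
  VAF-outside-LOH / pool-of-normals cascade with COSMIC hotspot rescue, as
  order-invariant labels (`filter_variants`), and a Bayes-factor
  present/absent/unknown caller per region (`call_presence`).
- **Immune micro-environment states** — compartmentalized cell densities (18
  features: {BC, TC, TREG} x {Ki67+, Ki67-, total} x {epithelium, stroma}),
  decile regularization, rank-4 NMF into meta-markers, and Ward clustering of
  the H matrix into Active / Suppressed / Excluded states
  (`compute_density_matrix`, `decile_regularize`, `factorize_densities`,
  `assign_immune_states`).
- **Supporting statistics** — Fisher's exact test returning the
  conditional-MLE odds ratio (the psi solving `E[a | psi, margins] = a` under
  the noncentral hypergeometric distribution, *not* the cross-product ratio),
  Mann-Whitney U with exact enumeration at small n, and OLS
  (`fisher_cmle_or`, `mann_whitney`, `ols_fit`).
- **Seeded synthetic-data generators** that plant known truth for every stage
  (`simulate_clonal_cna`, `simulate_variant_table`, `simulate_immune_cohort`),
  and the packaged 43-sample cohort table (`load_table1_fixture`).

## Worked example

```r
library(dcisatlas)

## Cohort: 43 specimens from 39 patients
tab <- load_table1_fixture()
summarize_cohort(tab, "grade_group")
#> HG-DCIS LG-DCIS     ADH
#>      32       9       2
count_samples_by_size(tab, 4)   # extended lesions, >= 4 cm
#> [1] 14

## Odds ratio of Suppressed immune state in younger cases (5/8 vs 4/24)
fisher_cmle_or(5, 3, 4, 20)
#> $odds_ratio  7.630204      $p_value  0.02331508

## Clonal reconstruction on simulated multi-region copy ratios
sim  <- simulate_clonal_cna(clonal_sim_spec(n_regions = 4, sigma = 0.1, seed = 7))
seg  <- joint_segment(sim$bins, gamma = 2)
sample_divergence(seg)
#> [1] 0.2920239
tree <- build_mp_tree(discretize(seg))
tree
#> phylo_tree: ((((R1,R4),R3),R2))diploid_ancestor;
#>   parsimony score 21 (1 co-optimal topology)
#>   7 branches, total length 21, 21 placed events, 0 unplaced
identical(tree$newick, sim$truth$newick)   # planted topology recovered
#> [1] TRUE
```

The tree's 7 branches each carry exactly the 3 planted copy-number events
(`tree$branches$events`), the parsimony score of 21 equals the 21 planted
events (one state change each), and the single co-optimal topology is the
planted one. `write_tree_newick(tree)` serializes the tree with integer
Hamming branch lengths and `[&events=...]` annotations.

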