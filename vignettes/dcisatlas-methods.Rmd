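---
title: "Methods: multi-region genomic and immune analysis of breast pre-cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region genomic and immune analysis of breast pre-cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcisatlas)
```

## What the package models

Ductal carcinoma in situ (DCIS) is pre-invasive breast cancer: neoplastic
epithelium still confined to the duct. Because lesions are small,
formalin-fixed and histologically heterogeneous, studies of DCIS increasingly
microdissect several regions per specimen and profile each region separately —
copy-number alterations (CNA) and mutations from whole-exome sequencing,
immune-cell composition from multiplex immunohistochemistry (mIHC). This
package implements the analytical core such a study needs once the upstream
calling is done:

1. joint multi-region segmentation of bin-level log2 copy ratios on shared
   breakpoints;
2. a bin-weighted divergence score between regions, CNA burden, and a ternary
   discretization of segments into parsimony characters;
3. exact maximum-parsimony reconstruction of the clonal tree of the regions,
   rooted at a normal diploid ancestor, with events placed on branches;
4. a tumor-only somatic-variant filtering cascade (no matched normal) and a
   Bayes-factor presence caller across regions;
5. non-negative matrix factorization (NMF) of compartmentalized immune-cell
   densities into meta-markers and the Active / Suppressed / Excluded immune
   states;
6. the supporting statistics: Fisher's exact test with the conditional-MLE
   odds ratio, Mann-Whitney U, and OLS.

Every stage has a seeded synthetic-data generator that plants known truth, so
the whole pipeline is testable without any controlled-access download.

## Joint segmentation

Regions of one sample share breakpoints by construction of the model: a CNA
either happened in an ancestor (and is present in several regions) or is
private, but its boundaries are the same genomic positions. `joint_segment()`
therefore minimizes, per chromosome,

$$\sum_{r}\sum_{i}(x_{ri}-\hat\mu_{r,s(i)})^2 \;+\; \gamma\,K,$$

over shared breakpoint positions, where $K$ is the number of breakpoints,
$s(i)$ the segment containing bin $i$, and $\hat\mu_{rs}$ the per-region
segment means. The exact optimum is found by an $O(n^2)$ dynamic program over
changepoints (tested against exhaustive enumeration of all breakpoint subsets
on small instances). Instances of this size pose no difficulty: a 700-bin
chromosome segments in well under a second.

The penalty $\gamma$ is in squared-log2-ratio units, so sensible values scale
with bin counts and noise. For whole-exome cohorts (thousands of bins per
chromosome, bin noise sd 0.3-0.5) $\gamma = 40$ is the conventional setting;
on the package's simulated 700-bin chromosomes with noise sd 0.1 and 20-bin
events of 0.8 log2 units, the same arithmetic (a breakpoint is kept when it
reduces the residual sum of squares by more than $\gamma$) gives
$\gamma \approx 2$: merging a planted event with its 10-bin neutral gap costs
$\ge 0.64 \cdot 10\cdot 20/30 \approx 4.3 > \gamma$ while a spurious noise
breakpoint saves only $O(\sigma^2 \log n) \approx 0.1 \ll \gamma$. The
vignette and tests use $\gamma = 2$ on simulated data for this reason; it is a
property of the objective's units, not a tuning knob.

`winsorize_bins()` guards the segmentation against single-bin artifacts by
clipping values outside median $\pm k\cdot$MAD (scaled by 1.4826, default
$k = 2.5$) per chromosome. The clip is global per chromosome: when genuine
copy-number plateaus cover a large fraction of a chromosome, the global MAD
bounds can land inside real signal and flatten it. Use it when bin-level
artifacts are expected, skip it (or raise `k_mad`) on clean or
heavily-altered data; the simulations plant no artifacts, so their pipeline
does not winsorize.

## Divergence, burden, characters

The genetic distance between two regions $a, b$ on their shared segmentation
is the bin-weighted L1 distance of segment means,

$$D_{a,b}=\sum_k \lvert a_k-b_k\rvert\,\frac{bins_k}{\sum_k bins_k},$$

so each segment contributes in proportion to its evidence. This is a true
metric on profiles sharing a segmentation (non-negative, symmetric, triangle
inequality — property-tested on random triples). A sample with more than two
regions is represented by the maximum pairwise divergence.

CNA burden is the fraction of covered base pairs in segments called gained or
lost. Burden cutoffs default to the complement of the neutral band used for
discretization (gain above 0.3, loss below -0.4), a choice made for internal
consistency since no separate burden cutoffs are conventional; the denominator
is the span actually covered by segments (targeted exome bins), not a nominal
genome length.

For phylogeny, segments become ternary characters: loss (-1) below -0.6,
neutral (0) in [-0.4, 0.3], undetermined (missing) elsewhere; segments with
fewer than 12 supporting bins are dropped. Undetermined is treated as unknown
(a Fitch/Sankoff wildcard), not as a fourth state. Gains are an off-by-default
option (`include_gains`): the character code is loss/neutral, but gain
annotation can be useful descriptively.

## Maximum parsimony with a diploid root

The regions of a sample descend from normal diploid epithelium, so trees are
rooted at an all-neutral ancestor. `build_mp_tree()` enumerates every rooted
binary topology over the regions — $(2n-3)!!$ trees, practical up to the
8-region bound — and scores each column with a Sankoff dynamic program under
unit substitution costs, with the root state fixed at neutral. Exhaustive
enumeration rather than heuristic search keeps the optimum exact and makes
co-optimality visible: the number of co-optimal topologies is always
reported, and ties are broken deterministically by the lexicographically
smallest canonical newick string.

Ancestral states are fixed root-to-tip, preferring the neutral state on ties;
this biases events later along the tree, the conservative reading of an
inferred normal ancestor. Branch lengths are Hamming distances between
endpoint state vectors (positions where a leaf is undetermined are skipped),
and each character is annotated on every branch where its state changes.
Mutations, given a regions-by-variants presence matrix, are placed on the edge
above the most recent common ancestor of the regions carrying them; a pattern
contradicted by an absent region inside that clade is flagged `unplaced`
rather than silently dropped, and fully clonal mutations map to the trunk.

## Tumor-only variant filtering

Without a matched normal, germline variants must be removed computationally.
The cascade labels records (never drops them), with each label a pure
predicate of the record, so the outcome is independent of filter order:

- `quality_fail` — depth < 5, mapping quality <= 45, mean position in read
  <= 15, mean mismatches >= 2.5, microsatellite length >= 5, tumor log-odds
  <= 10, strand-bias Phred >= 10, or VAF <= 0.1. Threshold senses are applied
  literally (mapping quality exactly 45 fails a strict "> 45"). Records
  missing a quality field are not failed for it unless `strict = TRUE`.
- `common_germline` — population allele frequency > 1e-3 or seen in > 9
  individuals, unless the variant lies in a tier-1 cancer-census gene and is
  known in COSMIC or ClinVar. When several population sources disagree, supply
  the maximum count.
- `vaf_germline` — VAF >= 0.9 outside loss-of-heterozygosity segments (inside
  LOH a germline allele legitimately reaches high VAF, so those records are
  exempt).
- `pon` — seen in more than 2 pool-of-normal patients.
- `rescued_hotspot` — known in >= 15 COSMIC patients within the supplied
  breast-cancer driver-gene list; rescued records survive the cascade.

`somatic_pass` is the closing conjunction. For multi-region presence, each
region-by-variant cell with $k$ alt reads of $n$ is called by the Bayes factor

$$BF=\frac{\int_{f_{min}}^{1}\mathrm{Binom}(k;n,f)\,df}{\mathrm{Binom}(k;n,e)},$$

with error rate $e = 0.02$, $f_{min} = 0.05$, present above 10, absent below
0.1, unknown otherwise (and always unknown at zero depth). This deliberately
replaces a full tree-aware Bayesian caller with a transparent, dependency-free
per-cell test that is sufficient to feed branch-event placement; it does not
learn error rates from data and does not share information across regions.

## Immune micro-environment states

From mIHC cell tables, `compute_density_matrix()` produces 18 features per
region: {B-cells, T-cells, T-regs} x {Ki67+, Ki67-, total} x {epithelium,
stroma}, as cells/mm2 with zeros (not missing) where a cell type is absent.
Epithelial (PanCK+) cells define the compartments but are not a feature, and
T-regs are excluded from the T-cell features by default so features stay
non-redundant (`tregs_in_tc` restores the overlap).

Densities are regularized to distribution deciles per feature
(`ceiling(10 * rank / n)`, average ranks for ties), which removes scale
differences between cell types and compartments. The decile matrix is
factorized by rank-4 NMF (Lee-Seung multiplicative updates on the Frobenius
loss, best of 10 seeded restarts, W columns normalized to unit maximum and
ordered by total H weight, fully deterministic given the seed). Regions are
then clustered on the H matrix (Euclidean distance, Ward linkage — the
conventional choice where only "hierarchical clustering" is specified; both
are configurable by operating on `model$H` directly) and cut at k = 3. The
naming rule follows the state definitions: the cluster with maximal mean MM4
is Excluded (stroma-restricted lymphocytes), the remaining cluster with
maximal mean MM2 is Active (ubiquitous high T-cells), the last is Suppressed
(low T-cells, elevated B-cells/T-regs). Deciles are computed jointly over all
regions, not within normal/premalignant strata. Note that which meta-marker
captures which signature is a property of the factorization of the data at
hand; on data unlike the planted archetypes, inspect `model$W` before reading
the state names literally.

The per-cell-type high/low/none density categories used alongside the states
split at the median of nonzero epithelial densities (none when both
compartments are empty) — a reimplementation choice where no threshold is
conventional.

## Synthetic data: what it emulates, what it does not

`simulate_clonal_cna()` draws a rooted binary tree over 2-8 regions whose
branches (trunk included) each carry 3 copy-number events: non-overlapping
20-bin intervals (10-bin minimum gaps) shifted by -0.8 log2 units in all
descendant regions, on a 700-bin chromosome with Gaussian bin noise. Event
magnitude defaults to a loss clearing the -0.6 character threshold under
sd-0.1 noise; events are additive log2 shifts, not integer copy states,
because downstream operations consume log2 ratios. The generator emits the
planted tree, events, induced segmentation and character matrix, so
noise-free runs round-trip exactly through
`discretize(joint_segment(...))`. It does not emulate replication-timing
waves, GC bias, subclonal mixtures within a region, or overlapping events.

`simulate_variant_table()` plants common germline (VAF near 0.5/1.0 with
population annotations), somatic (VAF ~ U(0.1, 0.4), clean quality) and
artifact records (each failing one random quality rule or recurrent in the
pool of normals). It does not emulate correlated quality failures or
trinucleotide context.

`simulate_immune_cohort()` draws 10 regions per state from three archetypes
that follow the state definitions, with multiplicative lognormal dispersion
(default sd 0.25) so densities stay non-negative and Ki67 components always
sum to totals. Archetype levels echo the magnitudes typical of DCIS mIHC
(epithelial T-cells around 120 cells/mm2 in the Active archetype; stromal to
epithelial ratios around 10 overall and far larger in the Excluded
archetype). It does not emulate spatial structure within a region or
cell-count (Poisson) noise at small areas.

Passing tests on these generators show the pipeline recovers structure it was
designed for when its assumptions hold; they cannot show robustness to the
artifacts real FFPE exomes and stained slides add.

## The conditional-MLE odds ratio

For a 2x2 table with all margins fixed, the top-left cell follows Fisher's
noncentral hypergeometric distribution with odds-ratio parameter $\psi$.
`fisher_cmle_or()` returns the conditional MLE: the $\psi$ solving
$E[a \mid \psi, \text{margins}] = a$, found by bisection on $\log\psi$ to
tolerance $10^{-8}$, with boundary tables mapping to 0 or $\infty$. This is
deliberately not the sample cross-product ratio $(ad)/(bc)$: for the table
(5, 3; 4, 20) the cross-product ratio is about 8.3 while the conditional MLE
is 7.6 — the estimator standard Fisher-test software reports, and the one this
package's test suite verifies against an independent noncentral
hypergeometric oracle. The two-sided p-value sums null probabilities no larger
than the observed table's (no mid-p correction).

`mann_whitney()` enumerates all rank assignments exactly when the combined
sample size is at most 12 (forceable with `exact = TRUE`) and otherwise uses
the normal approximation with tie and continuity corrections. `ols_fit()`
wraps `stats::lm()`.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; SEG files are read and
  written 1-based inclusive.
- Segmentation at more than ~50,000 bins per chromosome is quadratic-cost;
  such instances should be chunked by the caller (the package targets exome
  bin counts).
- NMF guards divisions with machine epsilon; a zero W column normalizes to
  scale 1.
- A constant response in `ols_fit()` returns $R^2 = 0$ with slope 0; a
  constant predictor is an error.
- Zero-depth presence cells are `unknown`; empty compartments yield density 0
  by definition, while a zero compartment area is an error.
- Parsimony tie-breaks: co-optimal topologies by smallest canonical newick,
  ancestral-state ties toward neutral.
- The problem sizes exercised in the test suite — 4-region trees over 50
  seeds, 20-seed filter and immune cohorts, 700-bin chromosomes — are the
  package's chosen simulation scale: large enough that every planted branch
  carries 3 distinguishing events and each immune state has 10 regions,
  small enough that exhaustive oracles (all topologies, all breakpoint
  subsets, all rank assignments) stay feasible.

## Known limitations

- Exhaustive tree search is bounded at 8 regions; no heuristic search or
  bootstrap support is provided.
- The presence caller is per-cell and ignores the tree; mutations with
  homoplastic presence patterns are only flagged, never resolved.
- Global winsorization can clip genuine plateaus (see above).
- Allele-specific copy number, purity/ploidy and whole-genome-doubling
  calling are out of scope, as are alignment, raw variant calling, expression
  subtyping and image segmentation.
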