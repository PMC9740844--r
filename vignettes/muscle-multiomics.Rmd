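---
title: "Methods: spectral-count proteomics and targeted metabolomics statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-count proteomics and targeted metabolomics statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleomics)
```

muscleomics implements the statistical chain of a two-group skeletal-muscle
multi-omics design: a pooled label-free proteomic comparison quantified by
spectral counting, over-representation analysis of the resulting protein
subsets, and a targeted amino-acid / acylcarnitine metabolomics suite. This
vignette explains each model, its assumptions, the tunable parameters, and
the numerical choices made where the design was genuinely open.

## Spectral-count differential proteomics

### The design

Each group's protein extracts are pooled into a single SDS-PAGE lane, so a
contrast has exactly two "samples". Protein abundance is estimated by the
spectral count (SpC): the number of MS/MS spectra assigned to the protein in
that lane. Before quantitation, identifications are filtered by the
acceptance rule *at least `min_peptides` (default 2) assigned peptides, each
with a search-engine score strictly greater than `min_score` (default 19)*.
The lane totals are computed **after** this filter, over exactly the
quantified protein universe, because only accepted proteins contribute
interpretable spectra.

### The Rsc statistic

For a protein with counts $n_1$, $n_2$ in the two lanes and lane totals
$t_1$, $t_2$:

$$
R_{sc} \;=\; \log_2\!\frac{n_2 + f}{n_1 + f}
       \;+\; \log_2\!\frac{t_1 - n_1 + f}{t_2 - n_2 + f},
$$

with the correction factor $f = 0.5$ removing the discontinuity at zero
counts. The second term makes $R_{sc}$ the exact log odds ratio of the
2×2 lane-composition table, so it corrects for unequal lane depth. The
statistic is antisymmetric under swapping the two lanes and is exactly zero
for proportion-matched counts — both properties are enforced by tests on
randomly generated entries.

**Orientation.** The contrast is specified as an explicit
(`group_a`, `group_b`) pair in `run_proteomics()`; `group_a`'s counts feed
the $n_2$ slot, so a positive $R_{sc}$ always means *higher abundance in
`group_a`* (the first-named, e.g. trained, group). This keeps the printed
formula and the biological sign convention consistent regardless of how the
groups are labelled in the input table.

Proteins are classified `over` when $R_{sc} \ge 1.40$, `under` when
$R_{sc} \le -1.40$ (boundaries **included**), `unchanged` otherwise. The
1.40 threshold corresponds to roughly a 2.6-fold change and is the value the
packaged published tables were thresholded at; `classify_differential()`
takes any positive threshold. Applied to the packaged transcription of the
published tables (`published_rsc_table()`), the classifier reproduces 92
overexpressed and 96 underexpressed proteins, 188 in total.

## Over-representation analysis

The differential subsets (over and under, analysed separately) are tested
against GMT annotation sets by the one-sided (enrichment-only) Fisher exact
test: with $k$ query hits in a term of background size $K$, query size $n$
and universe size $N$, the p-value is the hypergeometric upper tail
$P(X \ge k)$. Design choices:

- **Background** defaults to the filtered identification universe, not the
  genome. For spectral-count data the detectable proteome is the only
  defensible sampling frame; a genome background would exaggerate
  enrichment of muscle-expressed terms.
- Terms with fewer than 2 background members are skipped (a single-member
  term cannot be meaningfully enriched and destabilises the FDR).
- The EASE-style conservative variant (Fisher p computed on $k-1$) is
  available as `ease = TRUE` but off by default; whether the original
  annotation-server analysis used it is not documented, and plain Fisher is
  the reproducible choice.
- Multiplicity is controlled by Benjamini–Hochberg step-up FDR (`bh_fdr()`,
  a validated wrapper over the standard step-up procedure).
  `filter_significant()` gates on raw p ≤ 0.05 ("p" mode, annotation-server
  style) or FDR ≤ 0.05 ("fdr" mode, network-server style), both inclusive.

## Metabolite-panel statistics

The metabolomics container is a metabolite × sample matrix of strictly
positive concentrations normalised to total protein content, with exactly
two groups. The chain:

1. **Preprocessing** (`preprocess()`): per metabolite, $y = \log_{10} x$,
   then Pareto scaling $(y - \bar y)/\sqrt{s_y}$. Pareto scaling is the
   metabolomics compromise between no scaling (dominated by abundant amino
   acids) and unit-variance scaling (inflates noise on trace
   acylcarnitines); its signature identity — the scaled variance equals the
   unscaled standard deviation — is asserted in tests. A zero-variance
   metabolite is passed through centered-only with a warning rather than
   producing division by zero.
2. **PLS-DA** (`fit_plsda()`): NIPALS PLS1 against a ±1 group-coded,
   centered response with per-component deflation. Default 2 components
   (the score plane used for visual assessment of group homogeneity); the
   component count is reduced with a warning if the data rank is lower,
   using a score-norm tolerance of 1e-10. Explained Y-variance per
   component is reported as a fraction of the initial response sum of
   squares; this is the Y-side (discrimination) variance, the quantity VIP
   weighting needs. The component-1 weight vector is proportional to
   $X^\top y$, which tests verify against the closed form.
3. **VIP** (`vip_scores()`):
   $\mathrm{VIP}_j = \sqrt{p \sum_a w_{ja}^2\,\mathrm{SSY}_a / \sum_a \mathrm{SSY}_a}$
   — the weighted sum of squares of the PLS weights with each dimension
   weighted by the Y-variance it explains. The normalisation forces
   $\textstyle\sum_j \mathrm{VIP}_j^2 = p$, asserted to 1e-10 on every
   fitted model in the suite. The discriminant-feature cutoff defaults to
   VIP > 1.5 (strict), with 1.0 the other conventional choice; both are
   exercised in tests and the cutoff is a plain argument.
4. **Univariate testing** (`univariate_panel()`): per metabolite, the
   D'Agostino–Pearson omnibus test (transformed skewness + kurtosis,
   $K^2 \sim \chi^2_2$) is applied to each group's **raw** concentrations —
   the convention of the common graphing-statistics workflow is to test the
   analysed variable, and concentrations, not their transforms, are what
   the univariate comparison reports. If both groups pass (p > 0.05), the
   groups are compared by Welch's unequal-variance t-test; otherwise by the
   two-sided Mann–Whitney test, exact when the smaller group has ≤ 8
   observations and the data are untied, else the normal approximation with
   continuity and tie correction. The omnibus test needs n ≥ 8 per group;
   smaller panels fall back to Mann–Whitney with a warning, and fewer than
   3 samples per group is an error. Results carry group means ± SEM, the
   log2 fold change of group means (A over B), and a direction call at
   p ≤ 0.05.
5. **Volcano** (`volcano()`): `increased` iff log2FC > `fc_threshold_log2`
   and p ≤ 0.05. The fold-change threshold defaults to 0
   (significance-only gating): the published volcano and univariate counts
   disagree slightly (7 vs 5 increased), so no specific fold-change cutoff
   can be inferred, and 0 is the only choice that adds no hidden parameter.
6. **Clustering** (`cluster_heatmap()`): metabolites ranked by univariate
   p, top 40 kept, then agglomerative clustering with Euclidean distances
   on the preprocessed matrix for both axes. The linkage is not documented
   in the source workflow; Ward (`ward.D2`, the default of the common
   metabolomics web platform) is the default here, with
   single/complete/average available. Merge tables, heights and leaf
   orders are returned in serialisable form.

## Synthetic data: what it emulates and what it does not

`simulate_spectral_counts()` models the pooled design faithfully in one
specific sense: each lane's counts are **multinomial conditioned on the
fixed lane total**, not independent Poisson, because $t_1$, $t_2$ are
totals of one physical lane each, so realized totals must equal the
configured depth exactly. Baseline relative abundances are log-normal
(default sdlog 1.0, a typical compressed dynamic range for
spectral-count-detectable proteins), which keeps many proteins at low
counts and genuinely exercises the $f = 0.5$ correction.

Planted fold changes are split symmetrically across the groups
(up-regulated: $\times 2^{fc/2}$ in A, $\times 2^{-fc/2}$ in B). Because
counts are compositional, planting the whole effect into one lane would
shift every null protein's expected $R_{sc}$ by the planted mass imbalance
(about −0.7 log2 units at 10% planted fraction and 8-fold effects),
contaminating the null calibration the simulation exists to measure;
symmetric splitting preserves the exact planted log2 difference while
leaving lane composition balanced. The generator's ground truth records
each protein's planted class, and parameter-recovery tests assert ≥ 90%
recovery of planted 8-fold effects with ≤ 5% false calls on nulls at
500 proteins and 20,000 spectra per lane.

`simulate_metabolite_panel()` draws concentrations log-normally around
per-metabolite baselines (median 10, sdlog 1.5 — micromolar amino-acid
pools down to trace long-chain species) with multiplicative noise of
configurable CV (default 0.2, a typical inter-subject spread for targeted
panels), and applies planted log2 effects to group A means. The default
panel is 50 metabolites (16 amino acids, 34 acylcarnitines), 9 subjects
per group.

Neither generator models peptide-level identity, retention-time structure,
batch effects, censoring at the limit of detection, or inter-subject
correlation between metabolites. Passing recovery tests therefore shows the
*statistics* behave as designed under the stated noise model — not that the
pipeline is robust to every artefact of real acquisitions.

All generators run under a single configured seed with a documented draw
order and restore the caller's RNG state, so fixtures are reproducible
byte-for-byte.

## End-to-end driver

`load_config()` reads a YAML configuration (empty file = all published
defaults: f = 0.5, |Rsc| ≥ 1.40, ≥ 2 peptides, score > 19, VIP > 1.5,
α = 0.05), rejects unknown keys by name, and validates every threshold.
`run_all()` chains proteomics → enrichment (over- and under-subsets
separately) → metabolomics, writes TSV outputs stamped with a hash of the
analytic configuration (io paths excluded, so identical analyses written to
different directories carry identical provenance), and a machine-readable
`summary.json`. Reruns under the same configuration are byte-identical.

## Problem sizes and determinism

The test suite and the acceptance script use 500-protein / 20,000-spectra
proteomes and 50 × 18 metabolite panels — the scale of the emulated study —
plus exhaustive small-N oracles (all 2×2 tables with N ≤ 60; all untied
Mann–Whitney layouts with group sizes ≤ 5). Everything downstream of the
generators is deterministic given the input matrix; there is no RNG in the
statistics modules.

## Known limitations

- The Rsc chain assumes one pooled lane per group; it does not estimate
  within-group biological variance, so classification is a fold-change
  screen, not an inference with error control.
- The published study's own headline values that depend on unpublished raw
  data (total identified proteins, per-component variance percentages,
  specific metabolite lists) cannot be recomputed from the packaged tables
  and are not claimed by this package.
- The normality gate tests each group separately at n = 9; the omnibus
  test has modest power at that size, so the Welch/Mann–Whitney choice is a
  convention, not a guarantee of distributional correctness.
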