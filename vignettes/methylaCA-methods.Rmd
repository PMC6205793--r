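---
title: "Methods: differential methylation and immune cell-type signatures in placental inflammation"
author: "methylaCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and immune cell-type signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scientific setting

Acute chorioamnionitis (aCA) is an inflammation of the placenta and fetal
membranes, histologically defined by infiltration of maternal neutrophils,
and strongly associated with preterm birth. Because DNA methylation (DNAm)
profiles differ sharply between cell lineages, bulk methylation of a
placental biopsy reflects both within-cell-type regulatory changes and
shifts in cell composition. `methylaCA` implements the analysis pipeline
needed to dissect this in Illumina-array data from chorionic villi and the
fetal membranes (chorion, amnion): per-CpG differential methylation with
clinical covariates, batch correction, cross-tissue overlap testing,
immune-cell-type-specific CpG signatures, trend concordance against blood
cell references, and bootstrap-stable hierarchical clustering — plus a
synthetic-cohort generator so that every stage is testable end to end
without patient data.

# The differential methylation model

Methylation at a CpG is summarised as a beta value, the methylated fraction
$\beta \in [0,1]$. Linear modelling is done on the variance-stabilised
M-value scale, $M = \log_2 \beta/(1-\beta)$, clipped at
$\varepsilon = 10^{-6}$ so the logit stays finite. For each CpG we fit, by
ordinary least squares,

$$ M_{ij} = \alpha_j + \gamma_j\,\mathrm{aCA}_i + \beta_{1j}\,\mathrm{GA}_i
  + \beta_{2j}\,\mathrm{sex}_i + \beta_{3j}\,\mathrm{MDS1}_i
  + \beta_{4j}\,\mathrm{MDS2}_i + e_{ij}, $$

where gestational age (GA, weeks) is untransformed, fetal sex is a single
indicator, and ancestry enters as $k=2$ coordinates from classical
multidimensional scaling of ancestry-informative SNPs (how many coordinates
a study should carry is genuinely open; two is the default and it is a
`designSpec()` parameter). The tested quantity is the aCA coefficient
$\gamma_j$, with non-aCA as reference so positive estimates mean
hypermethylation in aCA.

With `moderation = "empirical_bayes"` (the default), residual variances are
shrunk across CpGs toward a common prior: the log residual variances are
fit by method of moments to a scaled inverse-chi-square prior $(d_0,
s_0^2)$, giving $s^2_{\mathrm{post}} = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and a
moderated $t$ on $d + d_0$ degrees of freedom. Moderation changes only the
standard errors; coefficients are identical to the unmoderated fit, and the
test suite cross-checks the moderated statistics against `limma` as an
independent oracle. Whether to moderate is exposed because with 44 samples
the choice is consequential for borderline sites; the moderated default is
the standard small-sample practice on arrays.

Effect sizes are reported on the interpretable beta scale:
$\Delta\beta = \overline{\beta}_{\mathrm{aCA}} -
\overline{\beta}_{\mathrm{non\text{-}aCA}}$ per CpG. A site is called
differentially methylated (DM) iff its Benjamini–Hochberg $q <
f_{\mathrm{max}}$ **and** $|\Delta\beta| > \delta_{\mathrm{min}}$. The
discovery thresholds default to $(0.15, 0.05)$; tissue-pair contrasts use
the strict $(0.01, 0.20)$. $|\Delta\beta|$ is used deliberately — both
hyper- and hypomethylated sites are biologically meaningful here. An
optional covariate-adjusted effect size (the primary coefficient refit on
the beta scale) is available via `delta_method = "covariate_adjusted"`;
the raw group-mean difference is the default because it is the quantity a
replication study measures directly. Candidate-gene runs
(`cpg_subset`) apply BH within the candidate set only, and sex-stratified
runs use a `sample_filter`.

# Preprocessing

* **Probe filtering** (`filterProbes`) removes CpGs by annotation flags
  (cross-reactive, polymorphic, sex chromosomes), custom blocklists,
  missingness fraction and (when supplied) detection-p failures, in a fixed
  order with per-criterion counts. The criterion set is generic because
  published filter lists differ between platforms and studies.
* **Sample QC** (`sampleQC`) reports replicate-pair M-value correlations
  and flags samples whose mean within-tissue correlation falls below
  median $- 3\cdot$IQR. Flags are advisory; removal is an explicit user
  action, never automatic.
* **Quantile normalization** (`quantileNormalize`, optional) forces each
  sample's distribution onto the cross-sample mean of sorted vectors
  (ties share their span mean). Raw-intensity normalizations
  (functional normalization, background correction, probe-type rescaling)
  are out of scope: they need channel intensities, not beta values.
* **Batch adjustment** (`combatAdjust` / `adjustBatchEffects`) is a
  parametric empirical-Bayes location/scale model: per-feature OLS of the
  protected design plus batch indicators under a size-weighted sum-to-zero
  constraint, standardisation, normal/inverse-gamma method-of-moments
  hyperpriors, and a fixed-point EB iteration to tolerance $10^{-4}$. The
  biological design (aCA, GA, sex, ancestry) is protected so batch removal
  cannot absorb it. Chip row is adjusted before chip id (order
  configurable); the two-pass order is not identifiable from the data and
  has negligible effect. The implementation exposes the per-batch
  $\hat\gamma, \gamma^\*, \hat\delta, \delta^\*$ and hyperparameters in a
  `BatchModel`, and is validated against `sva::ComBat` to $10^{-4}$.
  Note the EB estimator is only *approximately* idempotent: shrinkage
  leaves a small per-feature residual that a second pass shrinks again
  (the reference implementation behaves identically); the test suite
  asserts the second-pass change is an order of magnitude below the first.

# Cross-tissue analyses

Matched-tissue correlation (`matchedTissueCorrelation`) computes per-CpG
Spearman correlations of M values across individuals matched between two
tissues, against a null built by shuffling the individual matching and
pooling the resulting correlations; the report counts CpGs above the null
95th percentile and tests that count against the nominal 5% by a binomial
test. Tissue-pair differential methylation (`tissuePairDM`) reuses the EWAS
engine with tissue as the primary term, pairing matched samples through an
individual indicator when `individual_id` is available (on by default —
the matched design is the point of collecting matched samples).

DM-set overlap (`dmOverlapTest`) asks whether a query CpG set (e.g. the
villi DM sites) overlaps a target tissue's DM set beyond chance: random
same-size sets are drawn from the tested background without replacement
and the add-one-corrected empirical p is
$(1 + \#\{\mathrm{draws} \ge k_{\mathrm{obs}}\})/(n_{\mathrm{draws}}+1)$
(never exactly zero — with the default 10,000 draws the smallest
reportable value is $\approx 10^{-4}$), with the exact hypergeometric
upper tail reported alongside as a cross-check.

# Immune cell-type signatures and clustering

A cell class's specific CpGs (`deriveCellSpecificCpGs`) are the
intersection of DM sets from contrasts of that class against chorionic
villi and against each other immune class (neutrophil, eosinophil,
monocyte, lymphoid — the lymphoid class pools T, B and NK cells when they
are supplied separately), each contrast at FDR $< 0.05$ and $|\Delta\beta|
> 0.20$. Those defaults are a genuine open choice (published signature
thresholds vary); they are recorded in the `CellSignature` object and every
output manifest. Tightening them can only shrink a signature
(anti-monotonicity is property-tested).

Trend concordance (`trendConcordanceTest`) compares, per DM site, the sign
of (aCA − non-aCA villi) with the sign of (cell reference − non-aCA
villi); a site concordant in both signs supports the cell-infiltration
reading. Sites with tied means are excluded from the denominator. The
default p value is the upper-tail binomial under a 0.5 null; an empirical
p from random same-size CpG sets is always computed alongside, because a
"chance" baseline can also be defined by resampling the background.

Clustering (`hierarchicalCluster`, `clusterCellSignature`) is Euclidean on
beta values with average linkage by default; both scale and linkage are
configurable (M-scale clustering weights boundary CpGs more heavily; beta
scale matches how array heatmaps are usually drawn). Cluster confidence
uses two complementary procedures:

* **Multiscale bootstrap AU/BP** (`multiscaleBootstrapAU`): features
  (CpGs) are resampled with replacement at 10 relative sizes $r \in [0.5,
  1.4]$; per original node, $BP_r$ is the fraction of bootstrap trees
  containing the identical leaf set, and $z_r = \Phi^{-1}(1-BP_r)$ is fit
  against $(\sqrt{r}, 1/\sqrt{r})$ by weighted least squares with
  binomial-variance weights, giving the approximately unbiased support
  $AU = 1 - \Phi(v - c)$. Nodes with degenerate BP (all 0 or all 1) or
  fewer than two informative scales cannot be extrapolated and are
  flagged. 1,000 bootstrap replicates per scale is the default.
* **Monte-Carlo split significance** (`clusterSignificance`): the observed
  2-cluster index (within-split sum of squares over total) is compared
  with the best 2-split index of datasets drawn from a single Gaussian
  with diagonal covariance equal to the per-CpG sample variances. The
  diagonal-covariance null is a simplification of eigenvalue-model
  covariance nulls; with many more CpGs than samples it is the estimable
  choice, and it is what the calibration tests validate.

"Stable two-cluster structure" (`auStableTwoClusters`) requires the root
split to produce two clusters of at least two samples, both with $AU \ge
0.95$. A root that peels off a single sample is an outlier, not
structure — a one-sample side cannot carry cluster support and no split
test accepts it. Cluster–phenotype enrichment is a two-sided Fisher exact
test on the $2\times2$ cluster-by-aCA table, plus demographic comparisons
(Wilcoxon–Mann–Whitney for continuous covariates, exact below a combined
n of 30; Fisher for categorical; Kolmogorov–Smirnov for ancestry
coordinates).

# The synthetic cohort generator

`generateReferenceProfiles` + `generateCohort` emulate the statistical
structure the analysis assumes, with a full truth table:

* **Archetypes.** Each CpG gets a bimodal archetype beta (40% low in
  (0.02, 0.15), 20% intermediate in (0.25, 0.75), 40% high in
  (0.85, 0.98)) shared across tissues — the canonical bimodal array
  distribution.
* **Planted sets.** Disjoint CpG blocks are planted as tissue-specific,
  cell-type-specific (per immune class), direct-aCA, GA and sex effects,
  with beta-scale magnitudes `effect_delta`. Defaults: tissue 0.3;
  cell-type 0.4 (reference blood cell classes differ strongly, often
  near-binary, at their signature CpGs — planting them weakly would
  misrepresent how separable real references are); direct aCA 0.15; GA
  0.05 per 5 weeks; sex 0.1. Direct aCA effects default to **zero** —
  the generator's aCA signal is mixture-driven, reflecting the
  cell-infiltration hypothesis; direct effects are available as a dial
  for studies of the alternative mechanism.
* **Sampling design.** The default plan mirrors the discovery cohort:
  22 aCA + 22 non-aCA villi, 9 + 7 chorion, 8 + 7 amnion with shared
  individuals for matched tissues, and a six-donor reference panel per
  immune class with donors shared across classes. GA is drawn so the aCA
  group mean (≈30.8 weeks) is below the non-aCA mean (≈32.3), matching
  the cohort's significant GA difference; sex is balanced; ancestry
  coordinates come from a two-population structure mildly imbalanced
  between groups.
* **Noise and batch.** All effects and noise are additive on the M scale
  (residual SD 0.7, chip and row effects each SD 0.15 per feature),
  keeping betas in range after back-transformation — this mirrors
  modelling M values and the two ComBat passes. Betas are clipped to
  $(10^{-6}, 1-10^{-6})$.
* **Mixture.** Each aCA villus is mixed with the neutrophil reference
  profile: $\beta = (1-f)\beta_{\mathrm{villi}} +
  f\beta_{\mathrm{neutrophil}}$, $f \sim U(0.1, 0.4)$ by default, $f = 0$
  for non-aCA. Whole blood is modelled as a generic blood archetype that
  sits at the shared base at planted signature sites, so that
  cell-type-specific CpGs separate their class from *every* other type by
  construction.

What the generator does **not** emulate: probe-type I/II chemistry, raw
intensities and detection failure processes, spatially correlated chip
artefacts, correlated CpG blocks (every CpG is independent given its
archetype), realistic minor-allele structure in the AIM panel, and
cell-composition variation other than the single neutrophil fraction.
Passing tests therefore demonstrate the statistical machinery is correct
and calibrated under the assumed generative structure — not that the
pipeline is robust to artefacts the generator omits.

# Numerical choices and degenerate inputs

* Logit clipping $\varepsilon = 10^{-6}$ (clipped values are counted and
  warned about).
* BH is the standard step-up, NA p values propagate and never count
  toward the number of tests.
* EB batch iteration tolerance $10^{-4}$; features with zero pooled
  residual variance are an error (they indicate constant input).
* Per-CpG missing values: row-wise complete-case fits with per-row
  degrees of freedom; CpGs with one group fully missing get NA
  $\Delta\beta$.
* Spearman correlations exclude CpGs with fewer than 3 complete matched
  pairs or zero variance (excluded counts are reported).
* Merge-distance ties in `hclust` resolve to the lowest pair index;
  dendrogram node identity across bootstraps is the exact leaf set.
* Empirical p values use the add-one correction throughout.
* MDS signs are fixed (largest-magnitude coordinate positive) for
  reproducibility; degenerate configurations are padded with zero
  coordinates.

# Problem sizes in the shipped tests

The package's own validation uses cohorts of 300–20,000 CpGs: null
calibration and planted-effect recovery run at the full 20,000 × 44
design over 10 seeds; the signature-to-clustering mirror runs at 6,000
CpGs with 150 planted CpGs per immune class over 10 seeds (bootstrap
support at 300–1,000 replicates per scale). These sizes give stable
Monte-Carlo behaviour for every calibration check while keeping the suite
quick to run routinely.

# Known limitations

* Region-level (DMR) testing is not implemented; the per-CpG engine is
  the unit of inference.
* No reference-based cell-composition deconvolution: the package tests
  *concordance* with cell references and clusters on signatures, but does
  not estimate per-sample cell fractions — in this disease context
  cell-composition variance is signal, not nuisance, so it is
  deliberately not removed.
* The split-significance null uses diagonal covariance; strongly
  correlated CpG sets would make it anticlimactically conservative or
  liberal depending on structure.
* The EB batch model assumes additive location/scale batch effects on the
  M scale.
* Cross-platform site matching is an explicit CpG-id intersection; no
  probe liftover is attempted.
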