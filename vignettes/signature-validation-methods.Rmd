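---
title: "Validating a 24-gene hypoxia signature for soft-tissue sarcoma: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a 24-gene hypoxia signature for soft-tissue sarcoma: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxiaSTS)
```

## Why a hypoxia signature, and why this pipeline

Tumour hypoxia — chronically low oxygen inside solid tumours — drives
radioresistance, metastasis and poor prognosis, and it can be targeted
(hypoxia-modifying radiosensitisers, dose painting). Acting on it
clinically requires a test that labels a tumour *hypoxia-high* or
*hypoxia-low* from routine formalin-fixed biopsy material. A compact
transcriptional signature measured on a targeted counting assay
(nanoString nCounter) fits that brief: 24 hypoxia-responsive genes plus
a handful of endogenous reference genes, counted directly from ~100 ng
of RNA without amplification.

`hypoxiaSTS` implements every computational stage such a test needs —
lane-file handling, quality control, normalization, reference-gene
selection, classification, and the survival statistics used to validate
the classifier against patient outcomes — together with a calibrated
synthetic-data generator, because the patient-level data such a study
rests on cannot be distributed inside a package. The generator is not
an afterthought: every statistical routine here is validated end to end
by recovering the parameters that the generator was given.

## From lane files to a log2 expression matrix

An nCounter lane file (`.RCC`) carries a `Code_Summary` section with one
row per probe: endogenous signature genes, candidate housekeeping
genes, six positive spike-in probes at a known titration (128 fM down to
0.125 fM), and negative probes with no target. `read_rcc()` /
`write_rcc()` round-trip these files byte for byte;
`assemble_matrix()` joins lanes into a typed `expr_matrix` whose probe
roles drive everything downstream.

Lane QC (`qc_lane()`) follows vendor guidance: at least 75 % of fields
of view imaged; binding density within 0.05–2.25 spots/µm²; the
log–log regression of positive-probe counts on input concentration must
have R² ≥ 0.95; and the 0.5 fM positive probe must exceed the limit of
detection, defined as the negative-probe mean plus two standard
deviations. All thresholds are arguments of `qc_thresholds()`, not
constants.

`normalize_counts()` applies the standard four steps:

1. **Positive-control scaling.** Each lane is multiplied by
   (geometric mean of all lanes' positive geomeans) / (this lane's
   positive geomean). Geometric means are taken on count + 1 so a zero
   count cannot annihilate them.
2. **Background thresholding.** Endogenous counts below the lane's
   negative mean + 2 SD are *raised to* that threshold. Raising rather
   than subtracting keeps every value positive for the log step and
   never manufactures negative expression.
3. **Content normalization.** The same geometric-mean factor
   construction over the chosen endogenous reference genes.
4. **log2(x + 1).**

Both factors are recorded per lane (attribute `"norm_factors"`) and
checked against plausibility ranges (0.3–3 for the positive factor,
0.1–10 for the content factor). Note a structural property that the
test suite pins down: the pipeline is anchored at the grand geometric
mean, so rescaling one lane's counts shifts *all* lanes by a common
log2 constant while leaving every relative comparison untouched.

## Choosing the reference genes

Candidate housekeeping genes are first screened by coefficient of
variation (`cv_screen()`; with two cohorts, per-cohort CV ranks are
combined by mean rank so a gene must be stable in both). The surviving
candidates are ranked by the geNorm stability measure
(Vandesompele et al., 2002): for gene *j*,

$$M_j = \frac{1}{K-1}\sum_{k \ne j} \mathrm{SD}_s\!\left[\log_2
\frac{x_{js}}{x_{ks}}\right],$$

the average variability of its log ratio to every other candidate.
Because M is built from within-sample ratios, per-lane scale factors
cancel exactly — M can be computed on raw counts. `genorm_rank()`
iteratively removes the least stable gene (ties broken by dropping the
lexicographically last name, a deterministic convention) and sizes the
panel by the pairwise variation
$V(n, n+1) = \mathrm{SD}_s[\log_2(\mathrm{NF}_n/\mathrm{NF}_{n+1})]$,
selecting the smallest *n* with V below 0.15, the threshold proposed in
the original geNorm paper.

## The centroid classifier

`fit_centroids()` follows the classic R modelling idiom: it returns a
classed `centroid_model` object (with `print`, `coef` and `predict`
methods) holding the *unshrunken* per-class, per-gene mean profiles of
a labelled training cohort. A new sample is median-centred and assigned
to the centroid at the shortest Spearman distance
$d = 1 - \rho_{\mathrm{Spearman}}$ (average ranks for ties). Exact
distance ties go to "low" — the conservative call for a test whose
positive result escalates therapy. Rank correlation buys a strong
robustness property, verified in the test suite: any strictly monotone
per-sample distortion (lab-to-lab intensity shifts, scanner
nonlinearity) leaves every call unchanged.

The same property has a sharp consequence for simulation design. If the
hypoxia-high class were generated by adding a *uniform* log2 shift to
all 24 genes, the two centroids would share one rank order and a
rank-based classifier could not see the difference at all — every
sample would tie. Class separation must therefore live in the *pattern*
across genes. The generator's default effect alternates 0.5 and 1.5
log2 between adjacent genes (panel mean 1 log2), giving the two
centroids genuinely different rank orders while keeping the average
effect size at one doubling.

## The survival battery

All standard survival machinery is delegated to the `survival` package
rather than reimplemented; this package contributes the encodings,
rules and wrappers around it.

* **Cox models** (`cox_fit()`): Efron tie handling, Wald 95 % CIs and
  per-term p values. Covariates are encoded with clinically
  conventional references: hypoxia high vs low, male vs female, WHO
  performance status 1+ vs 0, grade I/II vs III (grade III the
  reference), deep vs superficial, R1 vs R0 margins, histology
  dummy-coded against leiomyosarcoma; age and tumour size stay
  continuous; "Unknown" strata of an included covariate are dropped.
* **Model building** (`select_multivariable()`): a covariate enters the
  multivariable model when its univariable likelihood-ratio p value is
  below 0.05; the hypoxia classification always enters.
* **Discrimination** (`c_index()`): Harrell's concordance via
  `survival::concordance()`; the reported standard error is the
  infinitesimal-jackknife estimate that routine provides.
* **Per-gene comparisons** (`compare_genes()`): Welch t or Mann–Whitney
  per gene, with discoveries flagged by the two-stage adaptive
  step-up of Benjamini, Krieger and Yekutieli (`two_stage_fdr()`):
  stage 1 runs the linear step-up at q′ = q/(1+q), its rejection count
  estimates the number of true nulls m₀, and stage 2 re-runs the
  step-up at q′·m/m₀. The deployed setting is stringent, Q = 1 %.
* **Risk stratification** (`stratify_pos()`): the binary hypoxia call
  crossed with nomogram-predicted 10-year overall survival at a 0.60
  cut-off (the boundary counts as favourable), compared by a K-group
  log-rank test with K − 1 degrees of freedom.

## Generator calibration

`sim_config()`'s defaults are the package's standing model of a
validation study; they are chosen from first principles and then held
fixed while the statistics are tested against them.

* **Expression.** Hypoxia-low per-gene means span 6–12 log2 counts (the
  assay's usable range); biological spread 0.3 log2 per gene; technical
  (replicate-lane) noise 0.05 log2, matching Spearman replicate
  correlations ≥ 0.98 across a 24-gene panel; lane library-size factors
  with 0.2 log2 spread. Seven candidate reference genes: five stable
  (SD 0.10 log2) and two deliberately loose ones (SD 0.45) so that
  stability selection has something to reject.
* **Survival.** Exponential event times under proportional hazards,
  administrative censoring at 5 years plus a small random-dropout
  hazard. Baseline rates are tuned analytically so event counts match
  realistic sarcoma cohorts: for example 0.016 events/year gives ~28
  local-recurrence events in a cohort of 280, and 0.075/year gives
  ~53 deaths in a cohort of 126.
* **Confounding.** Optionally, grade and tumour size are generated with
  class-dependent distributions and their own hazard effects, so that
  the marginal and conditional hazard ratios for hypoxia differ — the
  situation a multivariable model exists to handle. With confounding
  off (the default in recovery studies of univariable claims), survival
  depends on class alone and the generating hazard ratio is also the
  marginal one.
* **Multi-biopsy sampling.** Tumour-level biology plus a within-tumour
  SD per biopsy (3–8 biopsies per tumour); setting that SD to zero must
  and does yield fully concordant calls, which pins down the
  concordance bookkeeping itself.

## Numerical decisions worth knowing about

* **Hazard ratios are averaged on the log scale.** In recovery studies
  the replicate summary is `exp(mean(log HR))`. The arithmetic mean of
  an exponentiated coefficient is inflated by Jensen's inequality —
  noticeably so (~7 % and more) at low event counts — and would bias
  the summary upward for rare endpoints.
* **Geometric means are computed on value + 1** wherever raw counts can
  be zero; the log2 step likewise uses x + 1.
* **Cox convergence warnings are promoted to errors.** A monotone
  separation (a covariate that perfectly orders the failures) produces
  a divergent coefficient; the fit refuses rather than reporting a
  meaningless hazard ratio.
* **Deterministic tie rules everywhere**: exact classification ties go
  to "low"; geNorm exclusion ties drop the lexicographically last name;
  the pOS boundary 0.60 counts as favourable.

## Limitations

* The survival generator is exponential/proportional-hazards;
  the package does not provide proportional-hazards diagnostics,
  competing-risk models, or calibration plots.
* Centroids are unshrunken: with 24 pre-selected genes there is nothing
  to shrink away, but the object is not a general-purpose
  nearest-shrunken-centroid implementation.
* The C-index standard error is the infinitesimal-jackknife estimate,
  which can differ slightly from Harrell's original pairwise formula.
* Synthetic cohorts validate the *statistics*, not the biology: a green
  recovery study says the pipeline measures what it is pointed at, not
  that the 24 genes are the right genes.

## References

* Vandesompele J, et al. Accurate normalization of real-time
  quantitative RT-PCR data by geometric averaging of multiple internal
  control genes. *Genome Biology* 2002.
* Tibshirani R, et al. Diagnosis of multiple cancer types by shrunken
  centroids of gene expression. *PNAS* 2002.
* Benjamini Y, Krieger AM, Yekutieli D. Adaptive linear step-up
  procedures that control the false discovery rate. *Biometrika* 2006.
* Harrell FE, et al. Evaluating the yield of medical tests. *JAMA*
  1982.
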