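---
title: "Methods: quantifying domestic introgression from genomes and morphology"
author: "wildmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying domestic introgression from genomes and morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildmix)
```

## The problem

Wild progenitors of domesticated species — here the red junglefowl, the
ancestor of the domestic chicken — are threatened by *genetic swamping*:
recurrent gene flow from free-ranging domestic or feral conspecifics that
erodes the wild gene pool. Management agencies need two things: an estimate
of each individual's domestic ancestry from genome-wide SNPs, and a
field-usable morphological score that predicts that ancestry well enough to
triage birds without genotyping. wildmix implements both halves and the
statistical machinery linking them.

A distinctive feature of the design is the use of *historic anchor
samples*: museum specimens collected before the modern surge in
domestic contact. They define the "wild" end of the genomic continuum
far more defensibly than any present-day sample of unknown admixture
history, and the package uses them both to orient principal components
and to resolve label switching in the admixture model.

## Genotype QC

Input is a hard-called diploid GT VCF (genotype-likelihood-based calling,
read mapping and damage correction for degraded DNA are upstream of this
package). Three filters mirror standard practice:

* **Locus filters** (`filter_loci()`): call rate ≥ 0.90 (lenient regime;
  0.95 in the strict regime) and minor-allele frequency ≥ 0.01 (or 0.05),
  MAF computed on non-missing calls only.
* **Sample filter** (`filter_samples()`): individuals with *more than* 15%
  missing calls are excluded — the inequality is strict, so a sample at
  exactly 15% is retained.
* **LD pruning** (`ld_prune()`): sliding windows of 25 loci advanced by 10,
  removing the later-position member of any pair with squared dosage
  correlation above 0.5, iterated within each window to a fixed point.
  The later-member tie-break is a deliberate, documented choice (the
  classical tool leaves it unspecified); windows never span chromosomes.

**Kinship** (`kinship_ml()`) estimates, for every sample pair, the
IBD-sharing probabilities $(k_0, k_1, k_2)$ by maximum likelihood under
Hardy–Weinberg proportions and independent loci, and reports
$\varphi = k_2/2 + k_1/4$. The likelihood is a three-component mixture
with fixed component densities, so we maximise it by EM on the mixing
weights (monotone by construction) from three starting points, plus an
explicit evaluation of the three simplex vertices — EM approaches a
boundary optimum only geometrically, and the vertex check guarantees the
returned solution never falls below the exact unrelated, parent–offspring
or duplicate solutions. Pairs with $\varphi \ge 0.177$ (midpoint between
first- and second-degree expectations on the $2^{-k-3/2}$ ladder — the
study named the relationships but no cutoff) are flagged first-degree.
Flagged kin are *reported but retained* by default, matching the original
analysis; `drop_kin = TRUE` reproduces the sensitivity re-run. Pairs with
fewer than 50 overlapping informative loci are flagged
`insufficient_data` rather than called.

## Population structure

`run_pca()` mean-imputes missing dosages per locus, centres columns, and
scales them by $\sqrt{\hat p (1-\hat p)}$ (Patterson scaling), then takes
the SVD. PC1 is the domestic–wild continuum proxy; its sign is flipped if
needed so the anchors (historic cohort, else a user-designated wild proxy
set) sit above the captive cluster.

`fit_admixture()` replaces the original Bayesian MCMC clustering with a
maximum-likelihood admixture model of the *same generative form*: with
dosage $g_{il} \in \{0,1,2\}$ and $\pi_{il} = \sum_k Q_{ik} P_{kl}$,

$$\ell(Q, P) = \sum_{il} \big[ g_{il} \log \pi_{il} + (2 - g_{il}) \log (1 - \pi_{il}) \big],$$

maximised by block-relaxation EM over $Q$ (rows on the simplex) and $P$.
This choice trades the MCMC's posterior for determinism, desk-scale
runtimes and a testable monotonicity contract (the log-likelihood trace
must never decrease). Numerical choices: missing genotypes are skipped in
the likelihood (not imputed — imputation would bias $Q$ for the sparse
historic samples), $P$ is clamped to $[10^{-6}, 1-10^{-6}]$ to keep
$\ell$ finite, convergence is declared at relative change $<10^{-6}$ or
2000 iterations, and the best of `n_replicates` (default 10) random
restarts is returned. Cluster labels are arbitrary, so components are
relabelled after fitting: the component with the highest mean membership
over the anchors becomes "wild". No test for an optimal $K$ is run —
deliberately, as in the original design: only the single component
reflecting domestic admixture is of interest, and $K$ is a configuration
input (default 2).

`classify_genomic()` labels an individual wild-type when its wild
membership coefficient satisfies $q \ge 0.9$ — the inclusive threshold
set by the historic anchors, which themselves show $q \ge 0.9$ despite
evidence of some old introgression.

## Morphology scoring

`trait_schema()` encodes the sex-specific categorical scheme: 16 male and
10 female plumage/bare-part traits, each scored 1 for the wild character
state and 0 for a domestic state, with 0.5 available only for the traits
whose colour can be partially wild (male Body, Tail, Sec, S, Lap, Beak;
female Body, BP, WC). The raw sum is normalised by the sex maximum and
expressed on a 0–100 scale so sexes are comparable (`score_individual()`).
Only adults are scorable (juvenile plumage is unstable) and any obscured
or missing trait makes a record unscorable rather than imputed — exclusion
bookkeeping is reported explicitly. Display rounding is half-up to two
decimals (78.125 → 78.13), while comparisons always use full precision;
the published score table contains one unrounded value (46.875), which we
treat as a typesetting inconsistency. The published 62-individual score
table ships with the package (`reference_scores()`); its captive-cohort
maximum of 18.75 is the empirical basis of the domestic cutoff below.

## Linking morphology to genomics

* `regress_morphology()` fits OLS of the genomic axis (oriented PC1
  scores, or $q$) on the morphology score. The axis is the response, as in
  the original plots; with a single predictor $R^2$ is symmetric, so the
  headline statistic is unaffected by direction. Both raw and standardised
  axes give the same $R^2$ and $p$; the slope naturally depends on axis
  scaling, which is why the fit records which axis was used.
* `trait_pca_contributions()` runs a correlation PCA (centred,
  unit-scaled — the morphometric convention; the original text does not
  state the scaling) on one sex's trait matrix and reports each trait's
  contribution to PC1, $100\,\lambda_j^2 / \sum_j \lambda_j^2$. Traits
  exceeding the expected average $100/p$ are the candidates for model
  selection. Constant columns are excluded with a warning and reported
  with contribution zero.
* `aic_model_search()` fits OLS for every non-empty candidate subset
  (unioned with any forced traits — female tarsus colour is forced in the
  pipeline, given its standing interest as an introgressed trait) and
  ranks by $AIC = 2\,df - 2\hat\ell$ with the Gaussian-MLE log-likelihood
  $\hat\ell = -\tfrac n2 (\log(2\pi\,RSS/n) + 1)$ and $df = p + 2$
  (slopes + intercept + residual variance). This is exactly
  `stats::AIC` on an `lm` for full-rank fits; for aliased predictors we
  keep the nominal-predictor penalty so a redundant trait can never
  improve the ranking. Categorical traits enter as numeric 0/0.5/1,
  matching the formula notation of the original model table.
* `classify_morphology()` / `threshold_report()`: scores strictly above
  75 are classed wild (zero false positives against wild-type genomic
  profiles in the original data), strictly below 25 domestic (the captive
  maximum was 18.75), otherwise intermediate. Boundary values fall in the
  intermediate class — the published rules are strict inequalities and
  never adjudicate equality, so we state the choice explicitly. The
  report counts false positives (morphology-wild but genomically
  non-wild) and false negatives (genomically wild but scoring below the
  cutoff); false negatives are expected and, from a manager's viewpoint,
  tolerable — such birds show visible signs of introgression.

## The synthetic-data generator

Because the original raw genotypes are not redistributable, every stage is
tested against `simulate_dataset()`, which emulates the study design with
known truth:

* **Allele frequencies**: common ancestral $p_0 \sim U(0.05, 0.95)$ per
  locus; wild and domestic pool frequencies drawn independently from the
  Balding–Nichols construction
  $\mathrm{Beta}\!\big(p_0 \tfrac{1-F}{F},\,(1-p_0)\tfrac{1-F}{F}\big)$
  with drift $F = 0.2$ by default — a moderate wild–domestic divergence.
  The model gives $E[p\mid p_0] = p_0$ and
  $\mathrm{Var} = F\,p_0(1-p_0)$, both verified by test.
* **Individuals**: genotypes $\sim \mathrm{Binomial}(2,\; q_i p^w_l +
  (1-q_i) p^d_l)$ along an ancestry gradient: captive
  $q \sim \mathrm{Beta}(1, 19)$ (near 0), wild and historic
  $q \sim \mathrm{Beta}(19, 1)$ (near 1), feral $q \sim U(0.05, 0.95)$.
  Default cohort sizes 20 wild / 20 feral / 9 captive / 2 historic mirror
  the field situation (nine farm birds, two museum anchors).
* **Missingness**: calls masked at 2% baseline and 12% for the historic
  cohort. The historic rate is deliberately set *below* the 15%
  sample-exclusion threshold: anchors must survive QC to orient the
  continuum, exactly as the real museum samples passed quality filtering.
  Twelve percent is still sixfold elevated, which exercises the
  missingness-aware likelihood.
* **Traits**: each binary trait's wild-state probability is
  $\mathrm{logit}^{-1}(a_t + b_t q)$ with slope $b_t \sim U(4, 8)$ and
  $a_t = -b_t/2$, placing the flip-point mid-gradient; three-level traits
  use an ordered logistic with cutpoints at $\pm 1$ on the same latent
  scale. Historic samples carry no trait records (museum specimens are
  not colour-scorable).

What the generator does **not** emulate: linkage (loci are unlinked, so
LD-pruning tests use explicitly planted correlated loci), post-mortem DNA
damage biases (historic sparsity only), spatial/locality structure, and
pedigree structure (kinship tests construct duplicate and
parent–offspring pairs directly). A green test on synthetic data
therefore establishes correctness of the estimators under the stated
generative model, not robustness to these real-data complications.

## Design choices made where the design was open

* The acceptance-scale selection-consistency simulation plants two traits
  expressed near-deterministically along the gradient (logistic slope 14)
  and an axis driven by those two traits plus noise — the strong-signal
  world in which best-subset AIC can be expected to recover the true pair;
  with weaker slopes AIC's well-known $\approx 16\%$ per-noise-variable
  overfitting probability makes exact recovery impossible at any rate
  above chance-of-overfit, which no implementation could change.
* Genotype posteriors → hard calls: the original pipeline's conversion is
  unstated; this package standardises on GT input and leaves calling
  upstream.
* Oversampled-site thinning (a manual curation step in the original
  study) is supported only as an explicit sample-keep list (subset the
  `genotype_matrix` before analysis), never automated.
* Wild-type percentages and the headline $R^2 = 52\%$ of the original
  data depend on unreleased per-individual genotypes and are not
  reproduction targets; the regression machinery is instead validated on
  synthetic gradients where truth is known.

## Known limitations

Kinship estimation is quadratic in samples and EM-based per pair — fine
for field-study scales (dozens of samples), slow for thousands.  The
admixture model assumes unlinked loci after pruning and no
correlated-frequencies prior; with very few markers the continuum
degrades gracefully (more admixed-looking intermediates), as observed in
the original reduced-representation dataset. Morphology scoring consumes
pre-coded trait levels; it does not do image analysis, continuous traits
(comb, wattle, spur) or eclipse-plumage logic.
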