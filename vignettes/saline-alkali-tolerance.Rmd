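---
title: "Comprehensive saline-alkali tolerance evaluation and association mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensive saline-alkali tolerance evaluation and association mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Saline–alkali soils depress every yield-related trait of rice, but no single
trait measures tolerance: an accession may keep its tiller number while losing
grain weight, and raw trait values confound tolerance with intrinsic vigour.
`satol` implements the standard multi-trait evaluation chain used for
screening stress-tolerant germplasm in two-treatment (control CK vs stress
AK), multi-year field trials, and an association scan of the resulting
tolerance score:

1. descriptive statistics, coefficients of variation and Shannon–Weaver
   diversity of the trait panel;
2. per-group Pearson correlation, correlation-matrix PCA and Ward clustering;
3. three-factor ANOVA and REML variance components feeding a
   multi-environment broad-sense heritability;
4. the stress/control *salt tolerance index*, fuzzy membership functions and
   the comprehensive score `D`;
5. a mixed-linear-model GWAS of `D` with Bonferroni thresholding and
   candidate-region annotation.

A synthetic trial generator with known ground truth makes every step testable
end to end.

## The comprehensive score D

For accession $i$ and trait $t$ in one year, the salt tolerance index is the
stress value as a percentage of the control value,

$$S_{it} = 100 \cdot V^{AK}_{it} / V^{CK}_{it},$$

so 100 means "unaffected". The accession-by-trait index matrix is
standardized and decomposed by correlation-matrix PCA. For each retained
component the scores are mapped through the fuzzy membership function

$$U_i = (S_i - S_{\min}) / (S_{\max} - S_{\min}) \in [0, 1],$$

weighted by the normalized variance contributions $W_i = PV_i / \sum PV_i$,
and aggregated into

$$D = \sum_i U_i W_i \in [0, 1].$$

Larger `D` means more tolerant. Components are retained up to a cumulative
variance contribution of 80% (configurable); a fixed count is also available.

Two decisions here are genuinely open in the field's practice and are made
explicit because `D` is **not** invariant to them:

* **PC sign convention.** A principal component is defined up to sign, and
  the membership function maps a flipped component to $1 - U$. Each component
  is therefore flipped deterministically so that its largest-|loading| entry
  is positive, and the applied flips are reported in the score provenance.
* **Trait subset.** Trials commonly drop a trait that shows no treatment
  response (here seed-setting rate is the usual candidate). The default
  scores all nine traits; `drop_sr = TRUE` scores eight. The choice is
  surfaced rather than hard-coded because the scored subset changes `D`.

The index matrix is standardized before PCA (correlation, not covariance
PCA), consistent with the standardization applied to the phenotype PCAs; this
also makes `D` invariant to positive rescaling of any single index column.

## Heritability

Variance components per trait come from the REML fit of

`value ~ year + treatment + (1|G) + (1|G:year) + (1|G:treatment)`

(lme4), with genotype, genotype-by-year and genotype-by-treatment random.
Broad-sense heritability across $L$ treatments and $Y$ years is

$$R = \frac{V_A}{V_A + V_{AL}/L + V_{AY}/Y + V_e/(LY)},$$

the genotypic variance relative to the variance of a genotype mean over the
whole trial. $R$ increases in $V_A$, $L$ and $Y$ and lies in $[0,1]$.
Components at the zero boundary are kept at 0 and flagged. The companion
three-factor ANOVA (Type III sums of squares, sum-to-zero contrasts, fixed
genotype) serves the significance table; fitting genotype fixed in the ANOVA
and random in the variance-component model mirrors common trial practice, and
both are exposed.

## GWAS of D

The scan fits the null mixed model $y = X\beta + u + e$,
$u \sim N(0, \sigma^2_g K)$, with $K$ the VanRaden genomic relationship
matrix $ZZ'/(2\sum p_k(1-p_k))$. The variance ratio
$\delta = \sigma^2_e/\sigma^2_g$ is estimated once by REML on the eigenbasis
of $K$ (profiled log-likelihood maximized over $\log\delta \in [-10, 10]$)
and then fixed for all markers (P3D), each tested by generalized least
squares with a two-sided Wald $t$ test. With $K = I$ the scan collapses
exactly to ordinary least squares, which is one of the oracle tests.

This is a plain mixed linear model rather than a *compressed* MLM: kinship
compression is an efficiency device for very large panels and changes the
model only through grouping; at the scales this package targets the
uncompressed model is exact and simpler. This is the one intentional
methodological deviation and it is confined to `mlm_scan()`.

Significance uses the Bonferroni cutoff on the $-\log_{10}$ scale,
$\log_{10}(m)$ for $m$ scanned markers (after filtering; a panel of 189,019
markers gives 5.28). The genomic inflation factor
$\lambda = \mathrm{median}(\chi^2)/0.4549$ is always reported and no genomic
control is applied. Note that significant-marker tables elsewhere sometimes
print $\log_{10}(p)$ (negative); this package reports $-\log_{10}(p)$
(positive) throughout.

Candidate regions collect genes whose span intersects ±150 kb around a
significant marker — the reported LD-decay scale for temperate japonica
populations, configurable. Distances are to the gene span, 0 inside a gene
(with exon/intron context from the exon layout); ties break to the lower
start coordinate; coordinates are 1-based inclusive throughout (VCF/GFF3
convention). Region variants are classified exonic > intronic > intergenic,
SNP vs InDel by allele length.

## The synthetic trial

`sim_config()` / `simulate_phenotypes()` emulate a 450-accession, 2-year,
2-treatment trial over nine traits. Control values follow
$y = \mu_t + g_i + y_j + (gy)_{ij} + e$ with independent normal effects;
stress values are multiplicative,

$$y^{AK} = y^{CK} \cdot r_i + (gl)_i + e',$$

with the per-accession tolerance ratio
$r_i = \text{base} + \sum_k \beta_k (x_{ik} - \bar x_k) + \varepsilon_i$
floored at $10^{-3}$. Causal markers act on the *ratio*, not on raw traits,
so the stress/control index is the natural estimand and a GWAS on `D` should
recover them — this encodes the assumed causal chain.

Defaults are chosen as realistic field magnitudes: trait means of a
high-latitude japonica panel (e.g. plant height 95 cm, thousand-grain weight
25 g, heading at 100 days), per-trait effect SDs of 10% (genotype), 5%
(year), 4% (G×Y), 3% (G×L) and 8% (residual) of the trait mean, a base AK/CK
ratio of 0.85 (stress depresses growth), ratio SD 0.05, and three causal
markers of effects 0.15/0.12/0.10 per dosage unit at MAF drawn from
[0.05, 0.5]. Genotypes are unlinked binomial draws on 12 chromosomes
(`ld_block_size` adds block-copy LD when regions matter). One master seed
derives per-component sub-streams, so phenotype noise can be redrawn without
changing genotypes. Seed-setting rate is clamped to $[0,1]$ and all traits to
non-negative values.

What the generator does **not** emulate: population structure and admixture,
recombination/LD maps, spatial field trends, selection, and trait-specific
genetic architectures. Passing recovery tests therefore shows the chain is
correct under its own assumptions, not that real trials are free of the
confounders those features create.

A separate additive balanced-trial generator, `simulate_balanced_trial()`,
draws directly from the random-effects model the REML estimator assumes
(`y = mu + g + year + treat + gy + gl + e`). It exists because in the
multiplicative trial the stress value reuses the realized control value —
including its residual — and the G×treatment deviation enters the stress
equation only, so additive variance-component "truths" are not well-defined
there. Parameter-recovery tests for REML and heritability run against this
generator; ranking-consistency tests for heritability run against the
multiplicative trial.

## Numerical choices

* Missing phenotype cells are mean-imputed before PCA (count logged), keeping
  every accession scoreable; correlations use pairwise-complete observations;
  trait summaries exclude missing values listwise.
* Sample (n−1) SD everywhere, including the CV (`100·SD/mean`; zero mean
  flagged).
* Shannon–Weaver H′ defaults to *distinct* mode (each distinct observed value
  a group), whose ceiling is $\ln N$; a 10-class binned mode (classes of
  width $4\sigma/(k-2)$ between $\mu \pm 2\sigma$) is provided as the
  germplasm-survey convention.
* Ward clustering uses Ward.D2 (squared-distance updates) on Euclidean
  distance — the common reading of "Ward minimum variance"; merges are
  monotone and assignment is deterministic in input order.
* Degenerate membership components (all scores equal) map to 0.5 with a
  warning; empty retained component sets are an error.
* Scan p-values are floored at 1e-300 before the $-\log_{10}$ transform;
  missing dosages are mean-imputed per marker for kinship and testing;
  non-PSD kinship is refused with a jitter suggestion.
* Marker filters default to MAF ≥ 0.05 and missingness ≤ 0.2; the Bonferroni
  threshold uses the post-filter marker count.

## Problem sizes

The test suite and the acceptance script run the chain at desk scale as the
package's own verification conditions: 300 accessions × 2,000 markers for
GWAS calibration (null inflation factor, type-I error) and power (20 seeds,
one causal marker of effect 0.15), 200 accessions × 2 years × 2 treatments ×
20 seeds for REML recovery, and a 450 × 3,000 trial for the end-to-end
analysis scripts. These sizes give stable Monte-Carlo estimates while keeping
a full run in minutes.

## Limitations

* `D` depends on the retained-component rule, the PC sign convention and the
  scored trait subset; all three are logged per run, and cross-study
  comparisons of `D` values are only meaningful under identical settings.
* The MLM uses a single variance-ratio estimate (P3D); per-marker REML would
  be marginally more exact and substantially slower.
* Variant classification is region-level (exon/intron/intergenic, SNP/InDel);
  codon-level consequence prediction is out of scope.
* Heritability assumes the balanced random-effects decomposition; severely
  unbalanced trials are fit by REML but the closed-form denominator keeps its
  $1/L$, $1/Y$ weights.
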