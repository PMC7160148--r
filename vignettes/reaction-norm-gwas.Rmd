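---
title: "Single-step reaction-norm GWAS: models, choices, and what the synthetic experiments show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step reaction-norm GWAS: models, choices, and what the synthetic experiments show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ssgrn` implements a two-stage genome-wide association analysis for
genotype-by-environment interaction (GxE) in livestock populations where no
external environmental covariate is recorded. The motivating setting is a
beef-cattle fertility trait (age at first calving, AFC, in days) measured
once per heifer across many herds with very different management and
nutrition; the package is written against that shape of data — a deep
pedigree, a part-genotyped population, records organised in contemporary
groups (CGs) — but nothing ties it to cattle specifically.

This vignette documents the models, every numerical and design choice a
maintainer might question, what the synthetic-data generator does and does
not emulate, and consequently what the test suite can and cannot certify
about real data.

## Stage 1: the environmental gradient

With no temperature-humidity index or feed records available, the
environment a CG experienced is summarised by its effect on a
*descriptor trait* — here yearling body weight (YBW, kg), which integrates
nutrition and management. The descriptor model is a standard animal model

$$y = X\beta + Za + e, \qquad
  a \sim N(0,\, H\sigma^2_a), \quad e \sim N(0,\, I\sigma^2_e),$$

with fixed CG effects and age at recording as a linear covariable, and the
additive effect structured by the single-step relationship matrix $H$
(below). The best linear unbiased estimates (BLUEs) of the CG effects are
standardized over the unique CGs to mean 0 and standard deviation 1 — the
*environmental condition* (EC) descriptor — and winsorized at $\pm 3$.

Choices made where the method statement is silent:

* **Standardization over CGs, not records.** The descriptor is a property
  of the CG; weighting by CG size would let a few huge herds define the
  scale.
* **Population-sd convention** (divide by $n$, not $n-1$). One has to pick;
  at realistic CG counts the difference is in the third decimal.
* **Winsorizing, not dropping**, CGs beyond $\pm 3$: keeps their records in
  the stage-2 fit while respecting the declared gradient range.
* **Residual classes.** Stage 2 uses five heterogeneous residual classes
  over the gradient with fixed boundaries $(-1.5, -0.5, 0, 1.5)$, half-open
  upward (EC $=1.5$ falls in class 5). A 1-D k-means alternative
  (`kmeans_residual_classes()`, fixed seed, multiple restarts) is provided
  for data whose EC distribution makes the fixed map unbalanced; the fixed
  map is the default because it is exactly reproducible.

## The single-step relationship matrix

Genotyped and ungenotyped animals are analysed jointly through

$$H^{-1} = A^{-1} +
  \begin{bmatrix} 0 & 0 \\ 0 & G_b^{-1} - A_{22}^{-1} \end{bmatrix},$$

where $A$ is the pedigree (numerator) relationship matrix with inbreeding
(tabular method), $A_{22}$ its genotyped block, and
$G_b = w\,G + (1-w)A_{22}$ a blended VanRaden genomic matrix,
$G = M_cM_c'/(2\sum_k p_kq_k)$ with dosages centered by $2p_k$.

* **Allele frequencies** are those observed in the genotyped set;
  base-population frequencies are not reconstructable without extra data.
  A consequence worth knowing: observed-frequency centering puts the ones
  vector in the null space of an unblended $G$, which is therefore always
  singular. Back-solving handles this by solving on the range of $G$
  (eigen pseudo-inverse); $H^{-1}$ construction requires blending.
* **Blend weight** $w = 0.95$ by default (configurable up to 1), the
  standard ssGBLUP guard.
* **No $\tau/\omega$ scaling** of the correction block: the formula above
  is implemented literally.
* **Dense algebra throughout**; the intended scale is $\lesssim 10^4$
  animals. Sparse Henderson rules for $A^{-1}$, metafounders and APY are
  out of scope.
* Missing genotype calls are mean-imputed ($2p_k$) only when a dosage
  matrix is built; stored calls keep their NAs.

## Stage 2: the reaction-norm model

Genetic merit for the target trait is a line over the gradient. With
$\phi_f$ the *normalized* Legendre polynomials
($\Phi_f(x)=\sqrt{(2f+1)/2}\,P_f(x)$, the random-regression convention)
evaluated at $x = \mathrm{EC}/3$:

$$y_{ij} = F_{CG} + \sum_{f=0}^{1}\omega_f\Phi_f(EC_j)
         + \sum_{f=0}^{1}\alpha_{fi}\Phi_f(EC_j) + e_{ij},$$

$$\{\alpha_i\} \sim N\!\left(0,\, H \otimes K\right),\qquad
  K = \begin{bmatrix}\sigma^2_a & \sigma_{ab}\\
                     \sigma_{ab} & \sigma^2_b\end{bmatrix},
  \qquad e \sim N(0, R),$$

with $R$ diagonal holding one variance per residual class. Derived
surfaces: genetic variance $\sigma^2_a(\mathrm{EC}) = \phi K \phi'$,
genetic correlation between levels
$\phi_1 K \phi_2' / \sqrt{\sigma^2_a(1)\sigma^2_a(2)}$, and heritability
$\sigma^2_a / (\sigma^2_a + \sigma^2_{e,\mathrm{class}})$.

* **Domain mapping.** How the sd-scale gradient maps to the Legendre
  domain $[-1,1]$ is a free choice; dividing by the declared range
  ($\pm3$) is the minimal one, and with intercept + slope only it is a
  pure reparameterization — fits, correlations and tests are unaffected,
  only the scale of $K$ changes.
* **The fixed regression $\omega_f$ is kept in the model although it is
  collinear with the CG effects** (EC is a deterministic function of CG).
  The design builder (`fixed_design()`) resolves this by a sequential
  rank rule: full dummies for the first factor, later columns dropped if
  linearly dependent, with the dropped names reported. Estimable
  functions are invariant to this constraint (tested).
* **Identifiability of the slope** requires at least two distinct EC
  levels; a flat gradient is rejected with an explicit error.

## REML

Variance components ($K$ and the class residuals) are estimated by REML
with two interchangeable engines:

* **AI** (default): average-information updates on the dense phenotypic
  covariance $V = H_{\mathrm{rec}} \odot (\Phi K \Phi') + R$, with step
  halving whenever a step would decrease the restricted likelihood and
  eigenvalue flooring at $10^{-8}$ to keep $K$ positive definite.
  Convergence: largest relative parameter change $< 10^{-8}$ (the cap is
  200 iterations; non-convergence warns and flags the last iterate).
* **EM**: expectation-maximization through the mixed-model equations.
  Guaranteed ascent (tested property), linear convergence; used as a
  cross-check and for small problems.

Both agree with the closed-form ANOVA REML estimator on balanced one-way
designs to five decimals (tested). The solver itself is checked against a
brute-force GLS oracle ($V^{-1}$ formed explicitly) on dozens of random
instances, including mixed residual classes, to $10^{-8}$.

PEV blocks come from the inverse coefficient matrix; per-coefficient
accuracy is $\sqrt{\max(0, 1 - \mathrm{PEV}_{qq}/K_{qq})}$ — the
coefficient's own prior variance in the denominator, since the
back-solving filter applies to intercept and slope separately. PEV can
exceed the prior variance in weakly connected designs (fixed-effect
uncertainty); such values clamp to accuracy 0 with a warning.

## SNP effects, tests, calibration

Per-SNP intercept/slope effects are back-solved from the coefficient
BLUPs of the genotyped animals that pass the accuracy filter
(default $\geq 0.40$ on both coefficients):

$$\hat u_q = \frac{1}{2\sum p_kq_k} M_c' G_b^{-1} \hat a_q,$$

projected to any level as $\hat u_k(\mathrm{EC}) = \alpha_k\,\phi'$, with
variance share $2p_kq_k\hat u_k^2/\sigma^2_a(\mathrm{EC})\times 100$
(the effect enters squared — the unsquared form has wrong units and sign).
With an unblended $G$ and $\hat a$ in the row space of $M_c$ the
back-solve is an exact projection ($M_c\hat u = \hat a$, tested to
$10^{-6}$).

**The test statistic.** A literal reading of
$z = \hat u / \sqrt{\sigma^2_{SNP}}$ with the *realized* per-SNP variance
share degenerates: since $\sqrt{\sigma^2_{SNP}} \propto |\hat u|$, its
magnitude is constant and yields no p-value distribution (kept behind
`literal = TRUE` for inspection). The working statistic standardizes
genome-wide within each level — but on the per-SNP variance scale,
$x_k = \hat u_k/\sqrt{2p_kq_k}$, because back-solved effects have
standard deviation proportional to $\sqrt{2p_kq_k}$; standardizing raw
effects mixes scales across the MAF spectrum and measurably fattens the
null tails (null simulations: tail proportion at $p<0.01$ near 0.013,
$\lambda \approx 0.93$ – $0.95$), while the heterozygosity-scaled form
calibrates ($\lambda \approx 1.00$, tails within 3 binomial SEs — these
are exactly the quantities the acceptance suite recomputes). Two-sided
normal p-values, Benjamini–Hochberg q-values, the declared significance
rule $-\log_{10}p > 6$ (a 450k-panel operating point; the desk-scale
workflow drivers use 3), and the threshold-form FDR estimate
$n_m\,p_{sig}/n_{msig}$ are all reported.

**Inflation.** $\lambda = \mathrm{median}(z^2)/0.456$, the $\chi^2_1$
convention. The literal median-p ratio is also computed but sits near
$0.5/0.456 \approx 1.10$ for *any* calibrated test and cannot detect
inflation; the $\chi^2$ form drives interpretation.

## Annotation

Offline only: gene intervals from BED (converted to 1-based inclusive on
read) or GFF3, gene sets from GMT. Significant SNPs map to genes whose
interval intersects the *closed* window $\pm 200$ kb around the SNP (the
flank reading of a "200 kb region"; the total-width reading is a
parameter away). Enrichment is an upper-tail hypergeometric test per set
with BH control at 5% across sets, the universe being the annotation's
own gene list. LD is genotype-correlation (composite) $r^2$ over
complete pairs — phases are not available, so haplotype-EM $r^2$ is not
attempted.

## The synthetic-data generator

`simulate_study()` builds: a discrete-generation pedigree whose sires
serve several matings spread over that generation's CGs (so CGs are
connected through common sires, with a fix-up pass guaranteeing every
multi-mating sire spans $\geq 2$ CGs); founder genotypes at
Hardy–Weinberg proportions with uniform founder MAF, descendants by
Mendelian gene dropping at unlinked loci on a 29-autosome map; a
descriptor trait (default $h^2 = 0.3$, CG effects normal with sd =
range/6 so standardized effects span roughly $\pm 3$ — the method
statement gives no distribution, and a bounded uniform draw could never
reach the declared $\pm 3$); and the reaction-norm target trait with
polygenic coefficients following the pedigree, QTL effects on the markers
themselves, heterogeneous residuals by EC class, and a full truth table
(realized $K$, per-QTL effects, true CG effects and EC levels).

Defaults emulate the motivating study's shape at desk scale: AFC-like
mean 1050 d, $K$ with intercept variance 1600 d², slope variance 900 d²
and *negative* intercept–slope covariance (−240 d², genetic correlation
between extreme environments ≈ 0.3), residual class variances declining
from 2800 to 1600 d², QTLs carrying half the genetic variance.

What it deliberately does **not** emulate: linkage disequilibrium beyond
what pedigree transmission induces (unlinked loci), selection,
genotyping-platform error, imputation error, and environment descriptors
measured with noise. Passing tests therefore certify the estimator
chain — not robustness to LD structure or ascertainment in real panels.

Two generator details exist purely for honest experimentation:

* `qtl_effect_dist = "fixed"` gives every QTL an equal variance share
  with random sign. Detection-power experiments need this: under
  Gaussian effects roughly a third of QTLs carry effects too small for
  *any* method to see, so "$\geq 90\%$ of QTLs behave like X" statements
  would measure the effect-size lottery, not the method.
* In `slope_only` / `intercept_only` modes the QTL share is taken only
  from the targeted component (congruence-scaled polygenic remainder), so
  the other component keeps its full polygenic variance — otherwise the
  coefficient covariance degenerates to rank one and the fit's
  intercept/slope BLUPs become artificially collinear.

## Problem sizes in the test and acceptance suites

Chosen once, as the package's own desk-scale study conditions:

* Parameter recovery: 10 replicates of 2,000 animals (500 founders, 4
  generations), 5,000 SNPs, 200 QTL, 60 CGs, 50% genotyped; the fit sees
  the true gradient (it is a property of the REML stage, not of stage-1
  estimation error). Recovery is judged against the replicate-realized
  $K$, within two empirical standard errors of the replicate mean.
* Null calibration: 10 replicates of 1,200 animals, 1,500 SNPs, pure
  polygenic (no QTLs); $\lambda$ per level and pooled tail proportions.
  The accuracy filter is off here — in small null simulations it can
  retain almost nobody and it is irrelevant to calibration; the filter
  itself is exercised at its 0.40 default elsewhere.
* GxE detection asymmetry: 5 + 5 replicates of 2,000 animals with five
  fixed-share QTLs on one component only and residual variance 600 d²
  (a clear-signal world — the contrast being tested is qualitative:
  slope-only QTLs score higher at $\pm 3$ than at 0, intercept-only QTLs
  score level-independently).
* End-to-end: the workflow in `analysis/` runs at 1,600 animals / 2,500
  SNPs; the pipeline smoke test at 450 animals / 300 SNPs, twice, and
  its outputs must be byte-identical under a fixed seed.

## Known limitations

* Dense matrices cap the practical scale around $10^4$ animals.
* Variance-component estimates for the slope are weakly identified when
  one record per animal is all there is and families do not span
  environments; at a few hundred records the spurious slope variance can
  reach a quarter of the intercept variance. This is a property of the
  design, visible in the tests, and the reason the recovery experiments
  run at thousands of animals.
* The back-solved SNP test is calibrated under the generator's null;
  real-panel LD will correlate neighbouring tests and BH control is then
  approximate, as for any back-solved GWAS.
* The workflow is organised as numbered analysis drivers over package
  functions (`analysis/01_simulate.R` … `06_annotate.R`) rather than a
  subcommand CLI; `run_pipeline()` covers the one-shot case.
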