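---
title: "Models and methods behind the hair-shedding evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the hair-shedding evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The trait and the evaluation problem

Early-summer hair shedding in beef cattle is scored once a year on a 1-5
visual scale (1 = winter coat fully shed). Because the score responds to
heat stress and to fescue toxicosis, it is used as an indicator of
thermotolerance, and a routine genetic evaluation of the trait needs the
full quantitative-genetics toolchain: careful phenotype preparation and
contemporary grouping, pedigree and genomic relationships blended in the
single-step fashion, repeated-records animal models estimated by REML,
validation of breeding values, and a downstream association scan. This
package implements that toolchain end-to-end and pairs it with a
synthetic-data generator so every stage can be exercised against known
truth.

## Phenotype preparation

Records pass through filters in a fixed order: same-day duplicate scores
on an animal are averaged; records are dropped when the reported sex
disagrees with the pedigree, when the animal is male, younger than 275
days at scoring, or when the breeder-reported age differs from the
calculated age class by more than two years. Age classes follow shifted
year windows: class $n$ spans $(n \cdot 365) - 90$ days (inclusive) to
$((n+1) \cdot 365) - 90$ days (exclusive). The windows are
lower-inclusive by construction: the 275-day record floor coincides
exactly with the lower bound of the first window. For model fitting the
classes collapse to four levels (1, 2, 3, other), which won a formal
AIC/likelihood-ratio comparison against both no age effect and the
finer age-of-dam classification and keeps contemporary groups large.

Missing calving seasons are imputed from the most recent natural calving
before the score date, falling back to the animal's own birth date; the
month-to-season map (January-June = spring) is configurable because the
cut-off is a management convention, not a biological constant.

Contemporary groups are keyed by farm, year scored, calving season,
fescue grazing status, age group and score group. Score groups are built
greedily within farm-year: the earliest unassigned scoring date opens a
7-calendar-day window and every date inside joins the group. Greedy
assignment is deterministic and near-optimal when scoring days cluster,
which is the design goal (maximizing animals per group). Groups with
fewer than five animals or without score variation are dropped, and
every dropped record is logged with its reason; the preparation pipeline
is idempotent, and each input record ends up in exactly one of the kept
set or the removal log.

## Relationship matrices

The pedigree relationship matrix $A$ is built by the tabular method and
its sparse inverse by Henderson's rules with inbreeding-adjusted
Mendelian-sampling variances; inbreeding coefficients come from the
tabular diagonal, which is entirely adequate at the pedigree sizes this
package targets (thousands of animals; a faster algorithm would only
matter far beyond that). The genomic matrix follows VanRaden,
$G = ZZ' / (2\sum_j p_j(1-p_j))$, centering allele counts with observed
frequencies of the genotyped set; missing genotypes are mean-imputed per
SNP before centering so columns of $Z$ stay mean-zero. $G$ is blended as
$G_w = 0.95\,G + 0.05\,A_{22}$ before inversion, and the single-step
precision matrix is assembled as

$$H^{-1} = A^{-1} +
  \begin{bmatrix} 0 & 0 \\ 0 & G_w^{-1} - A_{22}^{-1} \end{bmatrix},$$

without additional scaling of the correction block and without shifting
$G$ to the $A_{22}$ base. Genotype quality control removes SNPs and
animals with call rates below 0.85 and monomorphic SNPs, and blanks a
parent link when the opposing-homozygote rate between an animal and that
parent exceeds 2% (opposing homozygotes are the phase-free Mendelian
check).

## The mixed models

All five models are instances of one machinery. The core univariate
repeated-records animal model is

$$y = Xb + Z_1 u + Z_2 p + e, \qquad
  u \sim N(0, K\sigma^2_a),\;
  p \sim N(0, I\sigma^2_{pe}),\;
  e \sim N(0, I\sigma^2_e),$$

with $K$ either $A$ or the blended single-step $H$ (supplied through its
sparse inverse) and $b$ the contemporary-group effects (plus age class
or fescue status where the model asks for them). Heritability is
$\sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e)$ and
repeatability $(\sigma^2_a + \sigma^2_{pe}) / (\sigma^2_a +
\sigma^2_{pe} + \sigma^2_e)$, with delta-method standard errors from the
inverse average-information matrix.

The bivariate fescue model treats scores taken while grazing and while
not grazing toxic fescue as two traits: the genetic block
$\mathrm{Var}(u) = G_0 \otimes K$ is free, permanent environment is
status-specific with its cross-covariance fixed at zero, and the
residual cross-covariance is also fixed at zero. The latter is a
deliberate deviation from a printed free residual covariance: the two
statuses are never observed on the same record, so that covariance has
no data support and would be unidentifiable.

The maternal weaning-weight model ties a dam's hair shedding score to
the weaning weight of the calf she weaned that year. It is implemented
as a single genetic term with three components sharing the pedigree
covariance: the dam's hair-shedding effect (no calf-side genetic effect
on hair shedding), the maternal weaning-weight effect (entering through
the calf's dam), and the calf's direct weaning-weight effect. The full
3x3 covariance is free, the cow's permanent-environment block is 2x2
with free covariance, and residuals are trait-specific with zero
cross-covariance. Dams scored in a year without a weighed calf receive a
dummy calf with missing weight and unknown sire: the record contributes
no residual row but keeps the dam-year link estimable. Identification of
the direct-maternal covariance leans on animals appearing in both roles,
which is why the synthetic design also gives every scored cow her own
weaning-weight record as a calf of her pedigree dam.

## REML estimation

Variance components are estimated by average-information REML driven
entirely through the mixed-model equations: one sparse Cholesky
factorization per iteration yields solutions and the restricted
likelihood; the AI matrix is assembled from working vectors, each
requiring only a solve against the already-factorized system. Newton
steps are safeguarded by step damping, Levenberg-Marquardt ridging of
the AI matrix, eigenvalue bending of out-of-bounds proposals, and a
monotonicity check against the (cheap) restricted likelihood.

First derivatives need traces of inverse-coefficient blocks. For systems
up to a few thousand equations these traces are computed exactly from
multi-right-hand-side solves, and an EM update -- always inside the
parameter space -- serves as fallback. For larger systems the score is
instead obtained by central differences of the restricted likelihood
(each evaluation reuses the symbolic factorization), while the AI
curvature stays exact; the two paths agree to ~1e-5 on shared problems,
which the test suite asserts. Convergence is declared when the aggregate
relative parameter change drops below the tolerance (default `1e-8`), or
when the likelihood stalls across several iterations, which is how
boundary optima (a correlation pinned at $\pm 1$, a variance collapsing
to zero) terminate; estimates at such boundaries are reported as-is.
Exceeding the iteration cap raises an error that carries the likelihood
trajectory.

Prediction error variances are the diagonal of the inverse coefficient
matrix over the genetic block (the equations carry $R^{-1}$, so no
residual-variance rescaling is needed), and reliability is
$1 - \mathrm{PEV}/\sigma^2_a$. Model comparison uses
$\mathrm{AIC} = -2\log L + 2k$; when candidate models differ in fixed
effects the comparison is made on profile maximum likelihood rather than
on REML, whose likelihoods are not comparable across different
fixed-effect structures.

## LR-method validation

Bias, dispersion and accuracy of breeding values are assessed by
comparing whole-data EBVs against partial EBVs computed with all
phenotypes of a random 25% of animals masked, over ten independent
partitions. Per iteration and per set (validation = masked animals,
reference = the rest) the statistics are $d$, the mean difference
between whole and partial EBVs (reported as an absolute value, with the
signed value retained for calibration checks, since a mean of absolute
values cannot be centred on zero); $b$, the regression slope of whole on
partial (expectation 1 without dispersion); and $\rho$, their
correlation (validation-set $\rho$ is the prediction accuracy). Under a
no-selection simulation these calibrate to $d \approx 0$ and
$b \approx 1$; the generator's truncation-selection toggle deliberately
violates the no-selection assumption and serves as a negative control.
Partial fits reuse the whole-data variance components by default, which
is standard practice and keeps validation affordable.

## Association analysis

EBVs are deregressed by simple reliability deregression,
$\mathrm{debv} = \mathrm{ebv} / r^2$ with
$r^2 = 1 - \mathrm{PEV}/\sigma^2_a$, one record per animal, weighted by
$r^2$ (parent-average-stripping deregression is noted as an alternative
but is not the default). The scan is a per-SNP generalized least-squares
fit of $y = 1\mu + x_j\beta_j + g + \varepsilon$ with
$\mathrm{Var}(g) = G\sigma^2_a$ and
$\mathrm{Var}(\varepsilon_i) = \sigma^2_e / w_i$. The heritability on
the proof scale is constrained to 0.40: the total is anchored on the
sample variance of the proofs and allocated so that the mean modelled
variance matches under the weights (with unit weights this reduces to a
plain 0.40/0.60 split; without the weight correction the Wald tests are
visibly conservative, which the calibration oracle in the test suite
would catch). Wald p-values receive Benjamini-Hochberg q-values via
`stats::p.adjust`, and genes are reported within 50 kb of significant
SNPs, strand-agnostic and inclusive at exactly 50 kb, with distance zero
inside a gene.

The scan is exactly calibrated when the proof covariance really is
$G\sigma^2_a + D\sigma^2_e$; proofs produced by the deregression of
shrunken EBVs only approximate that structure, so on pipeline output the
scan errs conservative. This mirrors the behaviour of two-step
deregressed-proof associations generally and is why the calibration
oracle simulates the polygenic null directly.

## The synthetic-data generator

The generator emulates the structure the models assume: a multi-
generation random-mating pedigree; unlinked biallelic SNPs gene-dropped
from founder frequencies; cow-year score records composed of a
contemporary-group effect, a U-shaped age-class effect (young and old
cows shed later), a fescue grazing-status effect, additive and
permanent-environment animal effects and a fresh residual. Breeding
values descend the pedigree with Mendelian-sampling variance adjusted
for parental inbreeding. Default parameters are the published point
estimates for this trait: additive, permanent-environment and residual
variances of 0.40, 0.04 and 0.56 score units squared -- the printed
heritability (0.40) and repeatability (0.44) fix only these ratios, so
the total was set to one -- a fescue effect of -0.59 score units, a
genetic correlation of 0.93 between the two status-traits with
per-status variances derived from the published phenotypic variances
(0.90, 0.95) and repeatabilities (0.45, 0.34), and maternal-model
correlations of -0.19 (hair shedding vs maternal weaning weight) and
-0.43 (direct vs maternal). Weaning-weight variances themselves are not
published for this data; the defaults (direct 350 kg^2, maternal
160 kg^2, maternal permanent environment 90 kg^2, residual 400 kg^2)
are typical of Angus field evaluations.

Scores stay continuous by default because the ordinal 1-5 score was
analysed as a linear trait; thresholding onto the integer scale is a
switch. Grazing status varies at the pasture-group level within
farm-years (so the fescue fixed effect is separable from contemporary
groups), and management effects are keyed without grazing status so the
configured fescue effect is the only systematic status difference.

What the generator does **not** emulate: linkage disequilibrium (SNPs
are unlinked, so the marker panel behaves like an idealized dense
panel), genotyping and imputation error, selection (except the explicit
negative-control toggle), scoring-technician differences, and any
environmental trend. Passing recovery tests therefore demonstrates
correctness of the estimation machinery under the stated model, not
robustness to these real-data complications.

## Problem sizes and numerical choices

Recovery studies in the tests and the acceptance script use ten seeded
replicates each, at sizes chosen to keep a full run comfortable on a
single CPU: roughly 1,300 scored cows (pedigrees of ~3,400) for the
univariate study, ~750 cows with two to five records each for the
bivariate fescue study, and ~300 dams (extended pedigrees of ~1,300
with calves) for the maternal study. Acceptance bands are three
Monte-Carlo standard errors of the replicate mean, so smaller studies
widen their own bands rather than weakening the check. REML tolerances
of `1e-6` (univariate/bivariate) and `1e-5` (maternal) are far below
the Monte-Carlo noise floor of these studies. Fixed-effect design
matrices use treatment contrasts with linearly dependent columns
dropped; ties in the greedy score-group scan cannot occur because
windows open on the earliest unassigned date.

## Known limitations

Residual covariances across traits are fixed at zero wherever the two
traits share no record, which is an identifiability statement rather
than a biological one. The maternal model's direct-maternal correlation
is weakly identified when few animals appear in both the calf and dam
roles, and small simulated datasets can push correlation estimates to
the parameter boundary; the engine terminates cleanly there and reports
the boundary estimate. The deregression default is the simple
reliability form; proofs for animals whose information is mostly
parent-average remain correlated with relatives, which the GRM in the
scan only partly absorbs.
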