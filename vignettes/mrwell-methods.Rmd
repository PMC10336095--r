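---
title: "Causal models and design choices in mrwell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal models and design choices in mrwell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mrwell estimates the causal effect of body mass index (BMI) on ordinal
subjective well-being outcomes by one-sample Mendelian randomisation (MR),
in cohorts where the analysis must be stratified (by sex and recruitment
region) and where the instrument has to be built from the same data it is
used in. This vignette explains the models, the tunable parameters, the
synthetic data the estimators are validated on, and the numerical
conventions — in particular the places where a design decision was genuinely
open and we had to pick one.

## The causal model and its assumptions

Let $d_i$ be the dosage of the effect allele at variant $i$, $x$ the
exposure (BMI, kg/m²), and $y$ a well-being outcome scored on an ordinal
ladder (0–3 for satisfaction scales, 0–5 for the happiness ladder) but
modelled as a numeric response. The genetic risk score is

$$GRS_w = \sum_{i=1}^n \beta_i d_i, \qquad
  GRS_s = \frac{n \, GRS_w}{\sum_i \beta_i},$$

and two-stage least squares (TSLS) estimates the causal slope of $y$ on $x$
(expressed per cohort SD of $x$) by regressing $x$ on the score (stage 1)
and $y$ on the stage-1 prediction (stage 2), with the same covariates in
both stages. Validity rests on the usual four MR assumptions: the score is
(1) associated with BMI — checked via incremental $R^2$ and the partial $F$
statistic (`instrument_strength`); (2) independent of confounders of the
BMI–well-being relationship; (3) affects well-being only through BMI; and
(4) the exposure–outcome relationship is correctly modelled — the linearity
half of that assumption is exactly what the non-linear machinery below is
for.

Ordinal outcomes are treated as numeric responses in linear models, so
effects read as "score points per SD of BMI". That convention is common for
4–6 level satisfaction ladders and keeps observational, TSLS and
control-function estimates on a single interpretable scale; an ordinal
logit would not drop into TSLS or the control function nearly as cleanly.

## Instrument construction

**Allele orientation.** Per sex, rank-inverse-normal-transformed BMI is
regressed *jointly* on all variants, and each variant is coded so its
effect allele is trait-increasing; when the sexes disagree in sign, the sex
with the larger absolute effect decides. We interpret "largest effect" as
largest in absolute value — sign conflict is precisely the situation the
rule exists to resolve. The RINT uses Blom's offset,
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ with average ranks for ties,
the prevailing convention when none is stated.

**Weights.** Weight estimation regresses *raw* BMI on all oriented variants
jointly plus principal components (12 by default), in the unrelated subset.
Orientation uses RINT BMI while weighting uses raw BMI deliberately: the
first is a rank decision that benefits from robustness, the second must be
on the exposure's measurement scale. Joint rather than per-variant
regression is the default (a per-variant mode exists) — with uncorrelated
variants the two coincide asymptotically, and joint estimation is what a
"univariate multiple regression" of one response on many variants means.

**Block jack-knife.** Using internally estimated weights naively would let
each individual's phenotype influence their own score — a classic route to
overfitting bias in one-sample MR. `jackknife_weights` partitions the
unrelated subset into $B$ near-equal blocks (default 100) by a seeded
random permutation (the partition rule is unstated in the designs we
emulate; a seeded shuffle is the neutral choice), estimates weights with
each block held out, and assigns those weights to the held-out block.
Related individuals get the full-unrelated-sample weights (the
split-sample rule). The leave-block-out property is tested structurally:
perturbing one block's phenotypes must leave that block's weights
bit-identical.

**Filtering.** Variants with MAF strictly below 0.01 or flagged
multiallelic are excluded before scoring; a variant at exactly the
threshold is retained.

## Stratified estimation, pooling, comparison

For a multi-region cohort the design is: fit every (sex × region) stratum
separately (sex is dropped from the covariate set inside sex strata;
strata below 50 individuals are skipped and logged — the floor is our
choice, small enough to keep real strata, large enough that a linear model
with PCs is estimable), then pool with fixed-effects inverse-variance
meta-analysis:

$$\hat\beta = \frac{\sum w_i \beta_i}{\sum w_i},\quad w_i = SE_i^{-2},
  \qquad Q = \sum_i w_i(\beta_i - \hat\beta)^2,
  \qquad I^2 = \max\!\Big(0, \frac{Q - df}{Q}\Big)\times 100.$$

Urban/rural summaries pool whole regions, which is why the generator makes
urbanicity a region-level label. Two cohorts are compared with the Fisher z
test $z = (\beta_1 - \beta_2)/\sqrt{SE_1^2 + SE_2^2}$; the two-sided P is
computed through the normal survival function and also returned as
$\log_{10} P$, which stays finite and accurate beyond double underflow
(z ≈ 38 is where a plain P hits 1e-308). Published estimates are consumed
through `ci_to_se` (SE = CI width / 3.92), so printed tables alone suffice
for the comparison. TSLS standard errors use the instrumental-variable
variance with residuals from the observed exposure — naive stage-2 OLS SEs
are wrong and are never reported.

No multiple-testing correction is applied across strata and outcomes; with
this many correlated analyses a single threshold would be arbitrary, so P
values are reported raw (a Bonferroni column can be added at display time).

## Non-linearity: fractional polynomials and the control function

The observational screen compares linear, quadratic and fractional
polynomial (FP) shapes. FP1 fits the 8 powers
$S = (-2, -1, -0.5, 0, 0.5, 1, 2, 3)$ ($x^0$ meaning $\log x$); FP2 fits
all 36 combinations — 28 distinct pairs plus 8 repeated powers using the
standard $(x^p, x^p\log x)$ basis. The exposure is divided by its sample
mean first (guaranteeing positivity for BMI and keeping powers of order
one); the scaling constant is stored on every fitted model. Powers (1, 2)
reproduce quadratic regression exactly, and $p = 1$ reproduces the linear
fit — both identities are tested to 1e-8.

AIC uses the Gaussian likelihood with the error variance profiled at its
MLE, and counts intercept + slope terms + covariates (not the variance).
Any internally consistent convention ranks models on the same data
identically; this one is simple and matches the equivalence identities
above. Exact AIC ties break toward fewer parameters, then lower powers.
Quadratic fits centre $x$ before squaring to tame collinearity (the centre
is stored with the fit).

The causal (control-function) version: stage 1 regresses the standardised
exposure on the GRS plus covariates and keeps the residual $r$; stage 2
regresses the outcome on $x_{sd}$, $x_{sd}^2$, the covariates, and $r$.
The coefficient on $r$ absorbs the unmeasured confounding; the exposure
coefficients are the causal estimates. Two deliberate choices here:

- The stage-1 regression is exposure-on-instrument. A literal reading of
  some descriptions of the method ("regress the instrument on the
  exposure") yields residuals of the *instrument*, which cannot control
  confounding of the exposure; only the exposure-on-instrument direction
  produces the residual the method needs, so that is what is implemented.
- Standard errors default to a nonparametric bootstrap over individuals
  (500 replicates, seeded, resampling both stages), because the stage-1
  residual is a generated regressor and naive stage-2 SEs are not valid in
  general. A fast `se_method = "naive"` mode exists; in the regimes this
  package simulates (strong instrument, quadratic term nearly orthogonal
  to the stage-1 score) it is empirically well calibrated — the type-I
  error of the naive quadratic test sits at its nominal 5% in the
  calibration suites — which is why the large replicate suites use it.
  With degree 1 the control-function estimate equals TSLS exactly (tested
  to 1e-8), a useful identity for catching regressions in either path.

## The synthetic cohort generator

`simulate_cohort` draws genotypes at Hardy–Weinberg equilibrium with
frequencies uniform in `maf_range` (no linkage disequilibrium, no
population structure — relatedness is a flag, not a pedigree), then

$$x = \mu + \textstyle\sum_i \beta_{g,i} d_i + c_x U + \varepsilon_x,
\qquad
y^* = \beta_1 m_r x_{sd} + \beta_2 x_{sd}^2 + c_y U + \varepsilon_y,$$

with $U \sim N(0,1)$ a single shared confounder — the minimal structure
that biases OLS while leaving the MR assumptions intact — $x_{sd}$ the
exposure in cohort-SD units (mirroring per-SD reporting), and $m_r$ an
optional region-specific multiplier on the linear effect used to inject
heterogeneity and exercise $Q$/$I^2$. The ordinal outcome cuts $y^*$ at
empirical quantiles (order statistics, quantile type 1) matching the target
category prevalences, so configured marginals are honoured at any noise
level and the mapping is invariant to monotone relabelling; the cutpoints
are recorded in the ground truth. Both the latent and the ordinal outcome
are returned, since betas on 0–3 ladders imply the numeric-response
convention but either can be analysed.

Defaults describe an East-Asian-biobank-like cohort, chosen once: 10
recruitment regions, 57% female, 44% of regions urban, 28% related, BMI
mean 23.7 and SD ≈ 3.5 kg/m², health-satisfaction marginals
(0.116, 0.443, 0.270, 0.171), and a 20-variant score explaining ≈ 3% of
BMI variance (per-allele effect 0.24 kg/m², confounder loading 2.4,
residual SD 2.4) — in the 1.5–3.1% range a real BMI score achieves there.
Confounding on the outcome side defaults to $c_y = 0.5$, producing an OLS
bias of ≈ +0.35 SD-units against a null causal effect, large enough that
any failure of TSLS to remove it is unmistakable.

What passing tests on these cohorts does **not** show: robustness to
pleiotropy (no pleiotropic paths are simulated, and no pleiotropy-robust
estimators are included), to LD between instrument variants, to population
stratification (simulated PCs are independent noise, so PC adjustment is
exercised only as a no-op), or to genuinely ordinal error structures.

## Problem sizes in the validation suites

Parameter-recovery suites use n = 20,000 individuals: 200 replicates per
true effect in {−0.2, 0, 0.3} for TSLS bias (|bias| < 0.01) and 95% CI
coverage (asserted in [92%, 98%] pooled over the 600 replicates, where the
Monte-Carlo noise on coverage is ±0.9 percentage points), and 40 replicates
for control-function recovery of (0.3, −0.05). The type-I calibration of
the quadratic-term test runs 1,000 replicates at n = 5,000 — the size at
which the naive-SE mode was verified calibrated — and asserts the rejection
rate's binomial CI covers 5%. The jack-knife agreement check (correlation
> 0.99 between jack-knifed and full-sample-weight scores) runs at
n = 10,000 with 100 blocks. The acceptance script scales the replicate
counts to 100/30/400 for a fast single-pass reproduction.

## Known limitations

- Ordinal outcomes as numeric responses: defensible and conventional for
  these ladders, but not a proportional-odds analysis.
- Fixed-effects pooling only; with high $I^2$ the pooled estimate is a
  precision-weighted average of genuinely different effects and should be
  read as such (the per-stratum table is always retained).
- The control function assumes the quadratic specification of the outcome
  model; it tests linearity, not arbitrary shape misspecification.
- External-weight (GWAS-derived) scores are supported, but no LD clumping
  or instrument discovery is performed here.
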