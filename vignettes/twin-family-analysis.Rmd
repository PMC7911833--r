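---
title: "Twin-family analysis of binary phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin-family analysis of binary phenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinfam)
```

This vignette is the package's account of the statistics it implements:
the pair-likelihood similarity models and their MZ-vs-DZ tests, the
familial-aggregation regressions, the liability-threshold simulator, and
the numerical and design choices behind each.

## The data model

A cohort is a long-format table, one row per person, with
`family_id, role, zygosity, sex, age` and one 0/1/NA column per condition.
Roles are `twin1`, `twin2`, `oldest_sibling`, `mother`, `father`. The long
format was chosen over one-row-per-family because roles vary by family and
missingness is per member; statuses are never imputed — each analysis
deletes incomplete units by its own rule (pairwise for twin analyses,
listwise over all five members for the family-association models), which
is why the effective n legitimately differs across analyses. Exclusion
counts are carried on the returned objects and logged by the pipeline.

Zygosity is taken as an input column: its determination (DNA testing or
similarity questionnaires) is upstream of this package, as is diagnostic
classification — conditions enter only as binary lifetime indicators. A
condition introduced later in a survey (e.g. a second questionnaire wave)
is represented simply as missingness in families never asked, not as an
explicit wave structure.

## Twin-pair similarity models

For one zygosity group and condition, complete twin pairs fall in three
cells: both affected ($N_c$), exactly one ($N_d$), neither ($N_{00}$),
with $N = N_c + N_d + N_{00}$. All three similarity measures are
parameterised through a pair model with marginal affection probability
$q$ and one association parameter, giving ordered-pair cell probabilities
$(p_{11}, p_{10}, p_{01}, p_{00})$:

* **Casewise concordance** $C = P(\text{twin affected} \mid \text{co-twin
  affected})$: $p_{11} = qC$, $p_{10} = p_{01} = q(1 - C)$. The MLE is
  closed-form, $\hat C = 2N_c / (2N_c + N_d)$. Casewise (not pairwise)
  concordance is used because it is interpretable as a recurrence risk and
  is the standard scale for comparing zygosities.
* **Correlation** $\rho$: $p_{11} = q^2 + \rho q(1-q)$. The MLE equals the
  phi coefficient of the *double-entered* table (each pair entered in both
  orders: $a = 2N_c$, $b = c = N_d$, $d = 2N_{00}$), an identity the test
  suite checks to machine precision across random tables.
* **Odds ratio** $\psi = \frac{p_{11}p_{00}}{p_{10}p_{01}}$: the odds of
  affection given an affected co-twin over the odds given an unaffected
  co-twin. The saturated MLE is $\hat\psi = N_c N_{00} / (N_d/2)^2$. For
  given margins the joint cell solves the Plackett quadratic
  $p_{11} = \frac{s - \sqrt{s^2 - 4\psi(\psi-1)p_1 p_2}}{2(\psi-1)}$,
  $s = 1 + (p_1 + p_2)(\psi - 1)$, with $p_{11} = p_1 p_2$ at $\psi = 1$.
  The solver switches to the independence branch for $|\psi - 1| <
  10^{-9}$ and clamps to the Fréchet bounds; inversion through the
  cross-product recovers $\psi$ to better than $10^{-10}$ relative error
  over $p \in [0.05, 0.95]$, $\psi \in [0.1, 100]$.

Standard errors for the closed-form estimators come from the delta method
on the trinomial proportions $(\hat p_{11}, \hat p_d)$ with their exact
multinomial covariance. Confidence intervals are untransformed Wald
(estimate ± 1.96 SE) truncated to the parameter range for $C$ and $\rho$,
and log-scale Wald for $\psi$ — the untransformed choice for $C$ is
deliberate: it is the convention under which published concordance
intervals for this class of tables reproduce digit-for-digit. Degenerate
cells ($N_d = 0$, all-concordant, etc.) are flagged as boundary estimates;
no continuity corrections are applied.

### Covariate adjustment

`fit_pair_model(..., adjusted = TRUE)` replaces the common marginal $q$ by
per-twin marginals $\mathrm{logit}(p_i) = \beta_0 + \beta_{age}\,age_i +
\beta_{sex}\,female_i$, keeping one association parameter across pairs
(association-by-covariate interactions are out of scope). With unequal
margins the three parameterisations generalise as $p_{11} = C(p_1+p_2)/2$
(so that $C = 2p_{11}/(p_1+p_2)$ remains the casewise probability),
$p_{11} = p_1 p_2 + \rho\sqrt{p_1(1-p_1)p_2(1-p_2)}$, and the Plackett
cell. Sex is coded female = 1; age is in years, uncentred.

Optimisation is quasi-Newton (BFGS) on transformed parameters — logit for
$q$ and $C$, Fisher-z for $\rho$, log for $\psi$ — with deterministic
closed-form plug-in starts, relative tolerance $10^{-10}$, and infeasible
cell combinations penalised. Standard errors come from the numerically
differentiated observed information on the natural scale. The unadjusted
fit reproduces the closed forms to $10^{-5}$ and its log-likelihood equals
the trinomial log-likelihood at the MLE to $10^{-8}$ (tested).

### The zygosity likelihood-ratio test

The unconstrained model fits $(q_z, \theta_z)$ separately per zygosity;
the constrained model shares the association $\theta$ while keeping
separate marginals $q_{MZ}, q_{DZ}$. Twice the log-likelihood difference
is referred to $\chi^2_1$. Sharing only the association (not the
marginals) was an open design choice: prevalence can differ by zygosity
for reasons irrelevant to the similarity hypothesis, so constraining it
would contaminate the test. On the shipped pain tables this choice
reproduces the published casewise p-values closely (e.g. growing pains
0.0092 vs 0.009; headache 0.066 vs 0.064); the constrained optimum is
verified in the tests against an independent profile-likelihood grid
search. The statistic is floored at zero (tolerance $-10^{-6}$ for
optimiser noise) and its null calibration is checked by simulation: over
1000 null data sets the rejection rate at $\alpha = 0.05$ must fall in
$0.05 \pm 0.02$.

A caveat documented rather than chased: for the shipped example tables the
saturated-model odds ratios need not coincide with odds ratios published
from individual-level estimation schemes (e.g. margins shared across
zygosities or covariate models); the package defines and tests the
saturated estimator and uses the correlation and concordance scales for
cross-checks. Similarly, one published concordance cell (recurrent
abdominal pain, MZ) prints 0.48 where the counts give
$66/139 = 0.4748 \to 0.47$, and one prevalence cell (growing pains, DZ)
prints 17.4% where $178/1026 = 17.35\% \to 17.3$ — both consistent with
double rounding upstream; the package asserts the arithmetic.

## Familial-aggregation regressions

`fit_logistic()` is an in-package iteratively reweighted least squares
fitter (score-equation residual below $10^{-8}$ at convergence, rank
deficiency reported with the collinear columns named, apparent complete
separation — $|\hat\eta| > 25$ or $|\hat\beta| > 15$ — raised as an error
rather than silently returning divergent estimates; no Firth or exact
corrections). Wald tests divide each coefficient by its observed-
information SE.

For the MZ-vs-DZ prevalence contrast both twins of each pair enter, so a
family-level normal random intercept is integrated out by Gauss–Hermite
quadrature, 21 nodes by default, nodes and weights built by the
Golub–Welsch eigen-decomposition. Non-adaptive quadrature (nodes scaled by
the random-effect SD) is used: with cluster sizes of at most two and the
variance scales arising here it is accurate far below test tolerances, as
validated against an independent adaptive-quadrature implementation
(`lme4::glmer`, agreement to $10^{-4}$ on coefficients) and against the
$\sigma \to 0$ degeneracy, where the quadrature marginal likelihood must
match the plain logistic log-likelihood (to $10^{-6}$ in the tests). Note
that on data without real clustering the *fitted* mixed model need not
degenerate — a logistic-normal marginal can fit slightly better than the
logistic — so degeneracy is a statement about the likelihood at
$\sigma \to 0$, not about the MLE.

The family-association models (index twin's status on co-twin, sibling,
mother, father statuses, univariately and multivariately) use one twin per
family, selected uniformly at random under a mandatory seed from families
with complete data for all five members. With one twin per family there
are no repeated family members, the random intercept is unidentified, and
the models are fitted as plain logistic — the clustering machinery is
exercised by the two-twins-per-family prevalence model instead.

"Adjusted for age and sex whenever significant" is operationalised as:
include a covariate when its own Wald p-value is below 0.05 in a
covariates-only model for that outcome. This is one of several defensible
readings, so the policy is an explicit argument
(`"when_significant"`, `"always"`, `"never"`). No multiple-testing
correction is applied anywhere; raw p-values are reported.

## The liability-threshold ACE simulator

Each family member receives a standard-normal liability decomposed into
additive-genetic (variance fraction $a^2$), shared-environment ($c^2$) and
unique-environment ($e^2 = 1 - a^2 - c^2$) components. Pairwise liability
correlations follow the kinship structure: additive-genetic correlation 1
for MZ co-twins, 0.5 for DZ co-twins, twin–sibling and parent–offspring, 0
for spouses; shared environment fully common to the co-resident children,
a configurable fraction (default 0) between parents and children, none
between spouses. An individual is affected iff liability (plus optional
probit-style covariate shifts, applied to age centred at 10.5 years and to
sex) exceeds $\tau = \Phi^{-1}(1 - K)$ for prevalence $K$. The normal
liability scale (rather than logistic) buys closed-form pairwise
correlations $r = a^2 \kappa + c^2$ and an analytic validation oracle:

$$C_{\text{expected}} = \frac{P(L_1 > \tau, L_2 > \tau;\, r)}{K},$$

with the orthant probability computed by adaptive 1-D quadrature of
$\int_\tau^\infty \phi(x)\,\Phi\!\left(\frac{rx - \tau}{\sqrt{1-r^2}}\right)dx$
(cross-checked in the tests against $10^6$-draw Monte Carlo). The same
oracle, inverted by root-finding, provides tetrachoric-style liability
correlations from observed pair counts.

Defaults mirror the cohorts this design targets: twins aged 3–18 (uniform
integers, shared within a pair), the oldest sibling 2–8 years older,
parental ages normal (mothers 42.6 ± 6.3, fathers 44.8 ± 6.5 years —
cosmetic realism only), 51.2% female, MZ co-twins sharing sex, roughly
equal MZ/DZ numbers, per-condition prevalences in the 6–20% range, and
optional per-member missingness. Because no calibrated age or sex effect
sizes exist for these conditions, `beta_age`/`beta_sex` default to zero
and any non-zero values should be treated as illustrative. Multiple
conditions can share genetic influences through a cross-condition genetic
correlation matrix (default identity); mate assortment and dominance are
deliberately absent (ACE/AE/CE only). All draws come from one RNG stream
seeded once per call — cohorts are byte-identical for a given seed, which
is the package's reproducibility contract.

### What the simulator does and does not establish

Passing validation on synthetic cohorts shows the estimators recover the
generating association structure (concordances match orthant oracles;
Falconer-style $2(r_{MZ} - r_{DZ})$ recovers $a^2$ within 0.05 on large
cohorts; the LR test holds its level when $a^2 = 0$ and has power 0.97 at
$a^2 = 0.6$, $K = 0.15$ with 1200 pairs per zygosity — calibrated once and
frozen as a regression test). It does not establish robustness to features
real questionnaire data possess and the generator omits: selective
response, recall and reporting correlation within families, zygosity
misclassification, age-structured incidence, or violation of the
equal-environments assumption itself.

Validation problem sizes were chosen so Monte-Carlo error is small
against each tolerance: e.g. the simulator-vs-oracle concordance check
averages eight cohorts of ~5000 pairs per zygosity, putting the Monte-
Carlo SE (~0.006) well inside the ±0.02 band, where a single cohort's SD
(~0.016) would make the same band a coin flip on a correct simulator.

## Reporting conventions

Rendered tables round half-away-from-zero: percentages to 3 significant
figures, concordances and correlations to 2 decimals, odds ratios to 3
significant figures, p-values to 3 decimals with `<0.001` below that.
Pipelines abort atomically on any stage failure (partial outputs removed,
stage named) and stamp a manifest with the seed, package version, input
hash and per-stage exclusion counts, so that two runs with the same
configuration and seed produce byte-identical bundles.

## Known limitations

* Heritability point estimates (ACE path coefficients) are intentionally
  not produced; the package stops at similarity contrasts, which is where
  binary lifetime data of this kind carry defensible information.
* The adjusted similarity models assume a covariate-free association
  parameter.
* The Wald/delta intervals are first-order; for very sparse cells
  (boundary flags) profile or exact intervals would be preferable and are
  not implemented.
* The IRLS fitter handles separation by refusing, not by penalisation.
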