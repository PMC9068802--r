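---
title: "Moderated Cholesky ACE models for educational tracking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated Cholesky ACE models for educational tracking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question

Ability tracking sorts students into school types of different academic
level. When the definitive track decision is taken immediately at the end
of primary school, family background may weigh more heavily than it does
when the decision is delayed by one to three years in a heterogeneous
(multi-level) class. The classical twin design offers an omnibus way to
quantify this: comparing monozygotic (MZ, genetic relatedness 1) and
dizygotic (DZ, relatedness 0.5) twin pairs decomposes the variance of
educational attainment into an additive-genetic part (A), a shared
(family) environmental part (C), and a non-shared part including
measurement error (E). If delayed tracking improves equality of
opportunity, attainment should show a larger standardized A and a smaller
C among students whose tracking was delayed.

`trackace` implements this analysis end to end: the recoding rules for
Dutch secondary-track reports, a bivariate Cholesky ACE model linking
end-of-primary-school test performance (CITO-like scale, nominal range
501-550) to secondary attainment (track-level score 0-4), linear
moderation of the attainment paths by the student's own performance,
multigroup estimation by full-information maximum likelihood (FIML), and
the descriptive surfaces around the models. Because register data of this
kind are typically available only on request, the package ships a
synthetic twin-pair generator that draws from exactly the model the
analysis assumes, with known parameters for recovery and calibration
studies.

## The model

For one twin, performance \(x\) and attainment \(y\) follow a Cholesky
factorization with unit-variance latent factors:

\[
x = \mu_x + \beta' w + a_{xx} A_x + c_{xx} C_x + e_{xx} E_x,
\]
\[
y = \mu_y + \beta' w
  + \tilde a_{yx} A_x + \tilde c_{yx} C_x + \tilde e_{yx} E_x
  + \tilde a_{yy} A_y + \tilde c_{yy} C_y + \tilde e_{yy} E_y,
\]

where \(w\) are covariates (male dummy, mean-centered birth year) and each
attainment path may depend linearly on the twin's own centered performance
\(X\), e.g. \(\tilde a_{yx} = a_{yx} + a'_{yx} X\) (the definition-variable
convention; the x-paths are never moderated). The attainment variance
splits into a part *common* with performance
(\(\tilde a_{yx}^2 + \tilde c_{yx}^2 + \tilde e_{yx}^2\)) and a part
*unique* to attainment (\(\tilde a_{yy}^2 + \tilde c_{yy}^2 +
\tilde e_{yy}^2\)). In the tracking literature, the common shared-
environment component corresponds to primary effects of family background
(via performance) and the unique shared-environment component to secondary
effects (net of performance).

Across a pair, A factors correlate \(r\) (1 MZ, 0.5 DZ), C factors are
fully shared, E factors are independent. `pair_covariance()` assembles the
implied 4x4 covariance over \((x_1, y_1, x_2, y_2)\); in the univariate
specialization this reduces to the familiar
\(\mathrm{Cov}_{MZ} = a^2 + c^2\), \(\mathrm{Cov}_{DZ} = 0.5 a^2 + c^2\).
Each twin carries its own tracking status, so tracking-discordant pairs
multiply status-specific effective paths in the cross-twin entries.

### The model sequence

Every twin has a tracking status: *immediate*, *delayed*, or
*tracking-missing* (kept as its own group so such twins and their co-twins
still inform the rest of the model). Three nested specifications mirror
the usual analysis sequence:

* **Model 1a** — one set of 9 paths and 2 intercepts shared by all
  statuses (15 free parameters with the 4 shared covariate slopes);
* **Model 1b** — a separate 11-parameter set per status (37); the
  1a \(\to\) 1b comparison tests whether tracking timing moderates the
  decomposition at all (22 df);
* **Model 2** — additionally frees the 6 moderation slopes in each status
  set (55); the 1b \(\to\) 2 comparison (18 df) tests whether the timing
  effect itself depends on the student's performance level.

Covariate slopes are shared across groups throughout. An optional
`moderator_mean` term adds a linear effect of centered performance on the
attainment mean (one slope per status set); it defaults to off and the
choice is recorded in every fit, since published variants of this model
family differ on whether the term is included.

### Estimation

`ace_fit()` minimizes the FIML deviance
\(\sum_i k_i\log 2\pi + \log|\Sigma_i| + z_i'\Sigma_i^{-1} z_i\)
over pairs, where \(\Sigma_i\) is the observed-variable submatrix of the
implied pair covariance, evaluated with each twin's own status and
moderator value. A twin with a missing moderator contributes nothing (its
co-twin still does); a twin missing only attainment contributes its
performance. The per-pair kernel is implemented in C++ since definition
variables force a pair-by-pair covariance construction.

Numerical choices, fixed once:

* quasi-Newton (`nlminb`) on the raw paths with no positivity bounds
  (published tables legitimately contain negative paths), parameter
  scaling \(1/\max(|\theta_0|, 0.05)\);
* a Falconer-style method-of-moments start (twin correlations give
  a starting A/C/E split; the x-y regression slope splits attainment
  paths into common and unique parts) plus jittered restarts
  (default 5; multiplicative 15% + additive 0.02 noise, seeded);
* standard errors from the inverse of a central-difference Hessian of the
  deviance, step \(10^{-4}\max(1, |\theta|)\); delta-method intervals for
  smooth transforms such as standardized components (`delta_ci()`);
* pairs whose implied covariance is numerically singular contribute a
  large finite penalty (`1e10`) so the optimizer can retreat instead of
  crashing;
* sign canonicalization at convergence: path signs are only identified up
  to latent-factor reflections, so fits are reported with
  \(a_{xx}, c_{xx}, e_{xx}, a_{yy} \ge 0\). A- and C-family reflections
  couple status sets through cross-twin products in discordant pairs and
  are therefore applied globally (anchored on the immediate set), while
  E-family reflections are per status. The unique-C sign is left as
  estimated, matching how such tables are usually printed.

Both AIC conventions are reported: the standard \(-2LL + 2k\) and the
Mx/SEM convention \(-2LL - 2(\text{records} - k)\) with *records* the
number of observed data values — published twin-model AICs are often far
below the deviance, which identifies the latter convention.

## The synthetic-data generator

`simulate_pairs()` draws from exactly the generative model above: pairwise
A factors built as \(\sqrt{r}\,G + \sqrt{1-r}\,g_i\) so MZ and DZ differ
only through \(r\); C shared; E independent; phenotypes assembled from
status-specific moderated paths evaluated at the twin's own realized
centered performance. Default generating values mirror published
register-based timing-specific decomposition estimates of this model
family (immediate: \(a_{xx}=7.11, c_{xx}=3.64,
e_{xx}=3.81\), attainment paths \(0.66/0.57/0.22\) common and
\(0.53/-0.16/0.44\) unique; delayed: \(5.40/0.98/3.25\),
\(0.53/0.04/0.19\), \(0.64/-0.13/0.43\)), with the overall single-set
estimates standing in for the tracking-missing status, whose full path set
is not published. Default sample scale is 4941 pairs (1700 MZ / 3241 DZ),
birth cohorts 1986-1999, 46% male, raw performance centered at 538.

Tracking assignment is the one component with no published counterpart.
The default is a latent-threshold model
\(\text{delayed} = 1\{b_0 + b_1 X + u_{\text{pair}} + g + e > 0\}\) with a
pair-shared normal component (school choice is mostly a joint decision), a
relatedness-correlated component, and a small twin-specific residual;
\(b_0 = -1.7, b_1 = 0.08, \sigma_u = 2.5, \sigma_g = 1, \sigma_e = 0.2\)
were calibrated once to give a ~27% marginal delayed share with ~4% (MZ)
and ~11-13% (DZ) pair discordance, the register pattern. Because the
selection operates on a provisional performance realisation (the reference
path set), phenotypes are then rebuilt from the same latent draws with
status-specific paths. Alternatives — a plain logistic per twin, or a
fixed probability independent of performance — are available through the
`selection` argument; the fixed-probability form is what the estimator
validation uses, since performance-dependent selection makes the fitted
model (as in the real study) only approximately correct within groups.
Item missingness defaults mimic survey participation: 37% missing
attainment, 5% missing performance (such twins are excluded individually,
their co-twins retained), 33% generatively missing tracking status.

What the generator does *not* emulate: the discreteness and the \([0,4]\)
range of real attainment scores (phenotypes are Gaussian, matching the
model's continuous-trait assumption); gene-environment correlation,
assortative mating, and non-additive genetic effects (assumption
violations, deliberately out of scope); multi-wave survey linkage.
Passing recovery tests therefore show that the estimator inverts its own
model correctly — not that the model is right for real data.

## Reporting surfaces

* `decomposition_table()` — intercepts, paths with SEs, raw variance
  components (common / unique / total, evaluated at \(X=0\)) and
  standardized shares per parameter set;
* `conditional_variance_curves()` — raw and standardized components over
  a centered-performance grid, the tabular form of the usual moderation
  figures;
* `twin_correlations()` — double-entry Pearson correlations per zygosity
  (each pair contributes both orderings, so the estimate is invariant to
  twin labelling);
* `crosstab_with_raoscott()` — twin-level contingency tables with the
  Rao-Scott second-order (Satterthwaite F) correction for within-pair
  dependence, clusters = pairs, equal weights. The finite-sample
  convention deliberately omits \(n/(n-1)\)-type factors so that two
  identities hold exactly: with singleton clusters the corrected statistic
  equals the Pearson chi-square, and duplicating every cluster leaves the
  corrected statistic unchanged;
* `homogeneity_checks()` — the standard assumption checks that phenotype
  means and variances do not depend on birth order, zygosity, or sex,
  run as a free \(\to\) equal-variances \(\to\) equal-means sequence of
  saturated Gaussian FIML fits compared by likelihood-ratio tests.

## Design decisions taken where the design was open

* Pairs in which exactly one twin's tracking status is unobserved are
  labelled `tracking-missing` at the pair level, but estimation is
  per twin: the observed twin uses its own status set, the other the
  missing set. Discarding the observed twin's status would waste
  information.
* Attainment is treated as continuous with equal category spacing — the
  standard simplification for Dutch track levels.
* Centering constants (performance mean, birth-year mean) are computed
  from the loaded sample and stored with the table; the generator instead
  stores its true generating constants, so fitted parameters are directly
  comparable to the configuration. Both can be overridden.
* Whether published 95% CIs on standardized components are delta-method
  or profile-likelihood is usually unstated; `delta_ci()` implements the
  delta method. Profile intervals are wider near variance boundaries, the
  main situation where the two differ.
* Performance bins for selection crosstabs default to the conventional
  CITO track-correspondence edges (500-518, ..., 545-550) and are
  configurable; crosstab units are twins, with pair clustering handled by
  the Rao-Scott correction.

## Problem sizes used by the test suite

The suite validates the estimator at sizes chosen to balance statistical
resolution against runtime on a single CPU: moment agreement of the
generator at 8000 pairs; parameter recovery with a Model-1b fit on 3000
pairs (55% MZ, complete data, statuses balanced one third each so every
parameter set is informed by roughly 1000 pairs); null calibration of the
timing LRT with 200 replicates of 500 pairs; oracle equivalence of the
FIML kernel against direct Gaussian density summation on small complete
and incomplete tables. The population-averaged standardized decomposition
is the quantity held to the +-0.05 recovery band; per-status shares have
delta-method standard errors near 0.06 at this size, so they are checked
through the +-2 SE criterion on the underlying paths instead.

## Known limitations

* Standard errors rely on a finite-difference Hessian; near variance
  boundaries (components approaching zero) they can be unstable, and
  likelihood-based intervals would be preferable there.
* The tracking-missing parameter set is only weakly constrained when few
  twins lack status information; in small samples its unique-C path is
  the least stable parameter.
* No dominance (ADE), sex-limitation, or ordinal-liability variants.
* LRT calibration assumes interior optima; comparisons that pin variance
  components to a boundary would need mixture reference distributions.
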