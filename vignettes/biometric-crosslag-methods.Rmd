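---
title: "Biometric cross-lagged twin models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biometric cross-lagged twin models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinclpm)
```

# The scientific problem

Children's mental-health problems co-occur strongly enough that a single
latent dimension — the general psychopathology or *p* factor — captures a
large share of their common variance. How that dimension relates, over
development, to the child's *perception of the home environment*
(household chaos, parental discipline) is a question about direction and
aetiology: does a disordered home foreshadow later psychopathology, does
child psychopathology evoke a more chaotic home (evocative
gene–environment correlation), and are the links carried by genes, by
the family-shared environment, or by child-specific experience?

`twinclpm` implements the full modelling chain used to answer such
questions in a twin cohort measured at three occasions (target ages 9,
12 and 16): data preparation, single-factor scoring, phenotypic
cross-lagged panel models (CLPM), univariate and cross-lagged ACE twin
models with a path-level A/C/E decomposition, and the MZ-differences
design. Because raw cohort data of this kind are access-restricted, the
package is built around a *generating model with known ground truth*:
every estimator can be exercised against simulated cohorts whose
component-level dynamics are exactly known, and parameter recovery is
the package's acceptance surface.

# The generating model

The unit of simulation is the twin pair. The bivariate trait vector
$y = (P, H)'$ (psychopathology factor, home-environment composite) is
the sum of three latent component processes $X \in \{A, C, E\}$
(additive genetic, shared environment, nonshared environment), each a
lag-1 vector autoregression over the three waves:

$$x^{(X)}_{t+1} = B^{(X)}_{t} \, x^{(X)}_{t} + \zeta^{(X)}_{t+1},
\qquad y_t = \sum_X x^{(X)}_t .$$

Each component carries its own wave-1 covariance $\Sigma^{(X)}_1$,
transition matrices $B^{(X)}_{12}, B^{(X)}_{23}$ (rows = outcome trait,
columns = predictor trait) and innovation covariances
$\Psi^{(X)}_2, \Psi^{(X)}_3$. Twins within a pair share component
scores and innovations with correlation $r_A = 1$ (MZ) or $0.5$ (DZ),
$r_C = 1$, $r_E = 0$. Because every cross-twin block of the joint
process is proportional to its within-twin counterpart, the implied
cross-twin 6×6 block equals $r_X$ times the within-twin component
covariance — `build_expected_cov()` uses this closed form, and the test
suite checks it against a brute-force enumeration of the linear map
from all innovations to all twelve observations.

The component-level (rather than phenotypic-level) transmission
parameterization is what makes the A/C/E *path decomposition* well
defined: the phenotypic transition is
$B^{ph}_t = \big(\sum_X B^{(X)}_t \Sigma^{(X)}_t\big) \Sigma_t^{-1}$
and the contribution of component $X$ to a path is the corresponding
entry of $B^{(X)}_t \Sigma^{(X)}_t \Sigma_t^{-1}$; contributions are
signed and sum exactly to the phenotypic path.

Percentage shares divide each contribution by the phenotypic path when
all three contributions share its sign. With mixed signs that ratio is
no longer a proportion, so the package divides by the sum of absolute
contributions instead — shares are then guaranteed nonnegative and sum
to 100, which is the convention the reported decompositions require.
This choice matters only for paths whose contributions disagree in
sign, and it is applied identically to ground truth and to estimates.

## Observation layer

Observed scores add a linear age effect (0.05 SD/year around the wave
mean age) and a sex effect (0.2 SD, about 1% of variance) to the latent
phenotype; both are removed again by the preprocessing stage, mirroring
the standard age/sex residualization of twin analyses. The home trait
$H$ is not observed directly: the generator emits *household chaos* and
*parental discipline* indicators
$\text{chaos} = \alpha H + \beta d$, $\text{disc} = \alpha H - \beta d$
with $\alpha^2 - \beta^2 = r_{cd} = .3$, so the two indicators
correlate at .3 while their re-standardized mean — the home composite
used downstream — recovers $H$ exactly. This keeps ground truth exact
through the composite stage while still exercising the two-indicator
plumbing (and the PCA-style equal-weighting argument for the mean
composite: by construction both indicators load equally on $H$).

Optional continuous items for the p factor are generated as
$\lambda_k f + e_k$ with unit total variance, emulating the
questionnaire battery abstractly; ordinal item responses are out of
scope.

## Default calibration

The defaults of `default_genspec()` are the package's standing study
conditions, chosen once to emulate a large UK child twin cohort:

* 6,212 pairs, 34.4% MZ, 50.9% female; ages 9.02 (SD 0.29), 11.31
  (0.72), 16.32 (0.68); half the pairs lose wave 3 (two of four birth
  cohorts measured), plus 5% missing cells per wave (MCAR — the
  simplest pattern compatible with the missing-at-random assumption
  the estimators make).
* Wave-wise variance fractions per trait. Parent-rated p:
  $a^2 = .51/.67/.59$; child-rated p: $a^2 = .47/.42/.46$; home
  environment: $a^2 = .19/.19/.31$. Published sources for such cohorts
  rarely print the accompanying $c^2$; the defaults fix parent-p
  $c^2 = (.10, .08, .10)$ (the age-12 value .08 is the one value with a
  documented anchor), child-p $c^2 = (.13, .18, .14)$ (leaving the
  ~40% child-specific E typical of self-ratings), and home
  $c^2 = (.55, .55, .45)$ (a C-dominated environment measure, as its
  C-driven stability requires).
* Standardized phenotypic transitions: stability 0.70 (p) and 0.40
  (HE); cross-lags at the published path estimates per rater (parent:
  .18/.10 from p to HE and .04/.08 back; child: .14/.13 and .11/.02);
  wave-1 cross-trait correlation .30. All three components share these
  transition matrices by default, so path shares start at the variance
  fractions; `solve_shares()` then retargets chosen paths exactly.

`solve_shares()` solves the inverse problem linearly: for a targeted
path it rescales the three components' coefficients in that outcome row
(jointly for both predictors when both paths of a row are targeted,
transition 1 before transition 2) so the implied decomposition matches
the target while the phenotypic path keeps its base magnitude.
Covariances and innovations are untouched, so positive
semi-definiteness is preserved by construction. When a target names
only one component's share (e.g. "68% A"), the remainder is split
across the other two components in proportion to their current
contributions.

# Estimators

All fits maximize casewise Gaussian likelihoods (FIML): each
observation contributes the likelihood of its observed subvector,
computed from per-missingness-pattern sufficient statistics. This is
valid under missing-at-random and reduces to ordinary ML on complete
data (a property the tests assert).

* **One-factor CFA** (`fit_cfa`): loadings and uniquenesses with factor
  variance fixed at 1 (loadings comparable across waves), first loading
  nonnegative. Uniquenesses are log-parameterized; a solution heading
  below $10^{-6}$ is clamped and flagged as a Heywood case. Factor
  scores are regression-method scores $\lambda' \Sigma^{-1} (y - \mu)$
  over each case's observed indicators, then standardized; the
  regression method is the common default where the scoring method is
  not otherwise specified.
* **CLPM** (`fit_clpm`): bivariate lag-1 model, innovation covariances
  free within wave, means saturated. On complete data the likelihood
  factorizes over the recursive structure, so path estimates are the
  equation-wise least-squares solutions, computed in closed form; with
  missing cells the 23-parameter FIML objective is maximized
  numerically from pairwise-complete starting values. Standardized
  paths use model-implied SDs; cross-sectional parameters are reported
  as correlations. Confidence intervals are percentile bootstrap over
  case resampling (default 1,000 draws; the percentile flavour because
  nothing more specific is required of them), deterministic given the
  seed.
* **Univariate ACE** (`fit_univariate_ace`): ML over the 2×2 expected
  pair covariances, components parameterized as path coefficients
  (variances enter as squares, hence nonnegative). AE/CE/E submodels
  are compared by likelihood ratio and AIC; interval estimates use a
  pair-level percentile bootstrap (500 draws).
* **Biometric cross-lagged ACE** (`fit_crosslag_ace`): the 51 structure
  parameters (plus 6 means) of the three component processes, fitted to
  the 12-dimensional MZ and DZ pair observations jointly. Covariance
  blocks stay PSD through Cholesky-factor parameterization (the
  matrix-square-root trick avoids boundary pathologies of raw-variance
  parameterizations). Starting values come from a moment decomposition
  — $\hat\Sigma_A = 2(\text{cross}_{MZ} - \text{cross}_{DZ})$,
  $\hat\Sigma_C = 2\,\text{cross}_{DZ} - \text{cross}_{MZ}$,
  $\hat\Sigma_E = W - \text{cross}_{MZ}$, eigenvalue-clipped to the PSD
  cone — so BFGS polishes an already-consistent estimate; five jittered
  restarts (drawn from a locally seeded stream, so fits do not depend
  on ambient RNG state) guard against local optima. Bootstrap CIs for
  this model are off by default: every draw would repeat the full
  57-parameter optimization, and the decomposition point estimates are
  the quantity of interest.
* **MZ differences** (`mz_differences`, `fit_diff_clpm`): within-pair
  differences after seeded random twin ordering cancel A and C exactly
  (both have cross-twin correlation 1 in MZ pairs), so the difference
  process follows the E transitions and the difference-CLPM's
  standardized paths estimate the standardized E paths. Differences are
  taken on residualized scores and not re-standardized before the CLPM,
  so difference-score SDs remain interpretable; the CLPM's own
  standardization handles scale. A difference is missing if either
  member is missing at that cell (cell-level, not pair-listwise).

## Numerical choices

Optimizer: BFGS with relative log-likelihood tolerance $10^{-8}$ and up
to five jittered restarts before declaring non-convergence. Fit
statistics follow the standard ML discrepancy
($\chi^2 = (n-1)F$, CFI/TLI against the independence baseline, RMSEA
with the saturated-model convention RMSEA = 0 at df = 0, SRMR on
correlation residuals); under missing data the sample moments entering
these statistics are pairwise-complete (an explicit approximation —
the parameter estimates themselves are full FIML). Twin correlations
are double-entered Pearson correlations (each pair contributes both
orderings), numerically near-identical to the intraclass correlation.
Falconer estimates are reported unclamped, with an out-of-bounds flag,
so boundary pathologies remain visible.

# What the simulations do and do not show

The generator reproduces the *structure* that matters for these
estimators: the MZ/DZ cross-twin contrast, three-wave lag-1 dynamics,
informant-specific p dynamics, a C-dominated two-indicator home
composite, MCAR cells plus pair-level wave-3 attrition, and age/sex
nuisance effects. It deliberately omits features of real cohort data:
ordinal item scales, rater bias and cross-rater error correlation,
assortative mating, sibling interaction, sex-limitation of variance
components, and non-Gaussian tails. Passing recovery tests therefore
demonstrates that the estimators are correct and efficient for the
stated model class, not that the model class is adequate for any
particular empirical cohort.

Sampling variability at the published operating points is documented
honestly rather than hidden: a univariate $\hat a^2$ at 5,000 pairs has
SD ≈ 0.03, and the A-share of a cross-lagged path of magnitude ≈ 0.13
has SD ≈ 7 percentage points even at 20,000 pairs (the A/C split rests
on differencing MZ and DZ cross-twin moments, which amplifies noise).
The test suite therefore checks recovery criteria on means of small
fixed-seed replicate batteries sized against these measured SDs
(5 × 5,000 pairs univariate, 3 × 10,000 CLPM, 10 × 20,000
decomposition), while single-run experiments report the single-run
estimate as such.

Problem sizes throughout (5,000–20,000 pairs for recovery experiments,
50,000 for moment checks, 200 replicates × 400 bootstrap draws for
coverage) were chosen so each experiment's Monte-Carlo error is small
relative to the tolerance it is checked against.

# Known limitations

* The cross-lagged ACE likelihood assumes a single DZ group (no
  opposite-sex distinction) and no mean structure beyond saturated
  means; data should be residualized first.
* Fit indices under heavy missingness inherit the pairwise-moment
  approximation above.
* `solve_shares()` requires the targeted component to carry variance on
  the predictor trait; a zero-variance component with a nonzero share
  target is reported as infeasible rather than silently adjusted.
* Whether published share decompositions refer to path coefficients or
  to explained covariance is immaterial here: under the additive
  contribution definition both reduce to the same quantities.

# A worked run

```{r example, eval = FALSE}
spec <- default_genspec("twin", n_pairs = 2000, seed = 1)
cohort <- simulate_cohort(spec)
cohort <- inject_missingness(cohort, spec)
cohort <- residualize_age_sex(cohort)
cohort <- add_home_composite(cohort)

# phenotypic cross-lagged model on one twin per pair
singles <- select_one_per_pair(cohort, seed = 1)
wide <- singles[, c("p_twin_9", "he_9", "p_twin_12", "he_12",
                    "p_twin_16", "he_16")]
names(wide) <- c("P9", "H9", "P12", "H12", "P16", "H16")
fit_clpm(wide)

# aetiology of the paths
fit_crosslag_ace(cohort)

# nonshared-environment dynamics via MZ differences
fit_diff_clpm(mz_differences(cohort, seed = 1), n_boot = 300, seed = 1)
```

The pipeline wrapper `run_pipeline()` chains all stages from a single
config and writes the CSV/JSON report bundle; `inst/cli/twinclpm.R` is
a thin command-line wrapper around it.
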