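---
title: "Simulating and stress-testing structural models of psychopathology within subgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and stress-testing structural models of psychopathology within subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifactorsim)
```

## The scientific question

Bifactor models summarize psychopathology with a general *p*-factor — a
latent propensity on which every disorder loads — plus specific
externalising and internalising factors. If *p* is to carry substantive
meaning it must describe not just a population but the people in it: a
subgroup selected for, say, high externalising symptoms and low *p* scores
should still be describable by the same structure, with similar loadings
and similar external correlates. `bifactorsim` operationalizes that test.
A large synthetic population with a *known* generating structure is built;
four structural models are fitted to the whole sample and to 63 overlapping
subgroups carved out by tertiles of symptoms and factor scores; solutions
are screened for statistical admissibility; and loadings, factor scores and
IQ correlates are compared between each subgroup and the total sample.

Because the population is simulated, every deviation observed in a subgroup
is attributable to the subgroup selection itself, not to sampling noise or
model misspecification at the population level.

## The generating model and its parameters

Data generation starts from a *revised bifactor* structure over 11
continuous disorder symptom variables (alcohol, cannabis, hard drugs,
tobacco, conduct disorder; depression, generalised anxiety, fears/phobias;
OCD, mania, schizophrenia): a general factor *p* over all 11, specific
Ext (5 substance/conduct indicators) and Int (3 mood/anxiety indicators)
factors orthogonal to *p*, a free Ext–Int correlation, and no
thought-disorder specific factor — the three thought-disorder indicators
load on *p* alone. Two published standardized parameter sets ship as
plain-text fixtures:

```{r}
generating_parameters("caspi")$loadings
```

the Dunedin-cohort solution (`"caspi"`, Ext~Int = −.471, the default
generating set) and the solution refitted on the original study's full
simulated sample (`"simdata"`, Ext~Int = −.387, used for the deterministic
implied-covariance checks). Residual variances are 1 − communality, so the
implied moment Σ = ΛΦΛ′ + Θ is exactly a correlation matrix.

The four fitted structures (`build_model`) are the correlated factors model
`A` (Ext/Int/Tht, three free correlations, df = 41), the full bifactor `B`
(*p* + three correlated specifics orthogonal to *p*, df = 30), the revised
bifactor `C` (df = 35) and the single factor `D` (df = 44). Identification
is by unit factor variance throughout, so generating and fitted parameters
live on the same standardized metric.

## The synthetic population

`generate_population()` draws latent factor scores and symptom variables
*jointly*: the (k + 11)-dimensional normal vector has the factor
correlation matrix Φ in its latent block, the Vale–Maurelli intermediate
correlation matrix in its symptom block, and ΛΦ as the cross block. Symptom
margins are then transformed with Fleishman cubic polynomials
Y = a + bZ + cZ² + dZ³ solved (Newton with analytic Jacobian) for skewness
2.0 and excess kurtosis 7.0 per variable.

Choices worth making explicit:

- **Skew target 2.0** is the study condition (symptom counts in the general
  population are strongly right-skewed); the realized mean marginal skew at
  n = 100,000 is 1.96–2.01 across seeds. An optional jitter
  (`jitter_skew = TRUE`) draws per-variable targets from N(2, .35²),
  truncated to the power-method feasible region
  (γ₂ ≥ −1.2264 + 1.6410 γ₁², with a 2% margin) — matching the
  heterogeneity of realized skews the original study reported (SD .35).
- **Excess kurtosis 7.0** is not stated anywhere and is our choice: it sits
  comfortably inside the Fleishman region for skew 2 and resembles
  count-like data. It is configurable.
- **Intermediate correlations.** The cubic transform attenuates
  correlations, so each pairwise pre-transform correlation is solved from
  the cubic r = ρ(b₁b₂ + 3b₁d₂ + 3d₁b₂ + 9d₁d₂) + 2ρ²c₁c₂ + 6ρ³d₁d₂ so that
  the *post*-transform matrix matches the implied Σ (verified to
  max |r − Σ| < .02 at n = 100,000). Setting `vale_maurelli = FALSE`
  deliberately skips the solve; recovered loadings then shrink, reproducing
  the direction of the attenuation visible between the published cohort
  loadings and the original study's simulated loadings (e.g. *p* loading of
  alcohol .397 → .294), which suggests that study used a non-corrected
  transform. The default is the corrected generator.
- **Covariates from true latents.** The four IQ subscales (VC, PR, WM, PS)
  are weighted combinations of the latent *p*, Ext and Int draws plus
  independent noise, with weights w = Φ⁻¹r and noise variance 1 − r′Φ⁻¹r,
  then rescaled to mean 100 / SD 15. Targets are matched within ±.01 at
  n = 100,000. Using true latent draws (available only in simulation) keeps
  the covariates exactly on-target; estimated factor scores would blur them
  by score indeterminacy.
- **Skewness convention**: the population estimator g₁ = m₃/m₂^{3/2}
  (divisor n), fixed everywhere.

What the generator does *not* emulate: ordinal/zero-inflated symptom
counts, item-level structure beneath the 11 disorder categories, missing
data, and the exact (unpublished) transform of the original study — so
passing tests demonstrate fidelity to the stated moments and structure, not
to that study's single frozen dataset.

## Estimation

`fit_ml()` minimizes F_ML = log|Σ(θ)| + tr(SΣ(θ)⁻¹) − log|S| − 11 over the
free loadings, factor correlations and residual variances. The analyzed
moments are the ML (divisor-n) covariance matrix; the optimizer works on
the correlation metric, where the fixed start values (loadings .5,
correlations 0, residuals .5) are well scaled, and the solution is mapped
back by rescaling — legitimate because all four models are scale invariant.
The quasi-Newton optimizer (`nlminb`) uses the analytic gradient; because
its stopping rule is relative, the engine restarts from the solution (up to
three times) until the largest gradient element is below 1e−5, typically
reaching 1e−6–1e−8; fits that cannot are flagged non-converged. Residual
variances are left unconstrained so Heywood cases appear as negative
estimates rather than silent boundary solutions. A canonical sign
convention (each factor's loading sum nonnegative) removes the sign
indeterminacy of the factors.

The test statistic is χ² = n·F (multiplier n, not n − 1 — this is what
reproduces the published RMSEA values exactly). With raw data available,
`robust_corrections()` estimates the asymptotic covariance Γ of vech(S) by
the ADF fourth-moment formula and computes the Satorra–Bentler mean-scaled
statistic T/c with c = tr(UΓ)/df, sandwich standard errors, and the scaled
independence baseline needed for robust CFI/TLI. On multivariate normal
data the scaling factor is ≈ 1; on the skew-2 populations it is materially
above 1 (≈ 1.5–1.7 at the full-sample fit), which is why the naive χ² would
overstate misfit. The exact Yuan–Bentler variant used by mainstream SEM
software differs from the Satorra–Bentler statistic by O(1/n) terms that
are negligible at these sample sizes and is not separately implemented.

**Admissibility** (`check_admissibility`) is the five-part screen used for
"model utility": converged; every free loading significant (two-sided
z-test at α = .05 by default — the original tables flag loadings at
p < .01, but the stated criterion is only "significant", so α is
configurable and p-values are returned); no negative standardized loadings
(after the sign convention — a wholly sign-flipped factor is not
"negative"); no negative residual variances; and no non-positive-definite
implied or latent covariance (smallest eigenvalue > −1e−8, one defensible
operationalization of "non-positive-definite identification issues").
A collapsed full-bifactor fit can satisfy the gradient criterion while its
information matrix is numerically singular; robust corrections are then
unavailable (a warning says so), the significance screen cannot pass, and
the solution is reported inadmissible — which is exactly how the
thought-disorder collapse manifests.

## Fit indices

CFI, TLI, SRMR and RMSEA follow the standard definitions (see
`compute_indices`); RMSEA uses the df·n denominator, forced by the
published-value identity √((4484.98 − 41)/(41·100000)) = .033, and its 90%
interval inverts the noncentral χ² distribution in the noncentrality
parameter. SRMR includes the diagonal on the correlation metric (66 unique
elements), the common software default, since the source study does not
define it. Indices are computed from the scaled statistics by default
(model and baseline both scaled); `type = "naive"` is available, and is
what fits to a bare covariance matrix report, since Γ needs raw data.
Whether the original study's printed CFI/TLI were robust or naive variants
is unstated; at n = 10⁵ the difference is small but nonzero, and the
deterministic acceptance checks use the naive variant on the implied
matrix, which reproduces the printed values to three decimals.

## Subgroups and the sweep

Tertiles are cut at the empirical 1/3 and 2/3 quantiles of the *full
sample*, coded 1 = upper, 2 = middle, 3 = lower, ties to the higher
category. The 63 overlapping subgroups are: 27 externalising variants
(≥ 1 of the 5 externalising disorders in symptom third a, Ext factor score
in third b, *p* score in third c), 27 internalising variants (analogous),
and 9 thought-disorder variants (≥ 1 thought disorder in third a, *p* in
third c — no thought-disorder factor exists in the revised bifactor model,
hence no factor third). The factor scores that define membership always
come from the full-sample revised-bifactor fit (regression scores, *p*
standardized to mean 100 / SD 15), and symptom tertiles are computed per
disorder variable on the raw simulated scale. The "at least one disorder"
rule makes membership overlapping by design: one subject can sit in the
upper third of one disorder and the lower third of another.

`run_subgroup_sweep()` refits every configured model in every subgroup
(252 attempts), screens each fit, and builds the downstream tables from
passing fits only. Subgroup-derived factor scores are compared with the
*same model's* total-sample scoring weights applied to the same subjects —
never a refit — and both score sets are correlated with the IQ covariates.
Failed attempts are recorded rows, never errors.

The headline count of subgroups passing at least one model is **reported,
not asserted**: it is a property of each random draw and of the original
study's unpublished transform. On regenerated corrected-generator data the
count comes out higher than the original 8 (typically ≈ 20 of 63 at
n = 100,000), which is consistent with the corrected generator giving the
subgroups cleaner covariance structure than a non-corrected one would; the
report prints both numbers side by side.

## Problem sizes and numerical settings

The headline profile is n = 100,000, as in the study design; the package's
own test suite runs the full 252-attempt sweep at that size (about a minute
of compute) and uses n = 3,000–50,000 for unit-level properties.
Monte-Carlo oracles for the Fleishman moments use 1–2 × 10⁶ draws with
tolerances set from the corresponding sampling error. Degenerate inputs
(constant indicators, non-positive-definite sample matrices, saturated
models, infeasible moment pairs, target correlations outside the
reproducible range) raise explicit errors; tertile cuts on near-constant
scores warn and collapse to one category.

## Known limitations

- Continuous symptom variables throughout; ordinal/WLSMV estimation is out
  of scope.
- The robust statistics are Satorra–Bentler mean-scaled (not mean-and-
  variance adjusted, not Yuan–Bentler).
- No higher-order factor models and no Monte-Carlo replication harness —
  single-dataset design, as in the study being re-implemented.
- Exact numeric replication of the original study's subgroup tables is
  impossible by construction: that study analyzed one random dataset whose
  seed and skew transform were never published.
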