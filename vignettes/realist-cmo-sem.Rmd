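---
title: "Modelling realist context-mechanism-outcome configurations with structural equation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling realist CMO configurations with SEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Realist evaluation reasons in context-mechanism-outcome (CMO)
configurations: a context triggers an (unobservable) mechanism, which
generates an outcome. `realistsem` operationalizes this quantitatively:
each mechanism becomes a mediator, each context-mechanism-outcome triple
becomes a mediation triangle, and all configurations sharing one outcome
are estimated jointly in a single structural equation model (SEM). The
motivating application is access to primary care for socio-economically
disadvantaged older people in rural areas: nine CMOs for the single
outcome "being able to obtain an appointment", built from
individual-level ageing-cohort survey items linked to practice-level
patient-experience percentages, with individuals nested in GP practices.

## Model

The package uses the all-y LISREL parameterization. With observed vector
$y$, latent vector $\eta$:

$$ y = \Lambda \eta + \varepsilon, \qquad \eta = B \eta + \zeta, $$

with $\mathrm{Cov}(\zeta) = \Psi$, $\mathrm{Cov}(\varepsilon) = \Theta$,
giving the implied covariance

$$ \Sigma(\theta) = \Lambda (I-B)^{-1} \Psi (I-B)^{-\top} \Lambda^\top + \Theta. $$

Measurement modes per concept:

* **Reflective** latents (assertiveness, self-esteem, health care
  experience): the concept causes its indicators. Identification fixes
  the first declared indicator's loading to 1 and frees the latent
  variance, the common ML-SEM software default; standardization is a
  separate explicit step.
* **Formative** composite (transport): indicators point into the
  concept. It is compiled with free weights in $B$ (first fixed to 1)
  and zero disturbance.
* **Observed** singletons are promoted to degenerate latents (loading 1,
  residual 0).
* **Categorical** contexts (education) expand to dummy variables with
  the highest-education category as baseline; every dummy gets its own
  context-to-mechanism and direct path.

Exogenous concepts receive free variances and pairwise covariances.
Requested residual correlations (e.g. within the self-esteem factor,
where modification indices and theory agree) are freed in $\Theta$ via
an explicit argument, never automatically.

## Estimation

Estimates minimize the ML discrepancy
$F(\theta)=\ln|\Sigma(\theta)|+\mathrm{tr}(S\Sigma^{-1})-\ln|S|-p$ with
the divisor-$n$ sample covariance $S$; the chi-square convention is
$T=(n-1)F_{\min}$. Ordinal Likert items enter as numeric codes treated
as continuous (the package refuses declared-categorical indicators,
pointing to this convention, because mixed categorical/continuous
measurement models are out of scope). Missing data are handled by
listwise deletion with a logged count.

Optimization is quasi-Newton (BFGS, analytic gradient, parameters
rescaled by their start magnitudes) followed by a modified-Newton polish
with eigenvalue-clamped Hessian. Start values: loadings 1, structural
paths 0 (composite weights 1), residual and latent variances half the
observed variance of the corresponding indicator, exogenous covariances
of observed singletons at their sample values. Convergence is declared
when the largest gradient element falls below `grad_tol` (1e-6) **or**
when the achievable improvement of a full Newton step drops below
`improvement_tol` (0.05 chi-square units, far below any reporting
precision). The second criterion matters when a formative composite's
outgoing paths are weak: the weights are then only weakly identified,
the likelihood has a near-flat valley whose supremum may lie at infinite
weights, and no gradient criterion is attainable in double precision,
although every identified function of the parameters has converged.
Non-convergence is flagged, never thrown; negative variance estimates
(Heywood cases) warn and are retained.

Two covariance matrices of the estimates are computed: the inverse
observed information ("naive"), and a cluster sandwich
$A^{-1} B A^{-1}$ with $A$ the information and $B$ the outer product of
cluster-summed casewise scores, which is robust to non-normality and
within-practice dependence. With singleton clusters it reduces exactly
to the HC0 estimator (with the correction disabled). By default the
sandwich is scaled by the CR1-style small-sample factor
$\frac{G}{G-1}\frac{n-1}{n-q}$ familiar from clustered linear
regression: with a non-trivial parameter count relative to the number
of clusters the uncorrected sandwich is measurably anti-conservative
(under the fixture null we observed z-statistic standard deviations of
1.1-1.26 for several direct-effect tests, i.e. per-test type-I error up
to ~11% at nominal 5%; corrected and evaluated at n = 5000 all flags
sit at 2-8%). The plain $G/(G-1)$ factor and no correction remain
selectable. Near-singular
information (the weak-composite case) is inverted with eigenvalue
clamping and a warning, so weakly identified directions get very large,
honest variances; direct calls to `naive_vcov()` keep the strict
"parameter not locally identified" error as their default contract.

## Standardization and effect decomposition

Coefficients are standardized by model-implied latent and observed
standard deviations, so a path reads as outcome change in SD units per
SD of predictor; standard errors are propagated by the delta method
(numeric Jacobian of the standardization map times the parameter
covariance). Per CMO, `decompose_all()` reports the standardized direct
effect, the indirect effect $a\cdot b$ with delta-method SE
$\sqrt{b^2v_a + a^2v_b + 2ab\,c_{ab}}$, the total effect, and the
proportion mediated $|ab| / (|\text{direct}| + |ab|)$. The magnitude
convention in the denominator is deliberate: it reproduces both a 21%
proportion for a same-sign pair (0.140/(0.140+0.514)) and a 53%
proportion for an opposite-sign pair (0.088/(0.078+0.088)), whereas the
signed formula degenerates in the second case.

Significance flags use the robust SEs at the 95% level. For effects of
a formative composite the flag compares $|z|$ with
$\sqrt{\chi^2_{k,0.95}}$ ($k$ = number of composite indicators) instead
of 1.96: because the composite weights are estimated, the fitted
composite is the indicator direction most associated with the outcomes,
and under a true null the usual 1-df reference is anti-conservative (we
measured roughly 30-40% type-I error for the transport direct-effect
flag at nominal 5%; the adjusted reference brings it to 3-7%). Reported
confidence intervals remain plain normal-theory intervals.

## Fit assessment

`fit_indices()` computes RMSEA, CFI and TLI from the unscaled ML
chi-square against the independence baseline (free variances, zero
covariances; its ML solution is closed-form, $F_b=-\ln|R|$):
RMSEA $=\sqrt{\max(T-d,0)/(d(n-1))}$, CFI
$=1-\max(T-d,0)/\max(T_b-d_b, T-d, 0)$, TLI
$=((T_b/d_b)-(T/d))/((T_b/d_b)-1)$, with good-fit verdicts at the
strict thresholds RMSEA < 0.06 and CFI, TLI > 0.95. TLI is reported
uncapped by default (a capped variant is an option); CFI never exceeds
1. With df = 0 the indices are undefined and reported missing. Scaled
(robust) chi-square corrections are out of scope; the indices always
use the plain statistic, a caveat the report carries alongside robust
standard errors.

## The synthetic generator

Because the linked microdata behind the motivating study are not
deposited, the package ships a generator whose defaults emulate that
study's structure: 276 individuals in 178 GP practices (mean cluster
size 1.55), three reflective latents with 3-5 ordinal indicators,
a formative transport composite, practice-level percentage variables
constant within practice, and a travel-time variable drawn log-normal
with parameters solved from the published quartiles (median 4.80
minutes, IQR 2.76-7.88). Cosmetic demographic columns (sex 61.2%
female, age bands, occupation) are generated to the published marginals
but never enter estimation.

Internally every concept score is a linear combination of independent
practice-level and individual-level shocks, which the generator tracks
exactly. Individual-level variables carry a practice variance share
(`icc`, default 0.3 - chosen so that practice aggregates of individual
traits retain usable signal at the study's small cluster sizes). A
practice-level endogenous concept (convenience, obtaining an
appointment) is driven by the practice components of its predictors,
each rescaled by the inverse of its practice-component variance so that
the marginal covariance between predictor and outcome equals the
declared standardized coefficient. Consequences worth knowing:

* the pooled single-level SEM holds essentially exactly at the
  population level (misfit from Likert discretization is second-order),
  so fixture draws are "correctly specified" data for fit-index checks;
* paths between practice-level variables are recovered exactly in
  expectation; cross-level paths are recovered up to the documented
  projection;
* dummy contexts have no practice component, so their direct paths into
  a practice-level outcome cannot be realized and are recorded as
  `unrealized` in the attached truth - the compiled model still frees
  those paths and estimates them near zero;
* percent-scale variables are linear transforms (mean + sd x score,
  clamped to [0, 100]) rather than logistic ones: a nonlinear transform
  would distort the generating standardized coefficients that recovery
  tests target. The mild truncation at 100 attenuates the strongest
  practice-level paths by roughly 0.01, visible as a small downward
  bias in large-sample recovery, well inside the tolerances used.

The fixture's mechanism-to-outcome coefficients are calibration choices
(convenience 0.40, assertiveness 0.10, health literacy 0.05); each
context-to-mechanism coefficient is then the published indirect effect
divided by the mechanism's coefficient, and direct effects are the
published point estimates, so the generating ease-of-getting-through
effects are 0.514 (direct) and 0.140 (indirect), implying 21% mediated.
When a fixture of different size is requested, the number of practices
scales proportionally (mean cluster size preserved). This is a
deliberate design choice: the headline percentage variables are
practice-level, so their sampling error scales with the number of
practices, not individuals; recovery at large n is only meaningful if
the practice count grows too.

Likert thresholds are fixed once: single-item concepts (health
literacy, internet use, transport frequency items) use thresholds
solved from the published frequency tables; multi-item latents use
mildly skewed generic grids. Increasing `icc` strictly increases the
intraclass correlation of affected indicators. Missingness is MCAR per
cell at a configurable rate (default 0).

What passing tests on this generator do **not** show about real data:
true survey items are not conditionally Gaussian before discretization,
practice percentages are estimated from finite survey counts (extra
noise), real exogenous contexts correlate, and missingness is unlikely
to be MCAR. The generator is a correctness harness, not a simulation of
survey nonresponse.

## Numerical choices and degenerate inputs

* Covariance divisor n; chi-square $T=(n-1)F$; RMSEA uses the matching
  $(n-1)$ denominator. A single documented convention pair.
* Pruning retains an indicator only if p < alpha (a p exactly at alpha
  is removed), drops the worst indicator one at a time with refitting,
  and stops at 2 indicators with a warning (a 2-indicator factor is
  identified only inside a larger model; standalone CFA requires 3).
* Pruning significance uses cluster-robust SEs whenever the data carry
  at least two clusters, else naive ones.
* Modification indices are univariate score tests restricted to
  residual covariances (the only modification type contemplated);
  candidates already free are skipped with a warning.
* Zero-variance variables, non-positive-definite sample covariance,
  a single cluster for the sandwich, and cyclic path requests are all
  hard errors with named variables.
* The education CMO uses health literacy as its mechanism; the source
  material implies but does not state this pairing, and the choice is
  confined to `access_cmos()`.
* The published degrees of freedom (212) cannot be reconstructed
  unambiguously from the published description (exogenous covariance
  and dummy-coding conventions are unstated); this package's
  conventions give df = 195 for the full model, and no equality with
  212 is asserted anywhere.

## Problem sizes used by the shipped checks

The test suite and the acceptance script generate everything at run
time: one large recovery draw (n = 50 000, about 32 000 practices), 20
fit-index replications at n = 5 000, 100 null-calibration replications
at n = 5 000 (the scale at which the sandwich's asymptotic calibration
claim is meaningful), and assorted small oracle models (n = 120 to
20 000).
Each full nine-CMO fit (25 observed variables, 130 free parameters)
takes a few seconds.

## Limitations

Single-group, covariance-structure-only modelling: no mean structure,
no feedback loops, no survey weights, no FIML for missing data, no
polychoric correlations, no scaled test statistics, no growth or
multiple-group extensions. Mediation here quantifies association along
a prespecified recursive path structure; it does not by itself license
the generative causal reading realist theory aims at, and is intended
to complement, not replace, qualitative evidence.
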