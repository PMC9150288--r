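---
title: "Preconception risk profiles: models, missing data, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preconception risk profiles: models, missing data, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregprofile)
```

## The estimand

A pregnancy attempt observed from a preconception visit is a multistate
process: the attempt may end with no clinically-recognized pregnancy within
a conception window of $\tau$ menstrual cycles, or pass through an active
pregnancy into one of three terminal states — clinical pregnancy loss,
preterm birth, full-term birth. Specifying continuous-time transition
intensities for the gestational transitions is biologically fraught (their
supports are dictated by fetal viability and the definitions of the
outcomes, and gestational age has an estimated time origin), and the active
pregnancy state is of only indirect prognostic interest. The package
therefore targets the individual **risk profile**

$$p_i(\tau) = \bigl(\pi_{i0}(\tau),\; \pi_{i2|1}(\tau)\,\pi_{i\neg 0}(\tau),\;
\pi_{i3|1}(\tau)\,\pi_{i\neg 0}(\tau),\; \pi_{i4|1}(\tau)\,\pi_{i\neg 0}(\tau)\bigr),$$

a probability vector over (no pregnancy, loss, preterm, full-term), with
$\pi_{i\neg 0}(\tau) = 1-\pi_{i0}(\tau)$ the probability of conception
within the window and $\pi_{ik|1}(\tau)$ limiting conditional
state-occupation probabilities given conception. The canonical class order
`(nopreg, loss, preterm, fullterm)` is fixed everywhere in the package —
profile columns, HUM labels, plots — to preclude silent permutation bugs.

## The two nested stage models

**Conception.** Time to clinically-recognized pregnancy is measured in
discrete menstrual cycles, so the conception intensity is modeled as a
discrete-time hazard,

$$\operatorname{logit} P(T_{1i}=t \mid T_{1i}\ge t, x_i) = g_t + \gamma^\top x_i,
\qquad t = 1,\dots,\tau,$$

with one baseline logit per cycle. Expanding each subject's follow-up into
one binary row per at-risk cycle turns the survival likelihood into a
logistic-regression likelihood on $N=\sum_i U_i$ rows, fit under working
independence (`fit_conception()`); subjects censored before conception
contribute their observed cycles only, which is valid under
$T_{1i} \perp C_i \mid x_i$ (an assumption, not a testable property — no
sensitivity machinery is provided). The per-cycle intercepts are
parameterized as a reference intercept at $t=1$ plus offsets
$I(t=2),\dots,I(t=\tau)$, matching how such models are conventionally
reported; a cycle with no person-period rows inherits the last estimable
cycle's baseline with a warning rather than extrapolating silently. The
conception probability is recovered as
$\sum_{t\le\tau} h_t(x)\prod_{j<t}(1-h_j(x))$, algebraically equal to
$1-\prod_t(1-h_t(x))$; both forms are computed and tested against each
other.

**Gestation.** Given conception, the clinical result follows a
multinomial logit with full-term birth as the reference class
(`fit_gestation()`), deliberately agnostic to *when* conception occurred
within the window — richer models that feed the predicted conception time
into the second stage are out of scope. Optimization uses `nnet::multinom`
with a tight relative tolerance (1e-12, up to 500 iterations);
non-convergence is an error, never a silent truncation. Per-subject
weights multiply log-likelihood contributions, which is the entry point
for the inverse-probability-weighted path. An empty outcome class is a
hard error naming the class: the model is not identifiable without all
three.

Covariates must arrive numerically coded (0/1 for binaries); the package
does not infer factor encodings, so coefficient meaning is stable across
refits and matches the reference coefficient table shipped in
`reference_models()`.

## Two-stage missingness

Let $R_{i1}$ indicate that first-stage status at $\tau$ is known and
$R_{i2}$ that the gestation outcome is known. Subjects fall into four
observed-data patterns (censored before conception; no pregnancy;
pregnancy with unknown result; pregnancy with known result) —
`observation_pattern()`. A subject followed through $\tau$ without
conceiving has $R_{i2}=1$ vacuously: the second-stage outcome is known to
be undefined. The package adopts this convention throughout (it mirrors
how such tables are reported), and rejects records with $R_2=1, R_1=0$.

The working assumption is **sequential missingness at random**:
$P(R_1{=}1\mid w,Y) = P(R_1{=}1\mid x')$ and
$P(R_2{=}1\mid w,R_1{=}1,Y) = P(R_2{=}1\mid z',R_1{=}1,Y_1)$ — second-stage
verification may depend on whether conception occurred but not on how the
pregnancy ended.

**Sequential multiple imputation** (`sequential_impute()`): per replicate,
(i) missing baseline covariates are imputed by chained equations (10
sweeps; logistic draws for binaries, normal draws with residual SD for
continuous variables, multinomial draws for categoricals) — a deliberately
light imputer covering the low covariate-missingness rates the generator
emulates (≤ 1.5%); (ii) the conception cycle of each subject censored at
$u_i<\tau$ is drawn from its conditional distribution over
$\{u_i+1,\dots,\tau,\tau+1\}$, with $\tau+1$ encoding no conception,
implied by a pooled discrete-time hazard fit on the auxiliary covariate
set. A fully stratified multinomial imputation model (one parameter vector
per censoring cycle) is the literal alternative, but its strata are sparse
at realistic cohort sizes; the pooled-hazard form targets the same
conditional distribution under logit-additive effects and is numerically
stable, so it is the implementation used. (iii) gestation outcomes of
unverified pregnancies (observed or imputed) are drawn from a multinomial
model on the gestation-plus-auxiliary covariates fit to observed outcomes.
The auxiliary set defaults to $x \cup x'$. Point estimates are pooled as
means across replicates; with supplied variances `rubin_pool()` returns
the total variance with the $(1+1/M)$ between-imputation inflation.
Replicates draw from sub-seeds derived once from the master seed, so
results are invariant to $M$ and evaluation order.

**Inverse-probability weighting** (`complete_case_weights()`): the
complete cases for the gestation model are weighted by
$1/\hat\pi^C_i$ with
$\pi^C_i = P(R_2{=}1\mid z',R_1{=}1,Y_1{=}1)\,P(Y_1{=}1\mid x,R_1{=}1)\,P(R_1{=}1\mid x')$,
each factor a logistic model. Weights are truncated at the 1st/99th
percentiles of their own distribution by default (configurable): weights
built from near-zero probabilities are the known instability of this
estimator. Choosing between MI and IPW is a modeling judgment — MI
requires a credible model for the missing data given the observed, IPW a
credible model for the missingness process, and MI is more efficient when
both are right; the package exposes both so that agreement between them
can serve as a specification check.

## Validation: forced-choice HUM

Discrimination over four unordered classes is measured by the HUM: the
probability that four individuals, one per class, are simultaneously
classified correctly. The decision rule assigns the four class labels to
the four individuals (each label used exactly once — an unconstrained
argmin would decouple the individuals and make the class weights inert),
minimizing $\sum_k \omega_k \lVert p^{(k)} - e_{c_k}\rVert$ over all $4!$
assignments. Ties within a tolerance of 1e-9 score zero: the conservative
choice, consistent with all-uniform profiles carrying no information.
Equal weights $\omega = (1,1,1,1)$ are the default, reading the HUM as
overall classification performance.

`hum_nonparametric()` averages the correct-classification indicator over
all $n_1 n_2 n_3 n_4$ tuples when that count is below a ceiling (1e6 by
default) and otherwise refuses exact mode, directing to Monte Carlo
sampling of tuples (2e5 draws by default — at realistic cohort sizes the
tuple count is on the order of 1e9, and the MC standard error at 2e5 draws
is about 0.0005 for a HUM near 0.1). The chance level is $1/4!$; note that
the *exact* HUM of a finite set of uninformative profiles is itself random
around that value (standard deviation roughly 0.007 with 200 profiles per
class), which is why the reference estimator `hum_chance_rate()` draws
fresh profile tuples per Monte Carlo draw, making its error exactly
binomial.

With differential verification, the complete-case HUM is biased;
`hum_ipw()` weights each verified tuple by the inverse product of its
members' verification probabilities
$\hat\pi^R_i = \hat P(R_2{=}1\mid z',R_1{=}1,Y_1)\hat P(R_1{=}1\mid x')$
and divides by the summed weights. With constant $\pi^R$ the weights
cancel and the estimator reduces exactly to the unweighted one (a tested
identity). `optimism_correct()` implements bootstrap optimism correction:
refit the pipeline on each resample, score it on the resample and on the
original data, and subtract the mean difference from the apparent
statistic. By default the correction conditions on the originally selected
model *form* (re-running covariate selection inside each replicate is
available behind a flag, but is less stable). Bootstrap resampling is at
the subject level, unstratified. Confidence intervals use bootstrap SEs
with a normal approximation, truncated to $[0,1]$.

## The synthetic cohort generator

`simulate_cohort()` emulates a preconception cohort of the kind that
motivated the methodology: some 1,000 women followed up to $\tau=6$
cycles, with continuous age and BMI, several 0/1 covariates, 1–2 previous
pregnancy losses, and a cycles-trying count. The default parameter set
(`eager_like_params()`) uses the reference two-stage coefficients as the
generative truth, a constant per-cycle censoring hazard of 0.035
(covariate-independent, matching the $T_1\perp C$ assumption;
covariate-dependent censoring is available for stress tests), a
second-stage verification model with a high intercept (secondary
missingness is rare, about 2% of conceivers), and MCAR covariate
missingness at the low observed rates (BMI 1.4%, others < 1%). These
defaults reproduce the published observed-pattern frequencies to well
within a factor of two (simulated ≈ 9.3 / 26.3 / 1.6 / 62.8% versus
published 8.1 / 29.2 / 1.1 / 61.5%) and were fixed once against those
frequencies, not against any estimator output.

What the generator does **not** emulate: day-level fecundability or
cycle-length biology (cycles are abstract Bernoulli trials), covariate
measurement error, informative censoring, or missingness that depends on
the gestation outcome (MNAR). Passing tests therefore demonstrate
correctness of the estimators under sequential MAR and the stated
independence assumptions — they cannot certify behavior on real data where
those assumptions fail.

First-stage verification in the generator is a consequence of censoring
($R_1 = 0$ exactly when dropout precedes both conception and $\tau$)
rather than an independent coin, which keeps the latent data internally
consistent ($\delta = 1 \iff T_1 \le C \wedge \tau$, an emitted-and-tested
invariant). Latent truth (`true_t1`, `true_censor`, `true_outcome`,
`true_class`) is emitted in a separately named column block so
observed-data code cannot consume it accidentally.

## Selection and orchestration

`backward_aic_select()` performs backward AIC elimination for either stage
on the stacked $M\times n$ completed cohorts, with forced-in covariates
never removed and lexicographic tie-breaking. The AIC is applied literally
to the stacked data — no adjustment for the $M$-fold inflation of the
sample size. This matches the procedure as commonly practiced; it makes
selection mildly conservative toward larger models, which is the safer
direction for a prediction tool, and the selected form is then refit per
completed cohort and pooled. `run_analysis()` chains the chosen
missing-data path, selection, per-imputation fits, Rubin pooling, profile
prediction (for subjects with complete baseline covariates — subjects with
missing model covariates are skipped and listed), verification-weighted
HUM, and optimism correction, with every random stage seeded from one
master seed; reports are reproducible bit-for-bit under a fixed seed.

## Numerical choices and problem sizes

- Logistic fits use `stats::glm`; the spurious non-integer-successes
  warning under fractional weights is muffled, and fits that do not
  converge raise errors. Coefficients above 15 in absolute value trigger a
  separation warning.
- The multinomial optimizer runs to relative tolerance 1e-12 with at most
  500 iterations.
- Probability floors: verification probabilities below 1e-3 are raised to
  the floor with a warning before inverse weighting.
- The test suite validates parameter recovery over 200 simulated cohorts
  of n = 2000 at the default generator settings for the complete-data, MI
  (M = 10), and IPW paths, verification-bias correction of the HUM over
  200 replicates of n = 1200, and the HUM estimators against brute-force
  enumeration on small instances; these sizes keep the full suite around
  ten minutes on one CPU while leaving Monte Carlo error well inside the
  asserted tolerances.

## Known limitations

- Sequential MAR is assumed, not tested; no MNAR sensitivity analysis and
  no doubly-robust estimator is provided.
- The second stage ignores conception timing by design; if gestation risk
  varies with time-to-conception, the conditional probabilities are
  marginal over it.
- Rubin total variance is available only when per-imputation variances are
  supplied; the HUM's interval estimation relies on the bootstrap, not on
  an analytic variance.
- The chained-equations imputer is intentionally minimal (generalized
  linear draws, no predictive mean matching); with heavy or structured
  covariate missingness a dedicated imputation package would be
  preferable, fed into `sequential_impute()`'s completed-cohort interface.
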