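# pregprofile

Individualized preconception risk profiles for pregnancy attempts, with
principled handling of two-stage outcome missingness and multiclass
validation.

## The problem

A person planning a pregnancy attempt, and their obstetrician, face a joint
question at the preconception visit: *will a clinically-recognized pregnancy
occur within the next `τ` menstrual cycles, and if so, how will it end?*
`pregprofile` estimates, from baseline covariates `w` collected at that
visit, the four-category **preconception risk profile**

```
p(τ) = ( π₀(τ),  π₂|₁(τ)·π₋₀(τ),  π₃|₁(τ)·π₋₀(τ),  π₄|₁(τ)·π₋₀(τ) )
```

over the outcomes *no pregnancy within τ cycles*, *clinical pregnancy
loss*, *preterm birth*, and *full-term birth*, where `π₋₀(τ) = 1 − π₀(τ)`
is the probability of conception within the window and `π_k|₁` are the
conditional probabilities of each gestation outcome given conception.

The profile is built from two nested models, sidestepping the untenable
task of specifying continuous-time transition intensities for gestational
outcomes:

1. **Conception stage** — a discrete-time hazard on the cycle scale,
   `logit P(T₁ = t | T₁ ≥ t, x) = g_t + γᵀx`, `t = 1..τ`, fit by logistic
   regression on the person-period expansion (one row per at-risk cycle).
   The conception probability is recovered as
   `P(T₁ ≤ τ | x) = Σ_t h_t(x) Π_{j<t} (1 − h_j(x))`.
2. **Gestation stage** — a multinomial logit for the result of a
   recognized pregnancy with full-term birth as reference,
   `log(π_k|₁ / π₄|₁) = α_kᵀ z`, `k ∈ {loss, preterm}`.

Cohort studies of pregnancy rarely observe both stages completely. The
package assumes the outcome vector is **missing sequentially at random**
(first-stage verification depends on covariates only; second-stage
verification on covariates and the first-stage outcome, not the result)
and offers two analysis paths:

- **Sequential multiple imputation**: impute the latent conception cycle
  for subjects censored before conception from its conditional
  discrete-time distribution (with `τ+1` encoding no conception), then the
  gestation outcome for unverified pregnancies, `M` times; fit per
  completed cohort and pool by Rubin's rules.
- **Inverse-probability weighting**: fit the gestation model on complete
  cases weighted by `1/π^C`, the inverse probability of being a complete
  case, factorized into the two verification stages and the selection
  probability.

Discrimination is validated with the **Hypervolume Under the Manifold
(HUM)** — the probability that four individuals, one per outcome class,
are all matched to their classes by a weighted forced-choice rule that
assigns the four class labels to minimize the summed distances between
risk profiles and simplex vertices. Chance level is `1/4! ≈ 0.0417`.
Because verification itself is differential, the package provides the
verification-bias-adjusted HUM (tuples weighted by inverse verification
probabilities `π^R`) and Harrell-style bootstrap optimism correction.

A synthetic-cohort simulator with a latent truth block stands in for the
restricted-access trial data that motivated the methodology, so every
estimator can be tested against known parameters.

## Worked example

The package ships the published two-stage coefficient set from the
motivating preconception cohort analysis and three hypothetical patients:

```r
library(pregprofile)

ref <- reference_models()
predict_profiles(ref$conception, ref$gestation, example_patients())
#> # preconception risk profiles: 3 subjects
#> # A tibble: 3 × 5
#>   id       p_nopreg p_loss p_preterm p_fullterm
#>   <chr>       <dbl>  <dbl>     <dbl>      <dbl>
#> 1 patient1    0.207 0.126     0.0497      0.617
#> 2 patient2    0.499 0.0768    0.120       0.304
#> 3 patient3    0.637 0.101     0.0504      0.211
```

Patient 1 (median-participant profile) has a 21% chance of not conceiving
within six cycles and, unconditionally, a 62% chance of a full-term birth;
patient 3 (advanced maternal age) has a 64% chance of not conceiving.
Each row sums to one.

A full simulate–impute–fit–validate cycle:

```r
cohort <- simulate_cohort(eager_like_params(n = 1000), seed = 42)
table(observation_pattern(cohort))
#>   censored_preconception             no_pregnancy pregnancy_unknown_result
#>                       99                      242                       17
#>   pregnancy_known_result
#>                      642

report <- run_analysis(cohort, path = "mi", M = 5, B = 0, seed = 7,
                       select = FALSE, mc_draws = 5e4)
report$hum$value        # verification-adjusted HUM on verified subjects
#> [1] 0.107874
hum_chance_rate(K = 4, draws = 2e5, seed = 7)$value  # ~ 1/4! reference
#> [1] 0.04199
```

The fitted model's HUM of 0.108 sits clearly above the chance value
`1/4! ≈ 0.0417`: in about 11% of random four-tuples (one subject per true
outcome class) the profiles match all four subjects to their classes
simultaneously, versus 4% by chance. `run_analysis(..., B = 200)` adds the
bootstrap optimism correction (conditioning on the selected model form).

A thin command-line wrapper over the same functions lives at
`inst/cli/pregprofile.R` (subcommands `simulate`, `fit-conception`,
`fit-gestation`, `predict`, `impute`, `weights`, `validate`, `run`).

## Package tour

| area | functions |
|---|---|
| cohort data | `preg_cohort()`, `cohort_roles()`, `read_cohort()`, `write_cohort()`, `observation_pattern()`, `expand_person_period()` |
| conception stage | `fit_conception()`, `new_conception_model()`, `conception_hazard()`, `cumulative_conception()`, `conception_mass()` |
| gestation stage | `fit_gestation()`, `new_gestation_model()`, `conditional_probs()` |
| risk profiles | `compose_profile()`, `predict_profiles()`, `autoplot()`, `plot_conception_mass()` |
| missing data | `fit_missingness()`, `verification_prob()`, `complete_case_weights()`, `impute_conception_time()`, `sequential_impute()`, `rubin_pool()` |
| validation | `classify_set()`, `hum_nonparametric()`, `hum_ipw()`, `hum_chance_rate()`, `hum_bootstrap_ci()`, `optimism_correct()` |
| simulation | `sim_params()`, `simulate_cohort()`, `eager_like_params()` |
| orchestration | `backward_aic_select()`, `run_analysis()`, `write_model_json()`, `read_model_json()` |

Fitted objects support `tidy()` and `glance()`. See the methods vignette
(`vignettes/methods.Rmd`) for the statistical background, default choices,
and limitations.
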