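#' Reference two-stage coefficient set from the motivating trial analysis
#'
#' The published selected models from the EAGeR preconception cohort
#' analysis: a discrete-time conception hazard over six cycles (per-cycle
#' baseline logits plus eight covariate effects) and a multinomial
#' gestation-outcome model (loss and preterm log-odds versus full-term on
#' four covariates), together with the single-model verification
#' coefficients. Useful as a realistic fixed truth for simulation, for the
#' worked example, and for reproducing the published hypothetical-patient
#' risk profiles.
#'
#' @return List with elements `conception` (a `conception_fit`), `gestation`
#'   (a `gestation_fit`), and `verification` (named logit coefficients for
#'   P(R = 1 | w)).
#' @export
reference_models <- function() {
  g1 <- -0.542
  offsets <- c(-0.047, -0.148, -0.152, -0.456, -0.402)
  conception <- new_conception_model(
    baseline_logits = g1 + c(0, offsets),
    coefficients = c(
      cycles_trying = -0.120, aspirin = 0.185, age = -0.026, losses = 0.058,
      white = 0.444, college = 0.251, bmi = -0.027, parous = 0.357
    ),
    tau = 6L
  )
  gestation <- new_gestation_model(
    alpha_loss = c(`(Intercept)` = -3.025, age = 0.041, losses = 0.265,
                   white = 0.012, hypertension = 0.412),
    alpha_preterm = c(`(Intercept)` = -0.827, age = -0.032, losses = -0.089,
                      white = -0.698, hypertension = 0.741)
  )
  verification <- c(`(Intercept)` = 2.050, white = 0.773, college = 0.474,
                    bmi = -0.024, parous = 0.366, smoker = -0.973)
  list(conception = conception, gestation = gestation,
       verification = verification)
}

#' Hypothetical patients for the worked example
#'
#' Three preconception covariate profiles spanning the published cohort: a
#' median-participant profile, a higher-risk profile (hypertensive,
#' nulliparous), and an advanced-maternal-age profile.
#'
#' @return Tibble with `id` and the covariate columns used by
#'   [reference_models()].
#' @export
example_patients <- function() {
  tibble::tibble(
    id = c("patient1", "patient2", "patient3"),
    cycles_trying = c(1, 2, 4),
    aspirin = c(1, 0, 0),
    age = c(28.3, 23.7, 39.3),
    losses = c(1, 1, 1),
    white = c(1, 0, 0),
    college = c(0, 0, 0),
    bmi = c(24.4, 21.1, 27.2),
    parous = c(1, 0, 1),
    hypertension = c(0, 1, 1)
  )
}
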