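test_that("simulation is deterministic under a seed and internally consistent", {
  params <- fast_sim_params(n = 400)
  a <- simulate_cohort(params, seed = 19)
  b <- simulate_cohort(params, seed = 19)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c2 <- simulate_cohort(params, seed = 20)
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c2)))

  # latent consistency: conceived = 1 iff T1 <= min(C, tau)
  expect_equal(a$conceived,
               as.integer(a$true_t1 <= pmin(a$true_censor, 4L)))
  # conceivers carry their latent outcome when verified
  known <- a$conceived == 1 & a$r2 == 1
  expect_equal(a$outcome[known], a$true_outcome[known])
  expect_true(all(is.na(a$outcome[!known])))
})

test_that("empirical per-cycle hazards match the generating model", {
  params <- fast_sim_params(n = 40000, censor_p = 1e-9)
  co <- simulate_cohort(params, seed = 23)
  dat <- tibble::as_tibble(co)
  for (t in 1:4) {
    at_risk <- dat$true_t1 >= t
    h_true <- mean(plogis(params$conception$baseline_logits[t] -
                            0.4 * dat$age[at_risk] +
                            0.3 * dat$aspirin[at_risk]))
    h_emp <- mean(dat$true_t1[at_risk] == t)
    se <- sqrt(h_true * (1 - h_true) / sum(at_risk))
    expect_lt(abs(h_emp - h_true), 3 * se + 1e-9)
  }
})

test_that("default trial-like parameters produce realistic pattern frequencies", {
  params <- eager_like_params(n = 20000)
  validate <- simulate_cohort(params, seed = 37)
  freq <- prop.table(table(observation_pattern(validate)))
  published <- c(censored_preconception = 0.081, no_pregnancy = 0.292,
                 pregnancy_unknown_result = 0.011,
                 pregnancy_known_result = 0.615)
  for (nm in names(published)) {
    expect_gt(freq[[nm]], published[[nm]] / 2)
    expect_lt(freq[[nm]], published[[nm]] * 2)
  }
  # cumulative conception at covariate means inside the published range
  ref <- reference_models()
  dat <- tibble::as_tibble(validate)
  means <- dat[, names(ref$conception$coefficients)] |>
    dplyr::summarise(dplyr::across(dplyr::everything(),
                                   ~ mean(.x, na.rm = TRUE)))
  pc <- cumulative_conception(ref$conception, means)
  expect_gt(pc, 0.145)
  expect_lt(pc, 0.919)
})

test_that("missingness is generated without reference to the latent outcome", {
  # among conceivers with identical z', R2 must be independent of Y2
  params <- fast_sim_params(n = 30000, verif_int = 0.5)
  co <- simulate_cohort(params, seed = 53)
  dat <- tibble::as_tibble(co)[co$conceived == 1, ]
  for (a in 0:1) {
    sub <- dat[dat$aspirin == a, ]
    p_by_outcome <- tapply(sub$r2, sub$true_outcome, mean)
    n_by_outcome <- table(sub$true_outcome)
    pooled <- mean(sub$r2)
    se <- sqrt(pooled * (1 - pooled) / n_by_outcome)
    expect_true(all(abs(p_by_outcome - pooled) < 4 * se))
  }
})

test_that("simulate-fit round trip recovers the reference truth", {
  params <- eager_like_params(n = 12000)
  params$covariate_missing <- numeric(0)
  co <- simulate_cohort(params, seed = 71)
  cm <- fit_conception(co)
  ref <- reference_models()
  se <- sqrt(diag(vcov(cm$fit)))
  for (nm in names(ref$conception$coefficients)) {
    expect_lt(abs(cm$coefficients[[nm]] - ref$conception$coefficients[[nm]]),
              4 * se[[nm]])
  }
  gm <- fit_gestation(co)
  expect_lt(abs(gm$alpha_loss[["age"]] - 0.041), 0.05)
  expect_lt(abs(gm$alpha_preterm[["hypertension"]] - 0.741), 0.75)
})

test_that("invalid simulation parameters are rejected", {
  params <- fast_sim_params(n = 10)
  params$conception$baseline_logits <- c(-1, -1)
  expect_error(simulate_cohort(params, seed = 1), "length tau")
  params2 <- fast_sim_params(n = 10)
  params2$covariates$age <- list("bernoulli", 1.4)
  expect_error(simulate_cohort(params2, seed = 1), "\\(0, 1\\)")
  expect_error(
    sim_params(
      n = 5, tau = 2,
      covariates = list(x = list("normal", 0, 1)),
      conception = list(baseline_logits = c(-1, -1),
                        coefficients = c(y = 1)),
      gestation = list(alpha_loss = c(`(Intercept)` = 0),
                       alpha_preterm = c(`(Intercept)` = 0)),
      censoring = list(intercept = -3),
      verification = list(intercept = 2),
      roles = cohort_roles(x = "x", z = "x")
    ),
    "undeclared covariates"
  )
})
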