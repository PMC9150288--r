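test_that("verification probability is the product of the stage models", {
  co <- simulate_cohort(fast_sim_params(n = 2000), seed = 17)
  mm <- fit_missingness(co, form = "product")
  dat <- tibble::as_tibble(co)
  p1 <- predict(mm$stage1, dat, type = "response")
  p2 <- predict(mm$stage2, dat, type = "response")
  expect_equal(verification_prob(mm, dat), unname(p1 * p2), tolerance = 1e-12)

  # degenerate: no variation at a stage
  all_obs <- dat
  all_obs$r1 <- 1L
  all_obs$U[all_obs$conceived == 0] <- 4L
  all_obs$r2[all_obs$conceived == 0] <- 1L
  expect_error(
    fit_missingness(preg_cohort(all_obs, tau = 4,
                                roles = attr(co, "roles"))),
    "stage 1"
  )
})

test_that("missingness coefficients are recovered from simulated truth", {
  co <- simulate_cohort(fast_sim_params(n = 8000, verif_int = 1.2), seed = 29)
  mm <- fit_missingness(co, form = "product")
  # stage 2 among conceivers: logit P(R2) = 1.2 - 0.5 * aspirin
  cf <- coef(mm$stage2)
  se <- sqrt(diag(vcov(mm$stage2)))
  expect_lt(abs(cf[["aspirin"]] - (-0.5)), 3 * se[["aspirin"]])
})

test_that("complete-case weights invert the three-factor probability", {
  co <- simulate_cohort(fast_sim_params(n = 1500), seed = 31)
  mm <- fit_missingness(co, form = "product")
  cw <- complete_case_weights(mm, co, truncate = NULL)
  dat <- tibble::as_tibble(co)
  cc <- dat$r1 == 1 & dat$conceived == 1 & dat$r2 == 1
  expect_equal(nrow(cw), sum(cc))
  row <- dat[cc, ][1, ]
  pi_c <- predict(mm$stage1, row, type = "response") *
    predict(mm$stage2, row, type = "response") *
    predict(mm$selection, row, type = "response")
  expect_equal(cw$weight[1], unname(1 / pi_c), tolerance = 1e-12)
  trunc <- complete_case_weights(mm, co)
  expect_lte(max(trunc$weight), quantile(cw$weight, 0.99) + 1e-9)
})

test_that("conception-time imputation follows the analytic conditional law", {
  cm <- new_conception_model(
    baseline_logits = qlogis(c(0.3, 0.25, 0.2, 0.15)), coefficients = c(x = 0)
  )
  cens <- tibble::tibble(
    id = as.character(1:20000), U = 1L, conceived = 0L, r1 = 0L, r2 = 0L,
    outcome = NA_character_, x = 0
  )
  draws <- impute_conception_time(cens, cm, seed = 12)
  # analytic conditional masses over {2, 3, 4, 5(=none)} given T1 > 1
  h <- c(0.25, 0.2, 0.15)
  mass <- c(h[1], (1 - h[1]) * h[2], (1 - h[1]) * (1 - h[2]) * h[3],
            prod(1 - h))
  emp <- as.numeric(table(factor(draws$t1, levels = 2:5))) / nrow(cens)
  se <- sqrt(mass * (1 - mass) / nrow(cens))
  expect_true(all(abs(emp - mass) < 3 * se + 1e-9))

  # degenerate point masses
  cm0 <- new_conception_model(qlogis(c(0.3, 1e-12, 1e-12, 1e-12)),
                              c(x = 0))
  d0 <- impute_conception_time(cens[1:50, ], cm0, seed = 1)
  expect_true(all(d0$t1 == 5L))
  cm1 <- new_conception_model(qlogis(c(0.3, 1 - 1e-12, 0.5, 0.5)), c(x = 0))
  d1 <- impute_conception_time(cens[1:50, ], cm1, seed = 1)
  expect_true(all(d1$t1 == 2L))

  # contradiction: censored at tau
  bad <- cens[1, ]
  bad$U <- 4L
  expect_error(impute_conception_time(bad, cm), "contradictory")
})

test_that("sequential imputation completes cohorts and is seed-deterministic", {
  params <- fast_sim_params(n = 800, censor_p = 0.10, verif_int = 1.0)
  co <- simulate_cohort(params, seed = 61)
  imp <- sequential_impute(co, M = 3, seed = 100)
  expect_equal(imp$M, 3)
  for (m in 1:3) {
    cm <- imp$cohorts[[m]]
    expect_true(all(cm$r1 == 1 & cm$r2 == 1))
    expect_false(anyNA(cm$outcome[cm$conceived == 1]))
    expect_true(all(cm$U[cm$conceived == 0] == 4))
  }
  imp2 <- sequential_impute(co, M = 3, seed = 100)
  expect_identical(
    lapply(imp$cohorts, tibble::as_tibble),
    lapply(imp2$cohorts, tibble::as_tibble)
  )
  # a cohort with no missingness comes back as M identical copies
  full <- simulate_cohort(fast_sim_params(n = 200, censor_p = 1e-9,
                                          verif_int = 30), seed = 3)
  stopifnot(all(full$r1 == 1), all(full$r2 == 1))
  imp3 <- sequential_impute(full, M = 2, seed = 5)
  expect_identical(tibble::as_tibble(imp3$cohorts[[1]]),
                   tibble::as_tibble(full))
})

test_that("MI pooling recovers gestation truth under sequential MAR", {
  reps <- 25
  est <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    co <- simulate_cohort(fast_sim_params(n = 1200, censor_p = 0.12,
                                          verif_int = 0.8),
                          seed = 4000 + r)
    imp <- sequential_impute(co, M = 4, seed = 4000 + r)
    alphas <- lapply(imp$cohorts, function(cm) {
      f <- fit_gestation(cm)
      c(f$alpha_loss[["age"]], f$alpha_preterm[["age"]])
    })
    est[r, ] <- rubin_pool(alphas)$estimate
  }
  se_mean <- apply(est, 2, sd) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - 0.5), 3 * se_mean[1])
  expect_lt(abs(mean(est[, 2]) - (-0.3)), 3 * se_mean[2])
})

test_that("Rubin pooling follows the combination rules", {
  pooled <- rubin_pool(list(c(a = 1), c(a = 3)),
                       variances = list(c(a = 2), c(a = 4)))
  expect_equal(unname(pooled$estimate), 2)
  expect_equal(unname(pooled$between), 2)
  expect_equal(unname(pooled$total), 3 + (1 + 1/2) * 2)

  ests <- list(c(a = 1, b = 0), c(a = 2, b = 1), c(a = 3, b = -1))
  expect_equal(rubin_pool(ests)$estimate, rubin_pool(rev(ests))$estimate)
  same <- rubin_pool(list(c(a = 5), c(a = 5), c(a = 5)))
  expect_equal(unname(same$estimate), 5)
  expect_equal(unname(same$between), 0)
  expect_error(rubin_pool(list(c(a = 1))), "at least 2")
})

test_that("chained-equations covariate imputation fills declared roles", {
  params <- fast_sim_params(n = 600)
  params$covariate_missing <- c(age = 0.15)
  co <- simulate_cohort(params, seed = 83)
  expect_true(anyNA(co$age))
  imp <- sequential_impute(co, M = 2, seed = 9)
  for (m in 1:2) expect_false(anyNA(imp$cohorts[[m]]$age))
  expect_gt(imp$diagnostics$n_covariates[1], 0)
})
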