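# Shared fixtures: a tiny hand-built cohort exhibiting all four observed-data
# patterns, and small parameter sets for fast simulation.

tiny_roles <- function() {
  cohort_roles(x = c("age", "aspirin"), z = c("age"),
               x_miss = c("aspirin"), z_miss = c("aspirin"))
}

# four subjects, one per observed-data pattern
tiny_cohort <- function(tau = 6L) {
  preg_cohort(
    tibble::tibble(
      id = c("a", "b", "c", "d"),
      U = c(3L, 6L, 2L, 4L),
      conceived = c(0L, 0L, 1L, 1L),
      r1 = c(0L, 1L, 1L, 1L),
      r2 = c(0L, 1L, 0L, 1L),
      outcome = c(NA, NA, NA, "fullterm"),
      age = c(28, 31, 25, 35),
      aspirin = c(1, 0, 0, 1)
    ),
    tau = tau, roles = tiny_roles()
  )
}

# small simulation parameters with strong effects and no covariate missingness
fast_sim_params <- function(n = 500, censor_p = 0.05, verif_int = 2.5) {
  sim_params(
    n = n, tau = 4L,
    covariates = list(
      age = list("normal", 0, 1),
      aspirin = list("bernoulli", 0.5)
    ),
    conception = list(
      baseline_logits = c(-0.6, -0.8, -1.0, -1.2),
      coefficients = c(age = -0.4, aspirin = 0.3)
    ),
    gestation = list(
      alpha_loss = c(`(Intercept)` = -1.2, age = 0.5),
      alpha_preterm = c(`(Intercept)` = -1.6, age = -0.3)
    ),
    censoring = list(intercept = qlogis(censor_p)),
    verification = list(intercept = verif_int,
                        coefficients = c(aspirin = -0.5)),
    roles = cohort_roles(x = c("age", "aspirin"), z = "age",
                         x_miss = c("age", "aspirin"),
                         z_miss = c("age", "aspirin"))
  )
}

# direct discrete-time survival log-likelihood: explicit loop over subjects
# and their at-risk cycles (independent of the person-period glm route)
direct_conception_loglik <- function(cohort, g, gamma) {
  dat <- tibble::as_tibble(cohort)
  covs <- names(gamma)
  ll <- 0
  for (i in seq_len(nrow(dat))) {
    x <- as.numeric(dat[i, covs])
    for (t in seq_len(dat$U[i])) {
      h <- plogis(g[t] + sum(gamma * x))
      d_it <- as.numeric(dat$conceived[i] == 1 && t == dat$U[i])
      ll <- ll + d_it * log(h) + (1 - d_it) * log(1 - h)
    }
  }
  ll
}

# hand-written multinomial log-likelihood (fullterm reference)
direct_gestation_loglik <- function(dat, a_loss, a_preterm, covs) {
  X <- cbind(1, as.matrix(dat[covs]))
  e2 <- exp(drop(X %*% a_loss))
  e3 <- exp(drop(X %*% a_preterm))
  denom <- 1 + e2 + e3
  p <- cbind(loss = e2 / denom, preterm = e3 / denom, fullterm = 1 / denom)
  sum(log(p[cbind(seq_len(nrow(dat)), match(dat$outcome, colnames(p)))]))
}

# brute-force HUM: nested loops over every tuple, scoring each set with
# classify_set (independent of the vectorized estimator)
brute_force_hum <- function(mats, weights = NULL, pi_r = NULL) {
  n_k <- vapply(mats, nrow, integer(1))
  idx <- expand.grid(lapply(n_k, seq_len))
  num <- denom <- 0
  for (r in seq_len(nrow(idx))) {
    profs <- do.call(rbind, lapply(seq_along(mats), function(k) {
      mats[[k]][idx[r, k], ]
    }))
    cr <- classify_set(profs, weights = weights)$correct
    w <- if (is.null(pi_r)) 1 else
      prod(vapply(seq_along(mats), function(k) 1 / pi_r[[k]][idx[r, k]],
                  numeric(1)))
    num <- num + w * cr
    denom <- denom + w
  }
  num / denom
}

observed_class_for_test <- function(dat) {
  ifelse(dat$r1 == 1 & dat$conceived == 0, "nopreg",
         ifelse(dat$r1 == 1 & dat$r2 == 1 & dat$conceived == 1,
                dat$outcome, NA))
}

profile_cols_for_test <- function() {
  paste0("p_", c("nopreg", "loss", "preterm", "fullterm"))
}

# uniform draws on the K-simplex
runif_simplex <- function(n, K) {
  g <- matrix(stats::rexp(n * K), n, K)
  g / rowSums(g)
}
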