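#' Specify a synthetic cohort generator
#'
#' Defines the full generative model for a two-stage pregnancy-attempt
#' cohort with known truth: baseline covariate distributions, the
#' discrete-time conception hazard, the multinomial gestation model, a
#' per-cycle censoring hazard (independent of conception given covariates),
#' second-stage verification, and covariate missingness rates.
#'
#' Supported covariate distributions: `list("normal", mean, sd, min, max)`
#' (optional truncation bounds), `list("bernoulli", p, shift)` (optional
#' integer shift, e.g. 1 + Bernoulli for counts in \{1, 2\}),
#' `list("integer_uniform", min, max)`, and `list("poisson_trunc", lambda,
#' max)`.
#'
#' @param n Cohort size.
#' @param tau Conception window in cycles.
#' @param covariates Named list of distribution specs.
#' @param conception List with `baseline_logits` (tau-vector `g`) and named
#'   `coefficients` (`gamma`).
#' @param gestation List with named vectors `alpha_loss` and `alpha_preterm`
#'   (log-odds vs full-term, each including `(Intercept)`).
#' @param censoring List with `intercept` and optional named `coefficients`:
#'   the per-cycle logit hazard of dropout before conception.
#' @param verification List with `intercept` and optional named
#'   `coefficients`: logit of P(R2 = 1 | z', Y1 = 1) for conceivers.
#' @param covariate_missing Named vector of MCAR missingness rates for
#'   observed covariate columns.
#' @param roles A [cohort_roles()] object for the emitted cohort.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n, tau, covariates, conception, gestation, censoring,
                       verification, covariate_missing = numeric(0), roles) {
  p <- structure(
    list(n = as.integer(n), tau = as.integer(tau), covariates = covariates,
         conception = conception, gestation = gestation,
         censoring = censoring, verification = verification,
         covariate_missing = covariate_missing, roles = roles),
    class = "sim_params"
  )
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(p$n >= 1, p$tau >= 1)
  if (length(p$conception$baseline_logits) != p$tau) {
    abort("conception baseline_logits must have length tau")
  }
  stopifnot(identical(names(p$gestation$alpha_loss),
                      names(p$gestation$alpha_preterm)))
  covs <- names(p$covariates)
  used <- c(names(p$conception$coefficients),
            setdiff(names(p$gestation$alpha_loss), "(Intercept)"),
            names(p$censoring$coefficients),
            names(p$verification$coefficients),
            names(p$covariate_missing),
            unlist(unclass(p$roles)))
  extra <- setdiff(used, covs)
  if (length(extra) > 0) {
    abort(paste0("parameters reference undeclared covariates: ",
                 paste(unique(extra), collapse = ", ")))
  }
  if (any(p$covariate_missing < 0 | p$covariate_missing >= 1)) {
    abort("covariate missingness rates must lie in [0, 1)")
  }
  for (nm in covs) {
    spec <- p$covariates[[nm]]
    ok <- spec[[1]] %in% c("normal", "bernoulli", "integer_uniform",
                           "poisson_trunc")
    if (!ok) abort(paste0("unknown distribution for covariate ", nm))
    if (spec[[1]] == "bernoulli" && (spec[[2]] <= 0 || spec[[2]] >= 1)) {
      abort(paste0("bernoulli p for ", nm, " must lie in (0, 1)"))
    }
  }
  invisible(p)
}

draw_covariate <- function(spec, n) {
  switch(
    spec[[1]],
    normal = {
      x <- rnorm(n, spec[[2]], spec[[3]])
      if (length(spec) >= 5) x <- pmin(pmax(x, spec[[4]]), spec[[5]])
      round(x, 1)
    },
    bernoulli = rbinom(n, 1, spec[[2]]) + (if (length(spec) >= 3) spec[[3]] else 0),
    integer_uniform = sample(seq(spec[[2]], spec[[3]]), n, replace = TRUE),
    poisson_trunc = pmin(rpois(n, spec[[2]]), spec[[3]])
  )
}

# draw a discrete event cycle from per-cycle hazards (n x tau matrix);
# returns tau + 1 when no event occurs within the window
draw_discrete_time <- function(H) {
  n <- nrow(H)
  tau <- ncol(H)
  t_event <- rep(tau + 1L, n)
  alive <- rep(TRUE, n)
  for (t in seq_len(tau)) {
    hit <- alive & (runif(n) < H[, t])
    t_event[hit] <- t
    alive <- alive & !hit
  }
  t_event
}

#' Simulate a two-stage pregnancy-attempt cohort with known truth
#'
#' For each subject: draw covariates; draw the conception cycle `T1` from
#' the discrete hazard `expit(g_t + gamma'x)` (with `tau + 1` meaning no
#' conception within the window); draw a censoring cycle `C` from the
#' per-cycle censoring hazard, independent of `T1` given covariates; form
#' the observed follow-up `U = min(T1, C, tau)` and conception indicator;
#' draw the gestation outcome from the alpha-softmax for every subject with
#' `T1 <= tau` (kept as latent truth even when unobserved); draw
#' second-stage verification for conceivers; and finally mask observed
#' fields accordingly and apply MCAR covariate missingness. Latent truth is
#' emitted in `true_*` columns so observed-data code cannot consume it
#' accidentally.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the draw is reproducible.
#' @return A `preg_cohort` with latent columns `true_t1` (`tau + 1` = none),
#'   `true_censor`, `true_outcome`, `true_class`.
#' @export
simulate_cohort <- function(params, seed = NULL) {
  validate_sim_params(params)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  tau <- params$tau
  covs <- purrr::map_dfc(params$covariates, draw_covariate, n = n)

  cm <- new_conception_model(params$conception$baseline_logits,
                             params$conception$coefficients, tau)
  t1 <- draw_discrete_time(hazard_matrix(cm, covs))

  cens_lp <- linear_predictor(covs, params$censoring$coefficients %||% numeric(0),
                              params$censoring$intercept)
  Hc <- matrix(expit(cens_lp), n, tau)
  cens <- draw_discrete_time(Hc)

  gm <- new_gestation_model(params$gestation$alpha_loss,
                            params$gestation$alpha_preterm)
  pr <- conditional_probs(gm, covs)
  true_outcome <- rep(NA_character_, n)
  has_preg <- t1 <= tau
  if (any(has_preg)) {
    u <- runif(n)
    true_outcome[has_preg] <- ifelse(
      u[has_preg] < pr$loss[has_preg], "loss",
      ifelse(u[has_preg] < (pr$loss + pr$preterm)[has_preg], "preterm",
             "fullterm")
    )
  }
  true_class <- ifelse(has_preg, true_outcome, "nopreg")

  conceived <- as.integer(t1 <= pmin(cens, tau))
  censored_pre <- cens < pmin(t1, tau)   # lost before conception and before tau
  U <- ifelse(conceived == 1, t1, ifelse(censored_pre, cens, tau))
  r1 <- as.integer(!censored_pre)

  ver_lp <- linear_predictor(covs, params$verification$coefficients %||% numeric(0),
                             params$verification$intercept)
  r2 <- integer(n)
  r2[r1 == 1 & conceived == 0] <- 1L
  is_conc <- r1 == 1 & conceived == 1
  r2[is_conc] <- rbinom(sum(is_conc), 1, expit(ver_lp[is_conc]))

  outcome <- ifelse(is_conc & r2 == 1, true_outcome, NA_character_)

  obs_covs <- covs
  for (nm in names(params$covariate_missing)) {
    rate <- params$covariate_missing[[nm]]
    if (rate > 0) {
      obs_covs[[nm]][runif(n) < rate] <- NA
    }
  }

  dat <- dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("s%05d", seq_len(n)),
      U = as.integer(U), conceived = conceived,
      r1 = r1, r2 = r2, outcome = outcome
    ),
    obs_covs,
    tibble::tibble(
      true_t1 = as.integer(t1),
      true_censor = as.integer(cens),
      true_outcome = true_outcome,
      true_class = true_class
    )
  )
  preg_cohort(dat, tau = tau, roles = params$roles)
}

#' Default trial-like simulation parameters
#'
#' A fixed, versioned parameter set emulating a preconception cohort of
#' women followed for up to six menstrual cycles, in the mold of the EAGeR
#' (Effects of Aspirin in Gestation and Reproduction) trial population:
#' continuous age and BMI, several 0/1 covariates, 1-2 previous pregnancy
#' losses, a declining per-cycle conception hazard, light censoring before
#' conception, near-complete second-stage verification, and low covariate
#' missingness. The conception and gestation coefficients are the package's
#' reference coefficient set (see [reference_models()]), so simulate-fit
#' cycles can check recovery of a realistic truth.
#'
#' @param n Cohort size (default 1000, the scale of the motivating trial).
#' @return A `sim_params` object.
#' @export
eager_like_params <- function(n = 1000) {
  ref <- reference_models()
  sim_params(
    n = n, tau = 6L,
    covariates = list(
      cycles_trying = list("poisson_trunc", 2, 11),
      aspirin = list("bernoulli", 0.5),
      age = list("normal", 28.7, 4.6, 18, 40),
      losses = list("bernoulli", 0.33, 1),
      white = list("bernoulli", 0.95),
      college = list("bernoulli", 0.5),
      bmi = list("normal", 26.3, 6.5, 15, 45),
      parous = list("bernoulli", 0.47),
      hypertension = list("bernoulli", 0.06),
      smoker = list("bernoulli", 0.1)
    ),
    conception = list(
      baseline_logits = ref$conception$baseline_logits,
      coefficients = ref$conception$coefficients
    ),
    gestation = list(
      alpha_loss = ref$gestation$alpha_loss,
      alpha_preterm = ref$gestation$alpha_preterm
    ),
    censoring = list(intercept = qlogis(0.035)),
    verification = list(
      intercept = 3.3,
      coefficients = c(white = 0.773, college = 0.474, bmi = -0.024,
                       parous = 0.366, smoker = -0.973)
    ),
    covariate_missing = c(bmi = 0.014, hypertension = 0.005,
                          smoker = 0.007, college = 0.007),
    roles = cohort_roles(
      x = c("cycles_trying", "aspirin", "age", "losses", "white", "college",
            "bmi", "parous"),
      z = c("age", "losses", "white", "hypertension"),
      x_miss = c("white", "college", "bmi", "parous", "smoker"),
      z_miss = c("white", "college", "bmi", "parous", "smoker")
    )
  )
}
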