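#' Fit the two-stage verification (missingness) models
#'
#' Under sequential missingness at random, first-stage verification depends
#' on baseline covariates only, `P(R1 = 1 | x')`, and second-stage
#' verification depends on baseline covariates and the first-stage outcome,
#' `P(R2 = 1 | z', R1 = 1, Y1)`. The `product` form fits both stage models
#' plus the selection model `P(Y1 = 1 | x, R1 = 1)` (needed for
#' complete-case weights); the `single` form fits one logistic model for the
#' probability of full verification, `P(R = 1 | w)`, a pragmatic
#' simplification often adequate when second-stage missingness is light.
#'
#' @param cohort A `preg_cohort`.
#' @param form `"product"` (default) or `"single"`.
#' @return A `missingness_fit` with components `stage1`, `stage2`,
#'   `selection` (product form) or `single`.
#' @export
fit_missingness <- function(cohort, form = c("product", "single")) {
  form <- match.arg(form)
  roles <- cohort_roles_of(cohort)
  dat <- tibble::as_tibble(cohort)
  out <- list(form = form, roles = roles)
  if (form == "single") {
    dat$.r <- as.integer(dat$r1 == 1 & dat$r2 == 1)
    covs <- unique(c(roles$x, roles$z, roles$x_miss, roles$z_miss))
    if (length(unique(dat$.r)) < 2) abort("no missingness variation for R")
    out$single <- quiet_binomial_glm(
      stats::reformulate(covs, response = ".r"), binomial(), data = dat
    )
  } else {
    if (length(unique(dat$r1)) < 2) {
      abort("no missingness variation at stage 1 (R1 constant)")
    }
    out$stage1 <- quiet_binomial_glm(
      stats::reformulate(roles$x_miss, response = "r1"), binomial(), data = dat
    )
    d1 <- dat[dat$r1 == 1, , drop = FALSE]
    if (length(unique(d1$r2)) < 2) {
      abort("no missingness variation at stage 2 (R2 constant given R1 = 1)")
    }
    out$stage2 <- quiet_binomial_glm(
      stats::reformulate(c(roles$z_miss, "conceived"), response = "r2"),
      binomial(), data = d1
    )
    out$selection <- quiet_binomial_glm(
      stats::reformulate(roles$x, response = "conceived"), binomial(), data = d1
    )
  }
  structure(out, class = "missingness_fit")
}

#' @export
print.missingness_fit <- function(x, ...) {
  cat("Verification models (", x$form, " form)\n", sep = "")
  invisible(x)
}

#' @method tidy missingness_fit
#' @export
tidy.missingness_fit <- function(x, ...) {
  parts <- intersect(c("stage1", "stage2", "selection", "single"), names(x))
  purrr::map_dfr(parts, function(p) {
    cf <- coef(x[[p]])
    tibble::tibble(model = p, term = names(cf), estimate = unname(cf))
  })
}

#' Probability of full outcome verification
#'
#' `pi^R = P(R2 = 1 | z', R1 = 1, Y1) * P(R1 = 1 | x')` under the product
#' form, or the single-model probability `P(R = 1 | w)`. Used as the
#' inverse weight in the verification-bias-adjusted HUM.
#'
#' @param models A `missingness_fit`.
#' @param newdata Data frame with the required covariates (and `conceived`
#'   for the product form's second stage).
#' @param floor Probabilities below this floor are raised to it with a
#'   warning (near-zero verification probabilities destabilize the weights).
#' @return Numeric vector of probabilities in (0, 1].
#' @export
verification_prob <- function(models, newdata, floor = 1e-3) {
  p <- if (models$form == "single") {
    predict(models$single, newdata = newdata, type = "response")
  } else {
    predict(models$stage1, newdata = newdata, type = "response") *
      predict(models$stage2, newdata = newdata, type = "response")
  }
  p <- unname(p)
  # NA for records with missing model covariates; callers decide how to drop
  low <- !is.na(p) & p < floor
  if (any(low)) {
    warn(paste0(sum(low), " verification probabilities below ", floor,
                " truncated"))
    p[low] <- floor
  }
  p
}

#' Inverse-probability-of-complete-case weights for the gestation model
#'
#' A subject is a complete case for the gestation model when their
#' conception is observed, occurred, and its clinical result is recorded
#' (`r1 = 1`, `conceived = 1`, `r2 = 1`). The probability of that event
#' factorizes as
#' `pi^C = P(R2 = 1 | z', R1 = 1, Y1 = 1) P(Y1 = 1 | x, R1 = 1) P(R1 = 1 | x')`
#' and the complete cases are weighted by `1 / pi^C` when fitting the
#' gestation model. Weights are truncated at the stated percentiles of their
#' own distribution to guard against instability from near-zero
#' probabilities.
#'
#' @param models A product-form `missingness_fit`.
#' @param cohort A `preg_cohort`.
#' @param truncate Lower/upper percentile bounds for weight truncation
#'   (default 1st and 99th); `NULL` disables truncation.
#' @return Tibble with columns `id`, `pi_c`, `weight` for the complete cases.
#' @export
complete_case_weights <- function(models, cohort, truncate = c(0.01, 0.99)) {
  if (models$form != "product") {
    abort("complete-case weights require the product-form missingness models")
  }
  dat <- tibble::as_tibble(cohort)
  cc <- dat$r1 == 1 & dat$conceived == 1 & dat$r2 == 1
  if (!any(cc)) abort("no complete cases for the gestation model")
  dat <- dat[cc, , drop = FALSE]
  p1 <- predict(models$stage1, newdata = dat, type = "response")
  p2 <- predict(models$stage2, newdata = dat, type = "response")
  psel <- predict(models$selection, newdata = dat, type = "response")
  pi_c <- unname(p1 * p2 * psel)
  w <- 1 / pi_c
  if (!is.null(truncate)) {
    bounds <- quantile(w, truncate, names = FALSE)
    w <- pmin(pmax(w, bounds[1]), bounds[2])
  }
  tibble::tibble(id = dat$id, pi_c = pi_c, weight = w)
}

#' Impute conception cycles for subjects censored before conception
#'
#' For a subject censored at cycle `u < tau`, the unobserved conception
#' cycle is drawn from the conditional distribution of `T1` over
#' `{u+1, ..., tau, tau+1}` given `T1 > u` implied by a discrete-time hazard
#' model fit on the auxiliary covariates, where the mass at `tau + 1` is the
#' probability of no conception within the window.
#'
#' @param cohort A `preg_cohort`; only rows with `r1 = 0` are imputed.
#' @param hazard_model A `conception_fit` on auxiliary covariates.
#' @param seed Optional integer seed.
#' @return Tibble with columns `id`, `t1` where `t1 = tau + 1` encodes no
#'   conception within the window.
#' @export
impute_conception_time <- function(cohort, hazard_model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dat <- tibble::as_tibble(cohort)
  dat <- dat[dat$r1 == 0, , drop = FALSE]
  tau <- hazard_model$tau
  if (nrow(dat) == 0) {
    return(tibble::tibble(id = dat$id, t1 = integer(0)))
  }
  if (any(dat$U >= tau)) {
    abort("r1 = 0 with U >= tau is contradictory (status would be known)")
  }
  H <- hazard_matrix(hazard_model, dat)
  t1 <- vapply(seq_len(nrow(dat)), function(i) {
    u <- dat$U[i]
    h <- H[i, (u + 1):tau]
    surv <- cumprod(1 - h)
    mass <- c(h * c(1, head(surv, -1)), surv[length(surv)])
    sample((u + 1):(tau + 1), 1L, prob = mass)
  }, integer(1))
  tibble::tibble(id = dat$id, t1 = t1)
}

# light chained-equations imputer for baseline covariates.
# vars: columns to impute; predictors: the other covariate columns.
impute_covariates <- function(data, vars, predictors, n_iter = 10) {
  obs <- lapply(vars, function(v) !is.na(data[[v]]))
  names(obs) <- vars
  # initialize by resampling observed values
  for (v in vars) {
    miss <- !obs[[v]]
    data[[v]][miss] <- sample(data[[v]][obs[[v]]], sum(miss), replace = TRUE)
  }
  var_type <- function(v) {
    x <- data[[v]][obs[[v]]]
    if (is.numeric(x) && all(x %in% c(0, 1))) "binary"
    else if (is.numeric(x) && length(unique(x)) > 8) "continuous"
    else if (is.numeric(x)) "integer"
    else "categorical"
  }
  types <- vapply(vars, var_type, character(1))
  for (iter in seq_len(n_iter)) {
    for (v in vars) {
      miss <- !obs[[v]]
      if (!any(miss)) next
      preds <- setdiff(predictors, v)
      if (types[[v]] %in% c("binary", "continuous")) {
        # numeric covariates throughout: work on model matrices directly
        X <- cbind(1, as.matrix(data[preds]))
        Xo <- X[obs[[v]], , drop = FALSE]
        Xm <- X[miss, , drop = FALSE]
        y <- data[[v]][obs[[v]]]
        data[[v]][miss] <- if (types[[v]] == "binary") {
          f <- suppressWarnings(
            glm.fit(Xo, y, family = binomial())
          )
          rbinom(nrow(Xm), 1, plogis(drop(Xm %*% f$coefficients)))
        } else {
          f <- stats::lm.fit(Xo, y)
          sigma <- sqrt(sum(f$residuals^2) / (nrow(Xo) - f$rank))
          drop(Xm %*% f$coefficients) + rnorm(nrow(Xm), 0, sigma)
        }
      } else {
        fit_rows <- data[obs[[v]], , drop = FALSE]
        new_rows <- data[miss, , drop = FALSE]
        fit_rows$.v <- factor(fit_rows[[v]])
        f <- nnet::multinom(stats::reformulate(preds, ".v"),
                            data = fit_rows, trace = FALSE)
        pr <- predict(f, new_rows, type = "probs")
        if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
        lev <- levels(fit_rows$.v)
        drawn <- apply(pr, 1, function(p) sample(lev, 1L, prob = p))
        data[[v]][miss] <- if (types[[v]] == "integer") as.numeric(drawn)
          else drawn
      }
    }
  }
  data
}

#' Sequential multiple imputation of a two-stage cohort
#'
#' Produces `M` completed cohorts. Within each replicate: (i) missing
#' baseline covariates are imputed by chained equations; (ii) conception
#' cycles are imputed for subjects censored before conception, from the
#' conditional distribution implied by a discrete-time hazard model on the
#' auxiliary covariates, and the conception indicator is set to
#' `I(T1 <= tau)`; (iii) gestation outcomes are imputed for subjects with an
#' observed or imputed conception but unrecorded result, from a multinomial
#' model on the gestation covariates plus auxiliaries fit to the observed
#' outcomes. Replicates use independent sub-seeds derived from the master
#' seed, so results do not depend on `M` or evaluation order.
#'
#' @param cohort A `preg_cohort`.
#' @param M Number of imputations (>= 2; default 10).
#' @param seed Master seed.
#' @param n_iter Chained-equations sweeps for covariate imputation.
#' @return An `imputed_cohorts` object: list of `M` completed `preg_cohort`s
#'   plus diagnostics.
#' @export
sequential_impute <- function(cohort, M = 10, seed = NULL, n_iter = 10) {
  if (M < 2) abort("M must be at least 2")
  roles <- cohort_roles_of(cohort)
  tau <- cohort_tau(cohort)
  dat <- tibble::as_tibble(cohort)
  all_covs <- unique(unlist(unclass(roles)))
  cov_missing <- all_covs[vapply(all_covs, function(v) anyNA(dat[[v]]), logical(1))]
  aux <- roles$aux
  out_covs <- unique(c(roles$z, aux))
  seeds <- derive_seeds(seed, M)

  completed <- vector("list", M)
  diag_rows <- vector("list", M)
  for (m in seq_len(M)) {
    set.seed(seeds[m])
    comp <- dat
    if (length(cov_missing) > 0) {
      comp <- impute_covariates(comp, cov_missing, all_covs, n_iter = n_iter)
    }
    n_t1 <- 0L
    if (any(comp$r1 == 0)) {
      cm_aux <- fit_conception(comp, covariates = aux, tau = tau)
      draws <- impute_conception_time(
        preg_like(comp, tau, roles), cm_aux
      )
      idx <- match(draws$id, comp$id)
      conc <- draws$t1 <= tau
      comp$conceived[idx] <- as.integer(conc)
      comp$U[idx] <- ifelse(conc, draws$t1, tau)
      comp$r1[idx] <- 1L
      comp$r2[idx] <- ifelse(conc, 0L, 1L)
      n_t1 <- nrow(draws)
    }
    need_y2 <- comp$conceived == 1 & is.na(comp$outcome)
    n_y2 <- sum(need_y2)
    if (n_y2 > 0) {
      gm_aux <- fit_gestation(comp, covariates = out_covs)
      pr <- conditional_probs(gm_aux, comp[need_y2, , drop = FALSE])
      comp$outcome[need_y2] <- vapply(seq_len(n_y2), function(i) {
        sample(c("loss", "preterm", "fullterm"), 1L,
               prob = c(pr$loss[i], pr$preterm[i], pr$fullterm[i]))
      }, character(1))
    }
    comp$r1 <- 1L
    comp$r2 <- 1L
    completed[[m]] <- preg_like(comp, tau, roles)
    diag_rows[[m]] <- tibble::tibble(
      m = m, seed = seeds[m], n_covariates = length(cov_missing),
      n_t1_imputed = n_t1, n_y2_imputed = n_y2
    )
  }
  structure(
    list(cohorts = completed, M = M, seed = seed,
         diagnostics = dplyr::bind_rows(diag_rows)),
    class = "imputed_cohorts"
  )
}

# reattach cohort attributes without re-running full validation
preg_like <- function(data, tau, roles) {
  structure(
    tibble::as_tibble(data),
    tau = as.integer(tau), roles = roles,
    class = c("preg_cohort", class(tibble::tibble()))
  )
}

#' @export
print.imputed_cohorts <- function(x, ...) {
  cat("# imputed_cohorts: M =", x$M, "completed cohorts of",
      nrow(x$cohorts[[1]]), "subjects\n")
  print(x$diagnostics)
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled point estimate is the arithmetic mean of the `M` per-imputation
#' estimates. When per-imputation variances are supplied, the total variance
#' is the mean within-imputation variance plus `(1 + 1/M)` times the
#' between-imputation variance.
#'
#' @param estimates List of `M` conformable named numeric vectors, or an
#'   `M x p` matrix.
#' @param variances Optional list/matrix of per-imputation variances
#'   (diagonal form), conformable with `estimates`.
#' @return List with `estimate`, `between`, and (when variances are given)
#'   `within` and `total`.
#' @export
rubin_pool <- function(estimates, variances = NULL) {
  est <- if (is.list(estimates)) do.call(rbind, estimates) else as.matrix(estimates)
  M <- nrow(est)
  if (M < 2) abort("need at least 2 imputations to pool")
  point <- colMeans(est)
  between <- apply(est, 2, var)
  out <- list(estimate = point, between = between, M = M)
  if (!is.null(variances)) {
    v <- if (is.list(variances)) do.call(rbind, variances) else as.matrix(variances)
    stopifnot(dim(v) == dim(est))
    within <- colMeans(v)
    out$within <- within
    out$total <- within + (1 + 1 / M) * between
  }
  out
}
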