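#' Fit the discrete-time conception hazard model
#'
#' Models the per-cycle probability of clinically-recognized pregnancy on the
#' logit scale, `logit P(T1 = t | T1 >= t, x) = g_t + gamma' x`, for cycles
#' `t = 1..tau`. The fit maximizes the discrete-time survival likelihood by
#' logistic regression on the person-period expansion (one binary row per
#' at-risk cycle) under working independence; censored subjects contribute
#' their observed at-risk cycles only. The per-cycle intercepts are
#' parameterized as a reference intercept at `t = 1` plus offsets for
#' `t = 2..tau`.
#'
#' @param data A `preg_cohort` (expanded internally over the `x` role) or a
#'   person-period tibble from [expand_person_period()].
#' @param weights Optional positive per-subject weights, either a numeric
#'   vector aligned with the cohort rows or a data frame with columns `id`
#'   and `weight`; each subject's person-period rows share their weight.
#' @param covariates Covariate columns; defaults to the cohort's `x` role.
#' @param tau Conception window; inferred from the cohort attribute or the
#'   largest observed cycle when omitted.
#' @return A `conception_fit` holding the per-cycle baseline logits `g`,
#'   covariate coefficients `gamma`, and fit metadata. Supports
#'   [conception_hazard()], [cumulative_conception()], `tidy()`, `glance()`.
#' @export
fit_conception <- function(data, weights = NULL, covariates = NULL, tau = NULL) {
  if (inherits(data, "preg_cohort")) {
    covariates <- covariates %||% cohort_roles_of(data)$x
    tau <- tau %||% cohort_tau(data)
    ppt <- expand_person_period(data, covariates = covariates)
  } else if (all(c("cycle", "event") %in% names(data))) {
    stopifnot(all(c("id", "cycle", "event") %in% names(data)))
    covariates <- covariates %||% setdiff(names(data), c("id", "cycle", "event"))
    tau <- tau %||% max(data$cycle)
    ppt <- tibble::as_tibble(data)
  } else {
    # subject-level tibble carrying id/U/conceived plus covariates
    stopifnot(all(c("id", "U", "conceived") %in% names(data)))
    if (is.null(covariates)) abort("covariates must be given for plain tables")
    tau <- tau %||% max(data$U)
    ppt <- expand_person_period(tibble::as_tibble(data), covariates = covariates)
  }
  if (nrow(ppt) == 0) abort("empty person-period table")
  if (sum(ppt$event) == 0) {
    abort("no conception events; the hazard model is not estimable")
  }
  if (anyNA(ppt[covariates])) {
    abort("missing covariate values in the x role; impute or weight first")
  }

  w <- person_period_weights(ppt, weights)
  ppt$cycle_f <- factor(ppt$cycle, levels = seq_len(tau))
  form <- if (length(covariates) > 0) {
    stats::reformulate(c("cycle_f", covariates), response = "event")
  } else {
    stats::reformulate("cycle_f", response = "event")
  }
  fit <- quiet_binomial_glm(form, family = binomial(), data = ppt, weights = w)
  if (!fit$converged) {
    abort("conception hazard fit did not converge")
  }
  cf <- coef(fit)
  # cycles with no rows are inestimable; carry the last estimable offset
  missing_cycles <- which(tabulate(ppt$cycle, nbins = tau) == 0)
  if (length(missing_cycles) > 0) {
    warn(paste0("no person-period rows for cycle(s) ",
                paste(missing_cycles, collapse = ", "),
                "; baseline logit carried from the last estimable cycle"))
  }
  offsets <- if (tau > 1) cf[paste0("cycle_f", 2:tau)] else numeric(0)
  g <- cf[["(Intercept)"]] + c(0, offsets)
  for (t in seq_along(g)[-1]) if (is.na(g[t])) g[t] <- g[t - 1]
  gamma <- cf[covariates]
  if (anyNA(gamma)) {
    abort(paste0("inestimable (aliased) coefficients: ",
                 paste(covariates[is.na(gamma)], collapse = ", ")))
  }
  if (any(abs(cf) > 15)) {
    warn("very large coefficients; possible complete separation")
  }

  new_conception_model(
    baseline_logits = unname(g),
    coefficients = setNames(as.numeric(gamma), covariates),
    tau = tau,
    fit = fit,
    n_subjects = dplyr::n_distinct(ppt$id),
    n_periods = nrow(ppt)
  )
}

person_period_weights <- function(ppt, weights) {
  if (is.null(weights)) {
    return(rep(1, nrow(ppt)))
  }
  if (is.data.frame(weights)) {
    w <- weights$weight[match(ppt$id, weights$id)]
  } else {
    ids <- unique(ppt$id)
    stopifnot(length(weights) == length(ids))
    w <- weights[match(ppt$id, ids)]
  }
  if (anyNA(w) || any(w <= 0)) abort("weights must be positive for every subject")
  w
}

#' Construct a conception model from known coefficients
#'
#' Used for published coefficient sets, simulation truths, and pooled
#' (Rubin-combined) estimates.
#'
#' @param baseline_logits Numeric tau-vector of per-cycle logit intercepts
#'   `g_1..g_tau` (cumulative scale, not offsets).
#' @param coefficients Named numeric vector `gamma` over covariate columns.
#' @param tau Conception window; defaults to `length(baseline_logits)`.
#' @param fit,n_subjects,n_periods Optional fit metadata.
#' @return A `conception_fit`.
#' @export
new_conception_model <- function(baseline_logits, coefficients,
                                 tau = length(baseline_logits),
                                 fit = NULL, n_subjects = NA_integer_,
                                 n_periods = NA_integer_) {
  stopifnot(length(baseline_logits) == tau, tau >= 1)
  structure(
    list(
      baseline_logits = as.numeric(baseline_logits),
      coefficients = coefficients,
      tau = as.integer(tau),
      covariates = names(coefficients),
      fit = fit,
      n_subjects = n_subjects,
      n_periods = n_periods,
      log_lik = if (!is.null(fit)) as.numeric(logLik(fit)) else NA_real_,
      aic = if (!is.null(fit)) AIC(fit) else NA_real_,
      converged = if (!is.null(fit)) fit$converged else NA
    ),
    class = "conception_fit"
  )
}

#' @export
print.conception_fit <- function(x, ...) {
  cat("Discrete-time conception hazard model (tau = ", x$tau, ")\n", sep = "")
  cat("Baseline logits g_t:", paste(round(x$baseline_logits, 3), collapse = " "), "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Per-cycle conception hazard
#'
#' `expit(g_t + gamma' x)` for each subject row at cycle `t`.
#'
#' @param model A `conception_fit`.
#' @param newdata Data frame with the model's covariate columns.
#' @param t Cycle, `1 <= t <= tau`.
#' @return Numeric vector of hazards in (0, 1).
#' @export
conception_hazard <- function(model, newdata, t) {
  stopifnot(length(t) == 1)
  if (t < 1 || t > model$tau) {
    abort(paste0("cycle t must lie in 1..", model$tau))
  }
  expit(model$baseline_logits[t] + linear_predictor(newdata, model$coefficients))
}

# n x tau matrix of per-cycle hazards
hazard_matrix <- function(model, newdata) {
  lp <- linear_predictor(newdata, model$coefficients)
  outer(lp, model$baseline_logits, function(a, g) expit(g + a))
}

#' Probability of conception within the window
#'
#' `P(T1 <= tau | x)`, recovered from the fitted hazards as the sum of the
#' per-cycle conception masses `h_t prod_{j<t}(1 - h_j)`, equivalently one
#' minus the tau-cycle survival product.
#'
#' @inheritParams conception_hazard
#' @return Numeric vector of probabilities.
#' @export
cumulative_conception <- function(model, newdata) {
  h <- hazard_matrix(model, newdata)
  1 - apply(1 - h, 1, prod)
}

#' Per-cycle conception mass
#'
#' The probability that conception occurs at exactly cycle `t`:
#' `h_t prod_{j<t}(1 - h_j)`. Rows sum to [cumulative_conception()].
#'
#' @inheritParams conception_hazard
#' @return Tibble with columns `mass_1..mass_tau`.
#' @export
conception_mass <- function(model, newdata) {
  h <- hazard_matrix(model, newdata)
  surv <- cbind(1, t(apply(1 - h, 1, cumprod)))[, seq_len(model$tau), drop = FALSE]
  mass <- h * surv
  colnames(mass) <- paste0("mass_", seq_len(model$tau))
  tibble::as_tibble(mass)
}

#' @method tidy conception_fit
#' @export
tidy.conception_fit <- function(x, ...) {
  if (!is.null(x$fit)) {
    s <- summary(x$fit)$coefficients
    term <- rownames(s)
    term <- sub("^cycle_f(\\d+)$", "I(t=\\1)", term)
    return(tibble::tibble(
      term = term, estimate = s[, 1], std.error = s[, 2],
      statistic = s[, 3], p.value = s[, 4]
    ))
  }
  tibble::tibble(
    term = c("(Intercept)",
             if (x$tau > 1) paste0("I(t=", 2:x$tau, ")"),
             names(x$coefficients)),
    estimate = c(x$baseline_logits[1],
                 if (x$tau > 1) x$baseline_logits[-1] - x$baseline_logits[1],
                 unname(x$coefficients)),
    std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
  )
}

#' @method glance conception_fit
#' @export
glance.conception_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_periods = x$n_periods, tau = x$tau,
    logLik = x$log_lik, AIC = x$aic, converged = x$converged
  )
}
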