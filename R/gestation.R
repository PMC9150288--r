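#' Fit the multinomial gestation-outcome model
#'
#' Among subjects with a clinically-recognized pregnancy, the final result
#' (clinical pregnancy loss, preterm birth, full-term birth) follows a
#' multinomial logit with full-term birth as the reference class:
#' `log(P(loss)/P(fullterm)) = alpha_loss' z` and
#' `log(P(preterm)/P(fullterm)) = alpha_preterm' z`. The model is agnostic to
#' the timing of conception within the window. Optional per-subject weights
#' multiply the log-likelihood contributions (the inverse-probability-
#' weighting path for missing outcomes).
#'
#' @param cohort A `preg_cohort`; the fit uses subjects with `conceived = 1`
#'   and a defined `outcome`.
#' @param weights Optional positive weights: numeric vector aligned with the
#'   used subjects, or data frame with columns `id`, `weight`.
#' @param covariates Covariate columns; defaults to the cohort's `z` role.
#' @return A `gestation_fit` with coefficient vectors `alpha_loss` and
#'   `alpha_preterm` (each including `(Intercept)`), supporting
#'   [conditional_probs()], `tidy()`, `glance()`.
#' @export
fit_gestation <- function(cohort, weights = NULL, covariates = NULL) {
  covariates <- covariates %||%
    (if (inherits(cohort, "preg_cohort")) cohort_roles_of(cohort)$z else
       setdiff(names(cohort), c("id", "U", "conceived", "r1", "r2", "outcome")))
  dat <- dplyr::filter(tibble::as_tibble(cohort),
                       .data$conceived == 1, !is.na(.data$outcome))
  if (nrow(dat) == 0) abort("no subjects with an observed gestation outcome")
  present <- gestation_classes %in% dat$outcome
  if (!all(present)) {
    abort(paste0("empty gestation outcome class(es): ",
                 paste(gestation_classes[!present], collapse = ", ")))
  }
  if (anyNA(dat[covariates])) {
    abort("missing covariate values in the z role; impute or weight first")
  }
  w <- if (is.null(weights)) {
    rep(1, nrow(dat))
  } else if (is.data.frame(weights)) {
    weights$weight[match(dat$id, weights$id)]
  } else {
    stopifnot(length(weights) == nrow(dat))
    weights
  }
  if (anyNA(w) || any(w <= 0)) abort("weights must be positive for every subject")

  # first level = reference class (full-term)
  dat$.y <- factor(dat$outcome, levels = c("fullterm", "loss", "preterm"))
  form <- if (length(covariates) > 0) {
    stats::reformulate(covariates, response = ".y")
  } else {
    .y ~ 1
  }
  dat$.w <- w
  fit <- nnet::multinom(form, data = dat, weights = .w, trace = FALSE,
                        maxit = 500, reltol = 1e-12)
  if (fit$convergence != 0) abort("gestation model did not converge")
  cf <- coef(fit)
  if (any(abs(cf) > 15)) warn("very large coefficients; possible separation")

  new_gestation_model(
    alpha_loss = cf["loss", ],
    alpha_preterm = cf["preterm", ],
    fit = fit, n = nrow(dat)
  )
}

#' Construct a gestation model from known coefficients
#'
#' @param alpha_loss,alpha_preterm Named numeric vectors of log-odds
#'   coefficients versus the full-term reference class; include an
#'   `(Intercept)` entry, remaining names must be covariate columns.
#' @param fit,n Optional fit metadata.
#' @return A `gestation_fit`.
#' @export
new_gestation_model <- function(alpha_loss, alpha_preterm, fit = NULL, n = NA_integer_) {
  stopifnot(identical(names(alpha_loss), names(alpha_preterm)))
  structure(
    list(
      alpha_loss = alpha_loss,
      alpha_preterm = alpha_preterm,
      covariates = setdiff(names(alpha_loss), "(Intercept)"),
      reference = "fullterm",
      fit = fit,
      n = n,
      log_lik = if (!is.null(fit)) as.numeric(logLik(fit)) else NA_real_,
      aic = if (!is.null(fit)) AIC(fit) else NA_real_,
      converged = if (!is.null(fit)) fit$convergence == 0 else NA
    ),
    class = "gestation_fit"
  )
}

#' @export
print.gestation_fit <- function(x, ...) {
  cat("Multinomial gestation-outcome model (reference: full-term)\n")
  cat("log(loss/fullterm):\n"); print(round(x$alpha_loss, 4))
  cat("log(preterm/fullterm):\n"); print(round(x$alpha_preterm, 4))
  invisible(x)
}

alpha_lp <- function(model, newdata, alpha) {
  int <- if ("(Intercept)" %in% names(alpha)) alpha[["(Intercept)"]] else 0
  linear_predictor(newdata, alpha[setdiff(names(alpha), "(Intercept)")], int)
}

#' Conditional gestation-outcome probabilities
#'
#' Softmax inversion of the fitted log-odds: `P(fullterm | conceived) =
#' 1 / (1 + exp(a2'z) + exp(a3'z))`, with the loss and preterm probabilities
#' scaled by the corresponding exponentiated log-odds. The three
#' probabilities are positive and sum to one.
#'
#' @param model A `gestation_fit`.
#' @param newdata Data frame with the model's covariate columns.
#' @return Tibble with columns `loss`, `preterm`, `fullterm`.
#' @export
conditional_probs <- function(model, newdata) {
  e2 <- exp(alpha_lp(model, newdata, model$alpha_loss))
  e3 <- exp(alpha_lp(model, newdata, model$alpha_preterm))
  p4 <- 1 / (1 + e2 + e3)
  tibble::tibble(loss = p4 * e2, preterm = p4 * e3, fullterm = p4)
}

#' @method tidy gestation_fit
#' @export
tidy.gestation_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(y.level = "loss", term = names(x$alpha_loss),
                   estimate = unname(x$alpha_loss)),
    tibble::tibble(y.level = "preterm", term = names(x$alpha_preterm),
                   estimate = unname(x$alpha_preterm))
  )
}

#' @method glance gestation_fit
#' @export
glance.gestation_fit <- function(x, ...) {
  tibble::tibble(n = x$n, logLik = x$log_lik, AIC = x$aic,
                 converged = x$converged)
}
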