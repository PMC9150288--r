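#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats glm glm.fit binomial coef predict logLik AIC plogis qlogis
#'   rnorm rbinom rpois runif quantile sd var complete.cases model.matrix
#'   lm rmultinom setNames qnorm
#' @importFrom utils head
NULL

expit <- function(x) stats::plogis(x)

# linear predictor for a named coefficient vector over columns of `data`;
# coefficient names must all be columns (numeric, 0/1-coded categoricals)
linear_predictor <- function(data, coefficients, intercept = 0) {
  if (length(coefficients) == 0L) {
    return(rep(intercept, nrow(data)))
  }
  missing_cols <- setdiff(names(coefficients), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "covariates not found in data: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  mat <- as.matrix(data[names(coefficients)])
  if (!is.numeric(mat)) {
    abort("covariates must be numeric (code categoricals as 0/1 or integers)")
  }
  drop(mat %*% coefficients) + intercept
}

# all permutations of 1..n, as an (n!) x n integer matrix
permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# glm(binomial) emits a spurious warning for non-integer weighted outcomes;
# muffle only that one. Weights are bound into `data` so glm's
# standard-evaluation machinery can always find them.
quiet_binomial_glm <- function(formula, family = binomial(), data,
                               weights = NULL) {
  data$.wt <- if (is.null(weights)) rep(1, nrow(data)) else weights
  withCallingHandlers(
    glm(formula, family = family, data = data, weights = .wt),
    warning = function(w) {
      if (grepl("non-integer #successes", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}
utils::globalVariables(c(".wt", ".w", ".y"))

# derive independent sub-seeds below 2^31 from a master seed
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(sample.int(.Machine$integer.max - 1L, n))
  }
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
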