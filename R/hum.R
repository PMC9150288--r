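#' Forced-choice classification of one individual per class
#'
#' Given K individuals, one drawn from each of the K outcome classes, the
#' decision rule assigns the K class labels to the K individuals (each label
#' used exactly once) so as to minimize the weighted sum of Euclidean
#' distances from each risk profile to its assigned vertex of the
#' probability simplex. The set is scored correct only when the identity
#' assignment is the unique minimizer (within `tie_tolerance`); ties score
#' zero.
#'
#' @param profiles K x K matrix (or data frame); row k is the risk profile
#'   of the individual from class k, columns in canonical class order.
#' @param weights Nonnegative class weights omega (default equal).
#' @param tie_tolerance Margin below which competing assignments are treated
#'   as tied.
#' @return List with `assignment` (integer permutation) and `correct` (0/1).
#' @export
classify_set <- function(profiles, weights = NULL, tie_tolerance = 1e-9) {
  P <- as.matrix(profiles)
  K <- ncol(P)
  if (nrow(P) != K) abort("profiles must be one row per class (K x K)")
  weights <- weights %||% rep(1, K)
  if (length(weights) != K || any(weights < 0) || all(weights == 0)) {
    abort("weights must be K nonnegative values, not all zero")
  }
  D <- vertex_distances(P) * weights   # row k scaled by omega_k
  perms <- permutations(K)
  costs <- apply(perms, 1, function(p) sum(D[cbind(seq_len(K), p)]))
  best <- which.min(costs)
  id_row <- which(apply(perms, 1, function(p) all(p == seq_len(K))))
  others <- min(costs[-id_row])
  list(
    assignment = perms[best, ],
    correct = as.integer(costs[id_row] < others - tie_tolerance)
  )
}

# Euclidean distances from each profile row to each simplex vertex e_c
vertex_distances <- function(P) {
  K <- ncol(P)
  sq <- rowSums(P^2)
  # ||p - e_c||^2 = ||p||^2 - 2 p_c + 1
  sqrt(pmax(outer(sq, rep(1, K)) - 2 * P + 1, 0))
}

new_hum_estimate <- function(value, mode, n_per_class, weights,
                             mc_draws = NA_integer_, seed = NULL,
                             se = NA_real_, ci = NULL) {
  structure(
    list(value = value, mode = mode, n_per_class = n_per_class,
         weights = weights, mc_draws = mc_draws, seed = seed,
         se = se, ci = ci),
    class = "hum_estimate"
  )
}

#' @export
print.hum_estimate <- function(x, ...) {
  cat("HUM estimate:", signif(x$value, 4), "(", x$mode, "mode )\n")
  if (!is.na(x$se)) {
    cat("  bootstrap SE:", signif(x$se, 3),
        " 95% CI: [", signif(x$ci[1], 3), ",", signif(x$ci[2], 3), "]\n")
  }
  if (!is.null(x$optimism)) {
    cat("  initial:", signif(x$initial, 4),
        " mean optimism:", signif(x$optimism, 4),
        " corrected:", signif(x$corrected, 4), "\n")
  }
  invisible(x)
}

#' @method tidy hum_estimate
#' @export
tidy.hum_estimate <- function(x, ...) {
  tibble::tibble(
    estimate = x$value, mode = x$mode, mc_draws = x$mc_draws,
    se = x$se,
    conf.low = if (!is.null(x$ci)) x$ci[1] else NA_real_,
    conf.high = if (!is.null(x$ci)) x$ci[2] else NA_real_,
    corrected = x$corrected %||% NA_real_
  )
}

# split a profile table into per-class matrices following the level order of
# `class`; profile columns must follow the same class order
split_profiles <- function(profiles, class, cols = NULL) {
  cols <- cols %||% intersect(profile_cols, names(profiles))
  if (length(cols) == 0) abort("no profile columns found")
  cls_full <- if (is.factor(class)) class else
    factor(class, levels = if (length(cols) == 4) outcome_classes else unique(class))
  keep <- !is.na(cls_full)
  cls <- droplevels(cls_full[keep])
  if (nlevels(cls) != length(cols)) {
    abort(paste0("need one class level per profile column (",
                 length(cols), "); classes present: ",
                 paste(levels(cls), collapse = ", ")))
  }
  P <- as.matrix(tibble::as_tibble(profiles)[keep, cols])
  lapply(levels(cls), function(l) P[cls == l, , drop = FALSE])
}

# core estimator over tuples of one individual per class.
# mats: list of n_k x K matrices; inv_pi: list of per-subject pi^R (or NULL)
hum_core <- function(mats, pi_r = NULL, weights = NULL, mode = "auto",
                     mc_draws = 2e5, seed = NULL, tie_tolerance = 1e-9,
                     exact_ceiling = 1e6) {
  K <- length(mats)
  n_k <- vapply(mats, nrow, integer(1))
  if (any(n_k == 0)) abort("every outcome class must be nonempty")
  weights <- weights %||% rep(1, K)
  D <- lapply(seq_len(K), function(k) vertex_distances(mats[[k]]) * weights[k])
  n_tuples <- prod(n_k)
  if (mode == "auto") {
    mode <- if (n_tuples <= exact_ceiling) "exact" else "monte_carlo"
  }
  if (mode == "exact") {
    if (n_tuples > exact_ceiling) {
      abort(paste0("exact enumeration over ", format(n_tuples, big.mark = ","),
                   " tuples exceeds the ceiling; use mode = 'monte_carlo'"))
    }
    idx <- as.matrix(expand.grid(lapply(n_k, seq_len)))
  } else {
    if (!is.null(seed)) set.seed(seed)
    idx <- vapply(n_k, function(n) sample.int(n, mc_draws, replace = TRUE),
                  integer(mc_draws))
  }
  perms <- permutations(K)
  id_row <- which(apply(perms, 1, function(p) all(p == seq_len(K))))
  costs <- matrix(0, nrow(idx), nrow(perms))
  for (p in seq_len(nrow(perms))) {
    for (k in seq_len(K)) {
      costs[, p] <- costs[, p] + D[[k]][idx[, k], perms[p, k]]
    }
  }
  cid <- costs[, id_row]
  cmin_other <- do.call(pmin, as.data.frame(costs[, -id_row, drop = FALSE]))
  correct <- as.numeric(cid < cmin_other - tie_tolerance)
  if (is.null(pi_r)) {
    value <- mean(correct)
  } else {
    wts <- rep(1, nrow(idx))
    for (k in seq_len(K)) wts <- wts / pi_r[[k]][idx[, k]]
    value <- sum(wts * correct) / sum(wts)
  }
  new_hum_estimate(
    value = value, mode = mode, n_per_class = n_k, weights = weights,
    mc_draws = if (mode == "monte_carlo") as.integer(mc_draws) else NA_integer_,
    seed = seed
  )
}

#' Nonparametric HUM (hypervolume under the manifold)
#'
#' The HUM generalizes the AUC to K unordered classes: it is the probability
#' that K individuals, one per outcome class, are all correctly matched to
#' their classes by the forced-choice rule of [classify_set()]. The
#' nonparametric estimator averages the correct-classification indicator
#' over all `n_1 * ... * n_K` tuples (exact mode) or over tuples sampled
#' uniformly with replacement (Monte Carlo mode). Under profiles carrying no
#' class information the HUM is `1/K!` (about 0.0417 for K = 4).
#'
#' @param profiles Data frame with profile columns `p_nopreg`, `p_loss`,
#'   `p_preterm`, `p_fullterm` (or `cols`).
#' @param class Observed class per row, using the canonical
#'   [outcome_classes] labels (or a factor whose level order matches the
#'   profile columns).
#' @param weights Class weights omega (default equal).
#' @param mode `"auto"` (exact when the tuple count fits the ceiling),
#'   `"exact"`, or `"monte_carlo"`.
#' @param mc_draws Monte Carlo tuples (default 2e5).
#' @param seed Seed for Monte Carlo mode.
#' @param tie_tolerance Tie margin; tied sets score zero.
#' @param exact_ceiling Maximum tuple count for exact enumeration.
#' @param cols Profile column names, in class-level order.
#' @return A `hum_estimate`.
#' @export
hum_nonparametric <- function(profiles, class, weights = NULL,
                              mode = c("auto", "exact", "monte_carlo"),
                              mc_draws = 2e5, seed = NULL,
                              tie_tolerance = 1e-9, exact_ceiling = 1e6,
                              cols = NULL) {
  mode <- match.arg(mode)
  mats <- split_profiles(profiles, class, cols)
  hum_core(mats, NULL, weights, mode, mc_draws, seed, tie_tolerance,
           exact_ceiling)
}

#' Verification-bias-adjusted HUM
#'
#' When outcome verification is not completely at random, the complete-case
#' HUM is biased. Each verified tuple is weighted by the inverse product of
#' its members' verification probabilities `pi^R`, and the estimator is the
#' weighted mean of the correct-classification indicator (the weighted sum
#' divided by the sum of the weights). With constant `pi^R` the weights
#' cancel and the estimator reduces to [hum_nonparametric()].
#'
#' @inheritParams hum_nonparametric
#' @param profiles Profiles of verified subjects only (`R = 1`).
#' @param pi_r Estimated verification probability per row, in (0, 1].
#' @return A `hum_estimate`.
#' @export
hum_ipw <- function(profiles, class, pi_r, weights = NULL,
                    mode = c("auto", "exact", "monte_carlo"),
                    mc_draws = 2e5, seed = NULL, tie_tolerance = 1e-9,
                    exact_ceiling = 1e6, cols = NULL) {
  mode <- match.arg(mode)
  if (any(pi_r <= 0)) abort("verification probabilities must be positive")
  mats <- split_profiles(profiles, class, cols)
  cols <- cols %||% intersect(profile_cols, names(profiles))
  cls_full <- if (is.factor(class)) class else
    factor(class, levels = if (length(cols) == 4) outcome_classes else unique(class))
  keep <- !is.na(cls_full)
  cls <- droplevels(cls_full[keep])
  pi_keep <- pi_r[keep]
  pis <- lapply(levels(cls), function(l) pi_keep[cls == l])
  hum_core(mats, pis, weights, mode, mc_draws, seed, tie_tolerance,
           exact_ceiling)
}

#' Monte Carlo estimate of the chance-level (non-informative) HUM
#'
#' When risk profiles carry no information about class, the forced-choice
#' HUM equals `1/K!` (about 0.0417 for K = 4) for any continuous profile
#' distribution, by symmetry over assignments. This estimator draws, for
#' each of `draws` tuples, K fresh profiles uniformly on the K-simplex --
#' one per class slot, independent of the class labels -- and scores the
#' tuple with the weighted forced-choice rule, so its Monte Carlo error is
#' exactly binomial.
#'
#' @param K Number of outcome classes (default 4).
#' @param weights Class weights omega (default equal).
#' @param draws Monte Carlo tuples.
#' @param seed Optional seed.
#' @param tie_tolerance Tie margin; tied sets score zero.
#' @return A `hum_estimate` with the estimated chance rate.
#' @export
hum_chance_rate <- function(K = 4, weights = NULL, draws = 2e5, seed = NULL,
                            tie_tolerance = 1e-9) {
  if (!is.null(seed)) set.seed(seed)
  weights <- weights %||% rep(1, K)
  D <- lapply(seq_len(K), function(k) {
    P <- matrix(stats::rexp(draws * K), draws, K)
    vertex_distances(P / rowSums(P)) * weights[k]
  })
  perms <- permutations(K)
  id_row <- which(apply(perms, 1, function(p) all(p == seq_len(K))))
  costs <- matrix(0, draws, nrow(perms))
  for (p in seq_len(nrow(perms))) {
    for (k in seq_len(K)) {
      costs[, p] <- costs[, p] + D[[k]][, perms[p, k]]
    }
  }
  cid <- costs[, id_row]
  cmin_other <- do.call(pmin, as.data.frame(costs[, -id_row, drop = FALSE]))
  value <- mean(cid < cmin_other - tie_tolerance)
  new_hum_estimate(value = value, mode = "monte_carlo",
                   n_per_class = NA_integer_, weights = weights,
                   mc_draws = as.integer(draws), seed = seed)
}

#' Bootstrap standard error and confidence interval for a HUM pipeline
#'
#' Resamples subjects with replacement, recomputes the statistic per
#' replicate, and returns the bootstrap SE with a normal-approximation CI
#' truncated to [0, 1].
#'
#' @param data Subject-level data frame passed to `statistic`.
#' @param statistic Function `data -> numeric` (fit and score).
#' @param B Bootstrap replicates (>= 50).
#' @param seed Master seed; replicates use derived sub-seeds.
#' @param level Confidence level (default 0.95).
#' @param max_fail Abort if more than this fraction of replicates error.
#' @return List with `estimate`, `se`, `ci`, and the replicate `values`.
#' @export
hum_bootstrap_ci <- function(data, statistic, B = 200, seed = NULL,
                             level = 0.95, max_fail = 0.1) {
  if (B < 50) abort("B must be at least 50")
  seeds <- derive_seeds(seed, B + 1)
  est <- statistic(data)
  n <- nrow(data)
  values <- rep(NA_real_, B)
  errors <- character(0)
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    res <- data[sample.int(n, n, replace = TRUE), , drop = FALSE]
    values[b] <- tryCatch(statistic(res), error = function(e) {
      errors <<- c(errors, conditionMessage(e))
      NA_real_
    })
  }
  if (mean(is.na(values)) > max_fail) {
    abort(paste0("bootstrap failure rate above ", max_fail, "; first error: ",
                 errors[1]))
  }
  se <- sd(values, na.rm = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(est + c(-1, 1) * z * se, 0), 1)
  list(estimate = est, se = se, ci = ci, values = values)
}

#' Bootstrap optimism correction of an apparent performance statistic
#'
#' Harrell's correction for in-sample optimism: for each bootstrap
#' resample, the full pipeline (`fit_score`) is refit on the resample and
#' scored both on the resample and on the original data; the mean of those
#' differences is the optimism, subtracted from the apparent (initial)
#' statistic.
#'
#' @param data Subject-level data frame.
#' @param fit_score Function `(fit_data, score_data) -> numeric`: fits the
#'   pipeline on `fit_data` and scores it on `score_data`. To condition on
#'   an originally selected model form, bake the selected covariates into
#'   this closure.
#' @param B Bootstrap replicates (>= 50).
#' @param seed Master seed.
#' @param max_fail Abort if more than this fraction of replicates error.
#' @return A `hum_estimate` with fields `initial`, `optimism`, `corrected`,
#'   `B`, and the per-replicate tibble `replicates`.
#' @export
optimism_correct <- function(data, fit_score, B = 200, seed = NULL,
                             max_fail = 0.1) {
  if (B < 50) abort("B must be at least 50")
  seeds <- derive_seeds(seed, B)
  initial <- fit_score(data, data)
  n <- nrow(data)
  boot <- orig <- rep(NA_real_, B)
  errors <- character(0)
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    res <- data[sample.int(n, n, replace = TRUE), , drop = FALSE]
    ok <- tryCatch({
      boot[b] <- fit_score(res, res)
      orig[b] <- fit_score(res, data)
      TRUE
    }, error = function(e) {
      errors <<- c(errors, conditionMessage(e))
      FALSE
    })
  }
  fail <- is.na(boot) | is.na(orig)
  if (mean(fail) > max_fail) {
    abort(paste0("bootstrap failure rate above ", max_fail, "; first error: ",
                 errors[1]))
  }
  optimism <- mean(boot[!fail] - orig[!fail])
  out <- new_hum_estimate(
    value = initial - optimism, mode = "optimism_corrected",
    n_per_class = NA_integer_, weights = NULL
  )
  out$initial <- initial
  out$optimism <- optimism
  out$corrected <- initial - optimism
  out$B <- B
  out$replicates <- tibble::tibble(b = seq_len(B), boot = boot, orig = orig)
  out
}
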