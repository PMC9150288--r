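test_that("forced-choice assignment picks the distance-minimizing permutation", {
  # profiles at their own vertices: identity, correct
  res <- classify_set(diag(4))
  expect_equal(res$assignment, 1:4)
  expect_equal(res$correct, 1L)

  # all-uniform profiles: every permutation ties, conservatively incorrect
  res2 <- classify_set(matrix(0.25, 4, 4))
  expect_equal(res2$correct, 0L)

  # classes 1 and 2 swapped: minimizer is the swap, set incorrect
  P <- diag(4)[c(2, 1, 3, 4), ]
  res3 <- classify_set(P)
  expect_equal(res3$assignment, c(2, 1, 3, 4))
  expect_equal(res3$correct, 0L)
})

test_that("class weights steer the assignment as intended", {
  # two borderline profiles; upweighting class 1 makes its fit dominate
  P <- rbind(c(0.4, 0.6, 0, 0) / 1,
             c(0.45, 0.55, 0, 0),
             c(0, 0, 1, 0),
             c(0, 0, 0, 1))
  eq <- classify_set(P, weights = c(1, 1, 1, 1))
  expect_equal(eq$correct, 0L)  # both prefer vertex 2
  up <- classify_set(P, weights = c(10, 1, 1, 1))
  expect_equal(up$assignment[1], 2L)  # class-1 distance dominates; it takes vertex 2
})

test_that("exact HUM equals a brute-force loop and is 1 for separated classes", {
  set.seed(23)
  mats <- lapply(1:4, function(k) runif_simplex(sample(2:5, 1), 4))
  exact <- hum_nonparametric(
    as.data.frame(do.call(rbind, mats)) |>
      stats::setNames(profile_cols_for_test()),
    class = rep(c("nopreg", "loss", "preterm", "fullterm"),
                vapply(mats, nrow, integer(1))),
    mode = "exact"
  )
  expect_equal(exact$value, brute_force_hum(mats), tolerance = 1e-12)

  sep <- lapply(1:4, function(k) {
    m <- matrix(rep(diag(4)[k, ], 3), 3, byrow = TRUE)
    m
  })
  sep_df <- stats::setNames(as.data.frame(do.call(rbind, sep)),
                            profile_cols_for_test())
  hsep <- hum_nonparametric(
    sep_df, class = rep(c("nopreg", "loss", "preterm", "fullterm"), each = 3),
    mode = "exact"
  )
  expect_equal(hsep$value, 1)
})

test_that("Monte Carlo mode is unbiased for the exact estimator", {
  set.seed(77)
  mats <- lapply(1:4, function(k) {
    0.8 * runif_simplex(4, 4) + 0.2 * matrix(rep(diag(4)[k, ], 4), 4,
                                             byrow = TRUE)
  })
  df <- stats::setNames(as.data.frame(do.call(rbind, mats)),
                        profile_cols_for_test())
  cls <- rep(c("nopreg", "loss", "preterm", "fullterm"), each = 4)
  exact <- hum_nonparametric(df, cls, mode = "exact")$value
  mc <- hum_nonparametric(df, cls, mode = "monte_carlo", mc_draws = 1e5,
                          seed = 4)$value
  se <- sqrt(exact * (1 - exact) / 1e5)
  expect_lte(abs(mc - exact), 3 * se)
})

test_that("IPW HUM reduces to the unweighted estimator for constant weights", {
  set.seed(41)
  mats <- lapply(1:4, function(k) runif_simplex(4, 4))
  df <- stats::setNames(as.data.frame(do.call(rbind, mats)),
                        profile_cols_for_test())
  cls <- rep(c("nopreg", "loss", "preterm", "fullterm"), each = 4)
  plain <- hum_nonparametric(df, cls, mode = "exact")$value
  all_one <- hum_ipw(df, cls, pi_r = rep(1, 16), mode = "exact")$value
  const <- hum_ipw(df, cls, pi_r = rep(0.37, 16), mode = "exact")$value
  expect_equal(all_one, plain, tolerance = 1e-12)
  expect_equal(const, plain, tolerance = 1e-12)
  # and matches the brute-force weighted ratio for non-constant weights
  pis <- runif(16, 0.2, 1)
  pis_by_class <- split(pis, rep(1:4, each = 4))
  weighted <- hum_ipw(df, cls, pi_r = pis, mode = "exact")$value
  expect_equal(weighted, brute_force_hum(mats, pi_r = pis_by_class),
               tolerance = 1e-12)
})

test_that("two-class HUM with equal weights is the strict pairwise ordering rate", {
  set.seed(55)
  n1 <- 17; n2 <- 13
  a <- runif_simplex(n1, 2); b <- runif_simplex(n2, 2)
  df <- stats::setNames(as.data.frame(rbind(a, b)), c("pA", "pB"))
  cls <- rep(c("A", "B"), c(n1, n2))
  h <- hum_nonparametric(df, factor(cls, levels = c("A", "B")),
                         mode = "exact", cols = c("pA", "pB"))$value
  # oracle: fraction of cross pairs where the class-A member has strictly
  # higher A-probability
  pairs <- outer(a[, 1], b[, 1], `>`)
  expect_equal(h, mean(pairs), tolerance = 1e-12)
})

test_that("HUM is invariant to within-class relabeling and consistent class permutation", {
  set.seed(66)
  mats <- lapply(1:4, function(k) {
    0.85 * runif_simplex(5, 4) + 0.15 * matrix(rep(diag(4)[k, ], 5), 5,
                                               byrow = TRUE)
  })
  df <- stats::setNames(as.data.frame(do.call(rbind, mats)),
                        profile_cols_for_test())
  cls <- rep(c("nopreg", "loss", "preterm", "fullterm"), each = 5)
  base <- hum_nonparametric(df, cls, mode = "exact")$value

  shuffle <- sample(nrow(df))
  expect_equal(hum_nonparametric(df[shuffle, ], cls[shuffle],
                                 mode = "exact")$value,
               base, tolerance = 1e-12)

  # permute class identities jointly in profiles and labels: new profile
  # column j holds the old class perm[j], so old class k is relabeled to
  # the class at position order(perm)[k]
  perm <- c(3, 1, 4, 2)
  df_p <- df[, perm]
  names(df_p) <- names(df)
  new_class <- c("nopreg", "loss", "preterm", "fullterm")[order(perm)]
  relabel <- stats::setNames(new_class, c("nopreg", "loss", "preterm",
                                          "fullterm"))
  expect_equal(
    hum_nonparametric(df_p, unname(relabel[cls]), mode = "exact")$value,
    base, tolerance = 1e-12
  )
})

test_that("exact mode refuses oversized enumerations and directs to MC", {
  df <- stats::setNames(as.data.frame(runif_simplex(400, 4)),
                        profile_cols_for_test())
  cls <- rep(c("nopreg", "loss", "preterm", "fullterm"), each = 100)
  expect_error(hum_nonparametric(df, cls, mode = "exact",
                                 exact_ceiling = 1e4),
               "monte_carlo")
})

test_that("the chance-level HUM estimator recovers 1/K!", {
  for (K in c(3, 4)) {
    est <- hum_chance_rate(K = K, draws = 1e5, seed = 10 + K)
    p0 <- 1 / factorial(K)
    se <- sqrt(p0 * (1 - p0) / 1e5)
    expect_lt(abs(est$value - p0), 3 * se)
  }
  # weighting does not move the chance level: assignments stay exchangeable
  w <- hum_chance_rate(K = 4, weights = c(4, 1, 1, 1), draws = 1e5, seed = 3)
  p0 <- 1 / 24
  expect_lt(abs(w$value - p0), 3 * sqrt(p0 * (1 - p0) / 1e5))
})

test_that("bootstrap CI is truncated and degenerate data give SE 0", {
  sep <- stats::setNames(as.data.frame(diag(4)[rep(1:4, each = 5), ]),
                         profile_cols_for_test())
  sep$class <- rep(c("nopreg", "loss", "preterm", "fullterm"), each = 5)
  stat <- function(d) hum_nonparametric(d, d$class, mode = "exact")$value
  bs <- hum_bootstrap_ci(sep, stat, B = 60, seed = 2)
  expect_equal(bs$se, 0)
  expect_equal(bs$ci, c(1, 1))
  expect_true(all(bs$ci >= 0 & bs$ci <= 1))
})

test_that("optimism correction reproduces the subtraction identity", {
  dat <- tibble::tibble(x = 1:40)
  # constant pipeline: no optimism
  const <- optimism_correct(dat, function(fit, score) 0.42, B = 50, seed = 1)
  expect_equal(const$optimism, 0)
  expect_equal(const$corrected, 0.42)

  # stubbed pipeline with a fixed in-sample advantage
  stub <- optimism_correct(
    dat,
    function(fit, score) if (identical(fit, score)) 0.108 else 0.093,
    B = 50, seed = 1
  )
  expect_equal(stub$initial, 0.108)
  expect_equal(stub$optimism, 0.015, tolerance = 1e-12)
  expect_equal(stub$corrected, 0.093, tolerance = 1e-12)
})
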