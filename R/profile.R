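#' Compose a preconception risk profile
#'
#' The four-category risk profile is the conception probability split across
#' the conditional gestation outcomes:
#' `(1 - p, p * P(loss|conc), p * P(preterm|conc), p * P(fullterm|conc))`
#' where `p = P(T1 <= tau | x)`. Entries are nonnegative and sum to one.
#'
#' @param p_conceive Numeric vector of conception probabilities in `[0, 1]`.
#' @param cond Data frame or matrix with columns `loss`, `preterm`,
#'   `fullterm`, rows aligned with `p_conceive`, each row summing to one.
#' @return Tibble with columns `p_nopreg`, `p_loss`, `p_preterm`,
#'   `p_fullterm`, class `preg_profiles`.
#' @export
compose_profile <- function(p_conceive, cond) {
  cond <- tibble::as_tibble(as.data.frame(cond))
  stopifnot(all(c("loss", "preterm", "fullterm") %in% names(cond)),
            nrow(cond) == length(p_conceive))
  if (any(p_conceive < 0 | p_conceive > 1)) {
    abort("p_conceive must lie in [0, 1]")
  }
  csum <- cond$loss + cond$preterm + cond$fullterm
  if (any(cond$loss < 0 | cond$preterm < 0 | cond$fullterm < 0) ||
      any(abs(csum - 1) > 1e-8)) {
    abort("cond must be rows of a probability vector over loss/preterm/fullterm")
  }
  out <- tibble::tibble(
    p_nopreg = 1 - p_conceive,
    p_loss = cond$loss * p_conceive,
    p_preterm = cond$preterm * p_conceive,
    p_fullterm = cond$fullterm * p_conceive
  )
  class(out) <- c("preg_profiles", class(out))
  out
}

profile_cols <- paste0("p_", outcome_classes)

#' Predict risk profiles for a cohort
#'
#' Composes a fitted (or constructed) conception model and gestation model
#' into one risk profile per subject. Subjects with missing values in the
#' required `x` or `z` covariates are skipped and listed in the
#' `skipped_ids` attribute (prediction requires complete baseline
#' covariates).
#'
#' @param conception A `conception_fit`.
#' @param gestation A `gestation_fit`.
#' @param cohort A `preg_cohort` or any data frame with `id` and the two
#'   models' covariate columns.
#' @param cycle_mass If `TRUE`, append the per-cycle conception-mass columns
#'   `mass_1..mass_tau`.
#' @return Tibble (`preg_profiles`) with `id` and columns `p_nopreg`,
#'   `p_loss`, `p_preterm`, `p_fullterm` summing to one per row.
#' @export
predict_profiles <- function(conception, gestation, cohort, cycle_mass = FALSE) {
  dat <- tibble::as_tibble(cohort)
  needed <- union(conception$covariates, gestation$covariates)
  complete <- complete.cases(dat[needed])
  skipped <- dat$id[!complete]
  if (length(skipped) > 0) {
    inform(paste0(length(skipped),
                  " subject(s) skipped for missing x/z covariates"))
  }
  dat <- dat[complete, , drop = FALSE]
  p_conc <- cumulative_conception(conception, dat)
  cond <- conditional_probs(gestation, dat)
  out <- dplyr::bind_cols(tibble::tibble(id = dat$id),
                          compose_profile(p_conc, cond))
  if (cycle_mass) {
    out <- dplyr::bind_cols(out, conception_mass(conception, dat))
  }
  class(out) <- c("preg_profiles", class(tibble::tibble()))
  attr(out, "skipped_ids") <- skipped
  out
}

#' @export
print.preg_profiles <- function(x, ...) {
  cat("# preconception risk profiles:", nrow(x), "subjects\n")
  NextMethod()
}

#' Plot a cohort's risk profiles as stacked probability bands
#'
#' Subjects are ordered by their predicted probability of no pregnancy within
#' the window; each vertical cross-section shows one subject's four-category
#' risk profile.
#'
#' @param object A `preg_profiles` tibble from [predict_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot preg_profiles
#' @export
autoplot.preg_profiles <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat <- dplyr::arrange(dat, .data$p_nopreg)
  dat$rank <- seq_len(nrow(dat))
  long <- tidyr::pivot_longer(
    dat[c("rank", profile_cols)],
    cols = dplyr::all_of(profile_cols),
    names_to = "class", values_to = "probability"
  )
  long$class <- factor(long$class, levels = rev(profile_cols),
                       labels = rev(c("No pregnancy", "Loss", "Preterm",
                                      "Full-term")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$probability,
                                     fill = .data$class)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "Subject (ordered by P(no pregnancy))",
                  y = "Predicted probability", fill = "Outcome") +
    ggplot2::theme_minimal()
}

#' Plot the average per-cycle conception mass
#'
#' Shows, for each cycle of the window, the cohort-average probability that
#' conception occurs at exactly that cycle.
#'
#' @param conception A `conception_fit`.
#' @param cohort Data frame with the model's covariate columns.
#' @return A ggplot object.
#' @export
plot_conception_mass <- function(conception, cohort) {
  mass <- conception_mass(conception, tibble::as_tibble(cohort))
  avg <- tibble::tibble(
    cycle = seq_len(ncol(mass)),
    probability = colMeans(as.matrix(mass))
  )
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$cycle, y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(breaks = avg$cycle) +
    ggplot2::labs(x = "Menstrual cycle since preconception visit",
                  y = "Mean P(conception at cycle)") +
    ggplot2::theme_minimal()
}
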