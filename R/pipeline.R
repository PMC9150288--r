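#' Backward AIC covariate selection on stacked completed cohorts
#'
#' Starting from the candidate set, repeatedly removes the non-forced
#' covariate whose removal most decreases the AIC of the stage model,
#' stopping when no removal decreases it. Applied to the concatenation of
#' the M completed cohorts (Mn rows), so all imputations inform one
#' selected model form; the AIC is used literally on the stacked data,
#' without adjustment for the M-fold sample inflation. Ties are broken
#' lexicographically; a non-convergent refit disqualifies that removal.
#'
#' @param data Stacked completed cohorts (rows of all M `preg_cohort`s), or
#'   any complete subject-level tibble.
#' @param stage `"conception"` (discrete-time hazard AIC) or `"gestation"`
#'   (multinomial AIC on conceivers).
#' @param candidates Candidate covariate columns.
#' @param forced_in Covariates never removed.
#' @param tau Conception window (needed for the conception stage).
#' @return List with `selected` (character vector) and a `trace` tibble of
#'   the removal path.
#' @export
backward_aic_select <- function(data, stage = c("conception", "gestation"),
                                candidates, forced_in = character(0),
                                tau = NULL) {
  stage <- match.arg(stage)
  stopifnot(all(forced_in %in% candidates))
  data <- tibble::as_tibble(data)
  stage_aic <- function(covs) {
    if (stage == "conception") {
      fit_conception(data, covariates = covs, tau = tau)$aic
    } else {
      fit_gestation(data, covariates = covs)$aic
    }
  }
  current <- sort(candidates)
  trace <- list()
  aic_now <- stage_aic(current)
  repeat {
    removable <- sort(setdiff(current, forced_in))
    if (length(removable) == 0) break
    aics <- vapply(removable, function(v) {
      tryCatch(stage_aic(setdiff(current, v)), error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(aics)) || min(aics, na.rm = TRUE) >= aic_now) break
    drop_var <- removable[which.min(aics)]   # first index wins ties
    trace[[length(trace) + 1L]] <- tibble::tibble(
      removed = drop_var, aic_before = aic_now, aic_after = min(aics, na.rm = TRUE)
    )
    current <- setdiff(current, drop_var)
    aic_now <- min(aics, na.rm = TRUE)
  }
  list(selected = current,
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble(removed = character(), aic_before = numeric(),
                        aic_after = numeric()))
}

pool_conception <- function(fits) {
  g <- rowMeans(vapply(fits, `[[`, numeric(fits[[1]]$tau), "baseline_logits"))
  gam <- rowMeans(vapply(fits, `[[`,
                         numeric(length(fits[[1]]$coefficients)),
                         "coefficients"))
  names(gam) <- fits[[1]]$covariates
  new_conception_model(g, gam, fits[[1]]$tau,
                       n_subjects = fits[[1]]$n_subjects)
}

pool_gestation <- function(fits) {
  a2 <- rowMeans(vapply(fits, `[[`, numeric(length(fits[[1]]$alpha_loss)),
                        "alpha_loss"))
  a3 <- rowMeans(vapply(fits, `[[`, numeric(length(fits[[1]]$alpha_preterm)),
                        "alpha_preterm"))
  names(a2) <- names(a3) <- names(fits[[1]]$alpha_loss)
  new_gestation_model(a2, a3, n = fits[[1]]$n)
}

# observed four-level class for verified subjects (NA otherwise)
observed_class <- function(cohort) {
  dplyr::case_when(
    cohort$r1 == 1 & cohort$conceived == 0 ~ "nopreg",
    cohort$r1 == 1 & cohort$r2 == 1 & cohort$conceived == 1 ~ cohort$outcome,
    TRUE ~ NA_character_
  )
}

#' Run the full estimation-and-validation pipeline
#'
#' Orchestrates one analysis end to end: handle two-stage outcome
#' missingness (sequential multiple imputation, inverse-probability
#' weighting, or a complete-case path kept for demonstrating verification
#' bias), optionally select covariates by stacked backward AIC, fit the two
#' stage models (pooling across imputations on the MI path), predict risk
#' profiles for subjects with complete baseline covariates, estimate the
#' verification-bias-adjusted HUM, and apply bootstrap optimism correction
#' conditioning on the selected model form.
#'
#' @param cohort A `preg_cohort`.
#' @param path Missing-data path: `"mi"`, `"ipw"`, or `"complete_case"`.
#' @param M Imputations for the MI path.
#' @param B Bootstrap replicates for optimism correction (0 skips it).
#' @param seed Master seed; all random stages use derived sub-seeds.
#' @param select Run backward AIC selection (default TRUE).
#' @param forced_in_x,forced_in_z Covariates forced into each stage.
#' @param hum_weights Class weights omega for the HUM.
#' @param mc_draws Monte Carlo tuples for each HUM evaluation.
#' @param reselect_in_bootstrap Re-run selection inside each optimism
#'   replicate instead of conditioning on the selected form (off by
#'   default; re-selection is less stable).
#' @param out_dir Optional directory: writes `report.json`, `profiles.csv`,
#'   and per-path intermediates.
#' @return A `preg_analysis` report list.
#' @export
run_analysis <- function(cohort, path = c("mi", "ipw", "complete_case"),
                         M = 10, B = 100, seed = 1, select = TRUE,
                         forced_in_x = character(0),
                         forced_in_z = character(0),
                         hum_weights = c(1, 1, 1, 1), mc_draws = 2e5,
                         reselect_in_bootstrap = FALSE, out_dir = NULL) {
  path <- match.arg(path)
  roles <- cohort_roles_of(cohort)
  tau <- cohort_tau(cohort)
  seeds <- derive_seeds(seed, 4)

  fitted <- fit_path(cohort, path, roles, tau, M, seeds[1], select,
                     forced_in_x, forced_in_z)

  profiles <- predict_profiles(fitted$conception, fitted$gestation, cohort)
  vm <- fit_missingness(cohort, form = "single")
  cls <- observed_class(cohort)
  verified <- !is.na(cls)
  pro_tab <- dplyr::inner_join(
    profiles,
    tibble::tibble(id = cohort$id, class = cls, verified = verified),
    by = "id"
  )
  scored <- pro_tab[pro_tab$verified, , drop = FALSE]
  pi_r <- verification_prob(
    vm, tibble::as_tibble(cohort)[match(scored$id, cohort$id), , drop = FALSE]
  )
  ok_pi <- !is.na(pi_r)
  scored <- scored[ok_pi, , drop = FALSE]
  pi_r <- pi_r[ok_pi]
  hum <- hum_ipw(scored, scored$class, pi_r, weights = hum_weights,
                 mode = "monte_carlo", mc_draws = mc_draws, seed = seeds[2])

  optimism <- NULL
  if (B > 0) {
    sel_x <- fitted$selected_x
    sel_z <- fitted$selected_z
    fit_score <- function(fit_data, score_data) {
      fit_data$id <- sprintf("b%06d", seq_len(nrow(fit_data)))
      fd <- preg_like(fit_data, tau, roles)
      sdat <- preg_like(score_data, tau, roles)
      f <- fit_path(fd, path, roles, tau, M, seeds[3],
                    select = reselect_in_bootstrap,
                    forced_in_x, forced_in_z,
                    covariates_x = sel_x, covariates_z = sel_z)
      prof <- suppressMessages(
        predict_profiles(f$conception, f$gestation, sdat)
      )
      cls_s <- observed_class(sdat)
      keep <- !is.na(cls_s) & sdat$id %in% prof$id
      prof_s <- prof[match(sdat$id[keep], prof$id), , drop = FALSE]
      vms <- fit_missingness(sdat, form = "single")
      pis <- verification_prob(vms, tibble::as_tibble(sdat)[keep, , drop = FALSE])
      ok <- !is.na(pis)
      prof_s <- prof_s[ok, , drop = FALSE]
      pis <- pis[ok]
      cls_keep <- cls_s[keep][ok]
      hum_ipw(prof_s, cls_keep, pis, weights = hum_weights,
              mode = "monte_carlo", mc_draws = mc_draws,
              seed = seeds[4])$value
    }
    optimism <- optimism_correct(tibble::as_tibble(cohort), fit_score,
                                 B = B, seed = seeds[4])
  }

  report <- structure(
    list(
      path = path, tau = tau, n = nrow(cohort), M = if (path == "mi") M else NA,
      selected_x = fitted$selected_x, selected_z = fitted$selected_z,
      conception = fitted$conception, gestation = fitted$gestation,
      profiles = profiles, hum = hum, optimism = optimism,
      seed = seed
    ),
    class = "preg_analysis"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# fit the two stage models under one missing-data path; when covariates_x/z
# are supplied, selection is skipped and those sets are used (the
# condition-on-model-form bootstrap)
fit_path <- function(cohort, path, roles, tau, M, seed, select,
                     forced_in_x, forced_in_z,
                     covariates_x = NULL, covariates_z = NULL) {
  if (path == "mi") {
    imp <- sequential_impute(cohort, M = M, seed = seed)
    stacked <- dplyr::bind_rows(lapply(imp$cohorts, tibble::as_tibble))
    sel_x <- covariates_x %||% if (select) {
      backward_aic_select(stacked, "conception", roles$x, forced_in_x,
                          tau = tau)$selected
    } else roles$x
    sel_z <- covariates_z %||% if (select) {
      backward_aic_select(stacked, "gestation", roles$z, forced_in_z)$selected
    } else roles$z
    cms <- lapply(imp$cohorts, fit_conception, covariates = sel_x, tau = tau)
    gms <- lapply(imp$cohorts, fit_gestation, covariates = sel_z)
    list(conception = pool_conception(cms), gestation = pool_gestation(gms),
         selected_x = sel_x, selected_z = sel_z)
  } else {
    # weighted / complete-case paths use records with complete baseline
    # covariates (the analysis-set restriction MI avoids)
    obs <- tibble::as_tibble(cohort)
    allc <- unique(unlist(unclass(roles)))
    coc <- preg_like(obs[complete.cases(obs[allc]), , drop = FALSE],
                     tau, roles)
    sel_x <- covariates_x %||% roles$x
    sel_z <- covariates_z %||% roles$z
    if (is.null(covariates_x) && select) {
      sel_x <- backward_aic_select(coc, "conception", roles$x, forced_in_x,
                                   tau = tau)$selected
      obs_g <- tibble::as_tibble(coc)
      obs_g <- obs_g[obs_g$conceived == 1 & !is.na(obs_g$outcome), ,
                     drop = FALSE]
      sel_z <- backward_aic_select(obs_g, "gestation", roles$z,
                                   forced_in_z)$selected
    }
    cm <- fit_conception(coc, covariates = sel_x, tau = tau)
    gw <- if (path == "ipw") {
      mm <- suppressWarnings(fit_missingness(coc, form = "product"))
      complete_case_weights(mm, coc)
    } else NULL
    gm <- fit_gestation(coc, weights = gw, covariates = sel_z)
    list(conception = cm, gestation = gm,
         selected_x = sel_x, selected_z = sel_z)
  }
}

#' @export
print.preg_analysis <- function(x, ...) {
  cat("Preconception risk analysis (", x$path, " path, n = ", x$n, ")\n",
      sep = "")
  cat("Selected conception covariates:", paste(x$selected_x, collapse = ", "), "\n")
  cat("Selected gestation covariates:", paste(x$selected_z, collapse = ", "), "\n")
  cat("Verification-adjusted HUM:", signif(x$hum$value, 4), "\n")
  if (!is.null(x$optimism)) {
    cat("Optimism-corrected HUM:", signif(x$optimism$corrected, 4), "\n")
  }
  invisible(x)
}

#' Serialize a fitted stage model to JSON
#'
#' @param model A `conception_fit` or `gestation_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "conception_fit")) {
    list(type = "conception", tau = model$tau,
         baseline_logits = model$baseline_logits,
         coefficients = as.list(model$coefficients))
  } else {
    list(type = "gestation",
         alpha_loss = as.list(model$alpha_loss),
         alpha_preterm = as.list(model$alpha_preterm))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stage model from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return A `conception_fit` or `gestation_fit`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "conception") {
    new_conception_model(unlist(obj$baseline_logits),
                         unlist(obj$coefficients), obj$tau)
  } else {
    new_gestation_model(unlist(obj$alpha_loss), unlist(obj$alpha_preterm))
  }
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tibble::as_tibble(report$profiles),
                   file.path(out_dir, "profiles.csv"), progress = FALSE)
  json <- list(
    path = report$path, n = report$n, tau = report$tau, M = report$M,
    seed = report$seed,
    selected_x = report$selected_x, selected_z = report$selected_z,
    conception = list(baseline_logits = report$conception$baseline_logits,
                      coefficients = as.list(report$conception$coefficients)),
    gestation = list(alpha_loss = as.list(report$gestation$alpha_loss),
                     alpha_preterm = as.list(report$gestation$alpha_preterm)),
    hum = list(value = report$hum$value, mode = report$hum$mode,
               mc_draws = report$hum$mc_draws),
    optimism = if (!is.null(report$optimism)) list(
      initial = report$optimism$initial,
      mean_optimism = report$optimism$optimism,
      corrected = report$optimism$corrected,
      B = report$optimism$B
    )
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
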