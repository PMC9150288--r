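#' Canonical pregnancy-outcome classes
#'
#' The fixed class order used everywhere in the package: no clinically-
#' recognized pregnancy within the conception window, clinical pregnancy loss,
#' preterm birth, full-term birth. Risk-profile columns, HUM class labels and
#' plotting all follow this order.
#'
#' @format Character vector of length 4.
#' @export
outcome_classes <- c("nopreg", "loss", "preterm", "fullterm")

gestation_classes <- c("loss", "preterm", "fullterm")

#' Declare covariate roles for a cohort
#'
#' Each role names the columns used by one model in the pipeline: `x` drives
#' the discrete-time conception hazard, `z` the multinomial gestation model,
#' `x_miss` the first-stage verification model P(R1 = 1 | x'), `z_miss` the
#' second-stage verification model P(R2 = 1 | z', R1 = 1, Y1), and `aux` the
#' auxiliary set used by the imputation models (defaults to the union of `x`
#' and `x_miss`).
#'
#' @param x,z,x_miss,z_miss,aux Character vectors of covariate column names.
#' @return A named list of roles, class `"cohort_roles"`.
#' @export
cohort_roles <- function(x, z, x_miss = x, z_miss = z,
                         aux = union(x, x_miss)) {
  out <- list(
    x = as.character(x), z = as.character(z),
    x_miss = as.character(x_miss), z_miss = as.character(z_miss),
    aux = as.character(aux)
  )
  structure(out, class = "cohort_roles")
}

#' Assemble a pregnancy-attempt cohort
#'
#' A cohort is a tibble with one row per subject holding the observed data of
#' a two-stage pregnancy attempt: `U` cycles of first-stage follow-up, the
#' conception indicator `conceived`, the gestation `outcome` (one of
#' `"loss"`, `"preterm"`, `"fullterm"`, or `NA` when undefined/unobserved) and
#' the two verification indicators `r1` (first-stage status known at tau) and
#' `r2` (gestation outcome known). Baseline covariates occupy the remaining
#' columns; their modelling roles are declared via [cohort_roles()].
#'
#' Rows violating the record invariants are rejected with row-indexed
#' diagnostics. The convention for subjects followed through tau without
#' conceiving is `r1 = 1, r2 = 1` (the second-stage outcome is vacuously
#' known to be undefined).
#'
#' @param data Data frame with columns `id`, `U`, `conceived`, `r1`, `r2`,
#'   `outcome` plus covariates.
#' @param tau Conception window in menstrual cycles (default 6).
#' @param roles A [cohort_roles()] object.
#' @param reject How to handle invalid rows: `"error"` or `"drop"` (drop with
#'   a warning listing the offending rows).
#' @return A `preg_cohort` tibble.
#' @export
preg_cohort <- function(data, tau = 6L, roles, reject = c("error", "drop")) {
  reject <- match.arg(reject)
  stopifnot(tau >= 1)
  data <- tibble::as_tibble(data)
  required <- c("id", "U", "conceived", "r1", "r2", "outcome")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) {
    abort("no subjects")
  }
  covs <- unique(unlist(unclass(roles)))
  missing_covs <- setdiff(covs, names(data))
  if (length(missing_covs) > 0) {
    abort(paste0("role covariates absent from data: ",
                 paste(missing_covs, collapse = ", ")))
  }

  problems <- validate_subject_rows(data, tau)
  if (nrow(problems) > 0) {
    msg <- paste0(
      "invalid subject rows:\n",
      paste0("  row ", problems$row, " (id ", problems$id, "): ",
             problems$problem, collapse = "\n")
    )
    if (reject == "error") abort(msg)
    warn(paste0(msg, "\nrejected ", length(unique(problems$row)), " row(s)"))
    data <- data[-unique(problems$row), , drop = FALSE]
    if (nrow(data) == 0) abort("no subjects (all rows rejected)")
  }
  if (anyDuplicated(data$id)) {
    abort("subject ids must be unique")
  }

  structure(
    data,
    tau = as.integer(tau),
    roles = roles,
    class = c("preg_cohort", class(tibble::tibble()))
  )
}

# row-indexed invariant diagnostics; returns tibble(row, id, problem)
validate_subject_rows <- function(data, tau) {
  probs <- list()
  note <- function(rows, text) {
    if (any(rows, na.rm = TRUE)) {
      idx <- which(rows)
      probs[[length(probs) + 1L]] <<- tibble::tibble(
        row = idx, id = as.character(data$id[idx]), problem = text
      )
    }
  }
  ok_outcome <- is.na(data$outcome) | data$outcome %in% gestation_classes
  note(!ok_outcome, "outcome not one of loss/preterm/fullterm/NA")
  note(!(data$U %in% seq_len(tau)), "U outside 1..tau")
  note(!(data$conceived %in% c(0, 1)), "conceived not 0/1")
  note(!(data$r1 %in% c(0, 1)) | !(data$r2 %in% c(0, 1)), "r1/r2 not 0/1")
  note(data$r2 == 1 & data$r1 == 0, "r2 = 1 requires r1 = 1")
  note(data$r1 == 0 & data$conceived == 1,
       "conceived = 1 requires r1 = 1 (conception is an observed event)")
  note(data$r1 == 0 & data$U == tau,
       "r1 = 0 (censored before conception) requires U < tau")
  note(data$r1 == 1 & data$conceived == 0 & data$U != tau,
       "r1 = 1 with no conception requires U = tau")
  note(data$r1 == 1 & data$conceived == 0 & data$r2 == 0,
       "r1 = 1 with no conception has r2 = 1 by convention")
  note(!is.na(data$outcome) &
         !(data$conceived == 1 & data$r1 == 1 & data$r2 == 1),
       "outcome defined requires conceived = 1, r1 = 1, r2 = 1")
  note(is.na(data$outcome) & data$conceived == 1 & data$r2 == 1,
       "conceived = 1 with r2 = 1 requires a defined outcome")
  if (length(probs) == 0) {
    return(tibble::tibble(row = integer(), id = character(), problem = character()))
  }
  dplyr::arrange(dplyr::bind_rows(probs), .data$row)
}

#' @export
print.preg_cohort <- function(x, ...) {
  cat("# preg_cohort: ", nrow(x), " subjects, tau = ", attr(x, "tau"), "\n",
      sep = "")
  NextMethod()
}

cohort_tau <- function(cohort) attr(cohort, "tau")
cohort_roles_of <- function(cohort) attr(cohort, "roles")

#' Classify each subject's observed-data pattern
#'
#' Every valid record falls into exactly one of four observed-data categories
#' determined by `(r1, r2, conceived)`: censored prior to conception
#' `(0, 0, .)`; no pregnancy within tau cycles `(1, 1, 0)`; pregnancy with
#' unknown result `(1, 0, 1)`; pregnancy with known result `(1, 1, 1)`.
#'
#' @param cohort A `preg_cohort` (or compatible data frame).
#' @return Factor vector, one level per pattern, aligned with the rows.
#' @export
observation_pattern <- function(cohort) {
  levs <- c("censored_preconception", "no_pregnancy",
            "pregnancy_unknown_result", "pregnancy_known_result")
  if (any(cohort$r1 == 0 & cohort$r2 == 1)) {
    abort("invalid record: r2 = 1 with r1 = 0")
  }
  out <- dplyr::case_when(
    cohort$r1 == 0 ~ levs[1],
    cohort$conceived == 0 ~ levs[2],
    cohort$r2 == 0 ~ levs[3],
    TRUE ~ levs[4]
  )
  factor(out, levels = levs)
}

#' Expand a cohort to person-period (subject-cycle) form
#'
#' Discrete-time survival data are restructured so subject i contributes
#' `U_i` rows, one per at-risk cycle `t = 1..U_i`, with the binary event
#' indicator equal to 1 only in the final row of subjects whose follow-up
#' ended in conception. Fitting a logistic regression of `event` on cycle
#' indicators plus covariates on this table maximizes the discrete-time
#' hazard likelihood.
#'
#' @param cohort A `preg_cohort`.
#' @param covariates Covariate columns to carry along (default: the `x` role).
#' @return Tibble with columns `id`, `cycle`, `event`, and the covariates.
#' @export
expand_person_period <- function(cohort, covariates = NULL) {
  covariates <- covariates %||% cohort_roles_of(cohort)$x
  base <- tibble::tibble(
    id = cohort$id, U = as.integer(cohort$U), conceived = cohort$conceived
  )
  base <- dplyr::bind_cols(base, tibble::as_tibble(cohort)[covariates])
  out <- base[rep(seq_len(nrow(base)), base$U), , drop = FALSE]
  out$cycle <- sequence(base$U)
  out$event <- as.integer(out$conceived == 1 & out$cycle == out$U)
  dplyr::select(out, "id", "cycle", "event", dplyr::all_of(covariates))
}

#' Read a cohort from a delimited text file
#'
#' Expects a comma-delimited file with a header and columns `id`, `U`,
#' `conceived`, `r1`, `r2`, `outcome` plus covariate columns. Covariate roles
#' come either from a [cohort_roles()] object or from a JSON/YAML config file
#' with top-level keys `x`, `z`, `x_miss`, `z_miss`, `aux` (and optionally
#' `tau`).
#'
#' @param path Path to the CSV file.
#' @param roles A [cohort_roles()] object, or path to a JSON/YAML role config.
#' @param tau Conception window (overridden by a `tau` entry in a config file).
#' @param reject Passed to [preg_cohort()]; default drops invalid rows with a
#'   warning.
#' @return A `preg_cohort`.
#' @export
read_cohort <- function(path, roles, tau = 6L, reject = "drop") {
  if (is.character(roles) && length(roles) == 1L) {
    cfg <- read_roles_config(roles)
    tau <- cfg$tau %||% tau
    roles <- cfg$roles
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(data) == 0) abort("no subjects")
  if ("outcome" %in% names(data)) {
    data$outcome <- as.character(data$outcome)
  }
  preg_cohort(data, tau = tau, roles = roles, reject = reject)
}

read_roles_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  roles <- cohort_roles(
    x = cfg$x, z = cfg$z,
    x_miss = cfg$x_miss %||% cfg$x,
    z_miss = cfg$z_miss %||% cfg$z,
    aux = cfg$aux %||% union(cfg$x, cfg$x_miss %||% cfg$x)
  )
  list(roles = roles, tau = cfg$tau)
}

#' Write a cohort (or person-period table) to CSV
#'
#' @param data A `preg_cohort` or tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}
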