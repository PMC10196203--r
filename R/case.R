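.trial_levels <- c("yes", "no", "unsure")
.outcome_levels <- c("poor_efficacy", "adverse_effects", "none_or_unknown")
.status_levels <- c("current", "past")

.input_stop <- function(msg) {
  stop(structure(class = c("pgx_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.normalize_trial <- function(x) {
  if (is.logical(x)) x <- ifelse(x, "yes", "no")
  x <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(x), .trial_levels)
  if (length(bad) > 0) {
    .input_stop(sprintf("trial_adequate must be yes/no/unsure, got: %s",
                        paste(bad, collapse = ", ")))
  }
  x
}

#' Construct a medication record
#'
#' One row of the medication history (consult step 1): current and past
#' medications are both admissible and score identically; status is carried
#' for display. `trial_adequate` is the clinician's step-3 judgment
#' (yes/no/unsure) and `outcome` the step-4 medication-related problem:
#' exactly one of unexpected `poor_efficacy`, intolerable `adverse_effects`,
#' or `none_or_unknown`.
#'
#' @param name drug name.
#' @param status `"current"` or `"past"`.
#' @param dose,duration free-text dose and duration (not interpreted).
#' @param trial_adequate `"yes"`, `"no"`, or `"unsure"` (logicals accepted).
#' @param outcome `"poor_efficacy"`, `"adverse_effects"`, or
#'   `"none_or_unknown"`.
#' @return a one-row data frame.
#' @export
medication <- function(name, status = "current", dose = "", duration = "",
                       trial_adequate = "unsure",
                       outcome = "none_or_unknown") {
  status <- match.arg(status, .status_levels)
  outcome <- match.arg(outcome, .outcome_levels)
  data.frame(name = as.character(name), status = status,
             dose = as.character(dose), duration = as.character(duration),
             trial_adequate = .normalize_trial(trial_adequate),
             outcome = outcome, stringsAsFactors = FALSE)
}

#' Construct a patient case
#'
#' Bundles the inputs of a structured PGx consult: the medication history,
#' co-medications (potential phenoconversion perpetrators), and optionally
#' the patient's genotype results. A case without genotypes represents an
#' untested patient, for which [recommend_testing()] decides whether
#' reactive PGx testing is indicated.
#'
#' @param medications a data frame with columns `name`, `status`, `dose`,
#'   `duration`, `trial_adequate`, `outcome` (see [medication()]); rows may
#'   be built by `rbind`-ing [medication()] calls.
#' @param comedications character vector of co-medication names.
#' @param genotypes `NULL` (untested) or a data frame with columns `gene`
#'   and `diplotype`.
#' @param patient named list of demographic fields (free-form; carried into
#'   reports).
#' @return an object of class `pgx_case`.
#' @export
#' @examples
#' case <- pgx_case(rbind(
#'   medication("codeine", trial_adequate = "yes", outcome = "poor_efficacy"),
#'   medication("clomipramine", trial_adequate = "yes", outcome = "poor_efficacy")
#' ))
pgx_case <- function(medications, comedications = character(),
                     genotypes = NULL, patient = list()) {
  if (is.null(medications)) {
    medications <- data.frame(name = character(), status = character(),
                              dose = character(), duration = character(),
                              trial_adequate = character(),
                              outcome = character(),
                              stringsAsFactors = FALSE)
  }
  medications <- as.data.frame(medications, stringsAsFactors = FALSE)
  needed <- c("name", "status", "dose", "duration", "trial_adequate",
              "outcome")
  for (col in setdiff(needed, names(medications))) {
    medications[[col]] <- if (col == "trial_adequate") "unsure"
    else if (col == "outcome") "none_or_unknown"
    else if (col == "status") "current" else ""
  }
  medications <- medications[, needed, drop = FALSE]
  if (nrow(medications) > 0) {
    medications$trial_adequate <- .normalize_trial(medications$trial_adequate)
    bad <- setdiff(unique(medications$outcome), .outcome_levels)
    if (length(bad) > 0) {
      .input_stop(sprintf("medication outcome must be one of %s; got: %s",
                          paste(.outcome_levels, collapse = "/"),
                          paste(bad, collapse = ", ")))
    }
    bad <- setdiff(unique(medications$status), .status_levels)
    if (length(bad) > 0) {
      .input_stop(sprintf("medication status must be current/past; got: %s",
                          paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(genotypes)) {
    genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
    if (!all(c("gene", "diplotype") %in% names(genotypes))) {
      .input_stop("genotypes must have columns gene and diplotype")
    }
    genotypes <- genotypes[, c("gene", "diplotype"), drop = FALSE]
    if (nrow(genotypes) == 0) genotypes <- NULL
  }
  structure(list(patient = patient, medications = medications,
                 comedications = as.character(comedications),
                 genotypes = genotypes),
            class = "pgx_case")
}

#' @export
print.pgx_case <- function(x, ...) {
  id <- if (!is.null(x$patient$id)) paste0(" ", x$patient$id) else ""
  cat(sprintf("PGx consult case%s: %d medication(s), %d co-medication(s), %s\n",
              id, nrow(x$medications), length(x$comedications),
              if (is.null(x$genotypes)) "no genotype results (untested)"
              else sprintf("%d genotype result(s)", nrow(x$genotypes))))
  if (nrow(x$medications) > 0) {
    print(x$medications[, c("name", "status", "trial_adequate", "outcome")],
          row.names = FALSE)
  }
  invisible(x)
}
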