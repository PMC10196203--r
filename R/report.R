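#' Read a patient case file
#'
#' Parses the YAML case schema: a `patient` block (free-form demographic
#' fields), a `medications` list (each with `name`, `status`, `dose`,
#' `duration`, `trial_adequate`, `outcome`), an optional `comedications`
#' list, and an optional `genotypes` list (`gene`, `diplotype`). Schema
#' violations are reported with the offending field path.
#'
#' @param path path to a YAML case file.
#' @return a `pgx_case`; the MD5 digest of the file is recorded for report
#'   provenance.
#' @export
read_case <- function(path) {
  if (!file.exists(path)) .input_stop(sprintf("case file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) .input_stop(
                    sprintf("case file %s is not valid YAML: %s", path,
                            conditionMessage(e))))
  if (!is.list(raw)) .input_stop(sprintf("%s: top level must be a mapping", path))

  meds <- raw$medications
  if (is.null(meds)) meds <- list()
  rows <- lapply(seq_along(meds), function(i) {
    m <- meds[[i]]
    if (is.null(m$name) || !nzchar(trimws(as.character(m$name)))) {
      .input_stop(sprintf("%s: medications[%d].name is required", path, i))
    }
    for (field in c("trial_adequate", "outcome")) {
      if (is.null(m[[field]])) {
        .input_stop(sprintf("%s: medications[%d].%s is required", path, i,
                            field))
      }
    }
    tryCatch(
      medication(m$name, status = m$status %||% "current",
                 dose = m$dose %||% "", duration = m$duration %||% "",
                 trial_adequate = m$trial_adequate, outcome = m$outcome),
      error = function(e) .input_stop(
        sprintf("%s: medications[%d] (%s): %s", path, i, m$name,
                conditionMessage(e))))
  })
  medications <- if (length(rows) > 0) do.call(rbind, rows) else NULL

  genotypes <- NULL
  if (!is.null(raw$genotypes) && length(raw$genotypes) > 0) {
    genotypes <- do.call(rbind, lapply(seq_along(raw$genotypes), function(i) {
      g <- raw$genotypes[[i]]
      if (is.null(g$gene) || is.null(g$diplotype)) {
        .input_stop(sprintf("%s: genotypes[%d] needs gene and diplotype",
                            path, i))
      }
      data.frame(gene = as.character(g$gene),
                 diplotype = as.character(g$diplotype),
                 stringsAsFactors = FALSE)
    }))
  }

  case <- pgx_case(medications,
                   comedications = unlist(raw$comedications) %||% character(),
                   genotypes = genotypes,
                   patient = raw$patient %||% list())
  attr(case, "digests") <- list(case = unname(tools::md5sum(path)))
  case
}

#' Read a genotype results file
#'
#' Tab-separated with a header row and columns `gene` and `diplotype`, one
#' row per gene; `#` comment lines are ignored. Carrier-system genes list
#' the present alleles separated by commas (or `negative`). An empty file
#' (header only, or no rows) represents an untested patient.
#'
#' @param path path to the TSV file.
#' @param kb optional `pgx_kb`; when supplied, rows for genes absent from
#'   the knowledge base trigger a warning (they are carried through and
#'   later treated as indeterminate, never dropped silently).
#' @return a data frame with columns `gene` and `diplotype` (zero rows for
#'   an untested patient).
#' @export
read_genotypes <- function(path, kb = NULL) {
  if (!file.exists(path)) {
    .input_stop(sprintf("genotype file not found: %s", path))
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          quote = "", na.strings = character())
  if (nrow(df) == 0 && ncol(df) == 0) {
    return(data.frame(gene = character(), diplotype = character(),
                      stringsAsFactors = FALSE))
  }
  if (!all(c("gene", "diplotype") %in% names(df))) {
    .input_stop(sprintf("%s: expected columns gene and diplotype", path))
  }
  df <- df[, c("gene", "diplotype"), drop = FALSE]
  if (!is.null(kb)) {
    unknown <- setdiff(df$gene, kb$genes$gene_symbol)
    if (length(unknown) > 0) {
      warning("genotype file lists gene(s) absent from the knowledge base ",
              "(treated as indeterminate): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  df
}

.csv_quote <- function(x) {
  paste0('"', gsub('"', '""', x, fixed = TRUE), '"')
}

.ledger_columns <- c("drug", "status", "guideline", "adequate_trial",
                     "problem", "congruency", "congruency_label", "rationale")

#' Format a consult as canonical CSV text
#'
#' The ledger in consult-step order (medication, guideline, adequate trial,
#' problem, congruency, rationale) followed by the summary lines. Fixed
#' dialect: comma-separated, strings quoted, UTF-8, LF line endings.
#' Timestamps and provenance are excluded so regenerating from the same
#' inputs yields byte-identical text.
#'
#' @param result a `pgx_consult`.
#' @return a single string of CSV text.
#' @export
format_consult_csv <- function(result) {
  stopifnot(inherits(result, "pgx_consult"))
  led <- result$ledger
  header <- paste(.ledger_columns, collapse = ",")
  body <- vapply(seq_len(nrow(led)), function(i) {
    paste(c(.csv_quote(led$drug[i]), .csv_quote(led$status[i]),
            led$guideline[i], led$adequate_trial[i], led$problem[i],
            led$congruency[i], .csv_quote(led$congruency_label[i]),
            .csv_quote(led$rationale[i])), collapse = ",")
  }, character(1))
  summary_lines <- c(
    sprintf("PGxBS,%d", result$pgxbs),
    sprintf("interpretation,%s", result$interpretation),
    sprintf("testing_recommended,%s", tolower(result$testing_recommended)),
    sprintf("n_guideline_meds,%d", result$n_guideline_meds))
  paste0(paste(c(header, body, summary_lines), collapse = "\n"), "\n")
}

.format_consult_markdown <- function(result) {
  led <- result$ledger
  lines <- c("## Structured PGx consult", "",
             "| medication | status | guideline | adequate trial | problem | congruency | rationale |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(led))) {
    lines <- c(lines, sprintf("| %s | %s | %d | %d | %d | %s | %s |",
                              led$drug[i], led$status[i], led$guideline[i],
                              led$adequate_trial[i], led$problem[i],
                              led$congruency_label[i],
                              gsub("|", "/", led$rationale[i], fixed = TRUE)))
  }
  c(lines, "",
    sprintf("**PGxBS: %d** (%s)", result$pgxbs,
            .display_interpretation[[result$interpretation]]),
    sprintf("- guideline-covered medications: %d", result$n_guideline_meds),
    sprintf("- reactive PGx testing recommended: %s",
            tolower(result$testing_recommended)),
    sprintf("- knowledge base: %s", result$provenance$kb_version))
}

#' Write a consult report
#'
#' Serializes a consult to one of three formats derivable from the same
#' result: `csv` (the canonical ledger spreadsheet, see
#' [format_consult_csv()]), `json` (the full structured result including
#' provenance; reloadable with [read_report()]), or `markdown` (a
#' human-readable consult-note section).
#'
#' @param result a `pgx_consult`.
#' @param format `"csv"`, `"json"`, or `"markdown"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, format = c("csv", "json", "markdown"),
                         path) {
  stopifnot(inherits(result, "pgx_consult"))
  format <- match.arg(format)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) .input_stop(
                    sprintf("cannot write report to %s: %s", path,
                            conditionMessage(e))))
  on.exit(close(con))
  if (format == "csv") {
    writeChar(format_consult_csv(result), con, eos = NULL, useBytes = TRUE)
  } else if (format == "json") {
    payload <- list(
      ledger = result$ledger,
      summary = list(pgxbs = result$pgxbs,
                     interpretation = result$interpretation,
                     testing_recommended = result$testing_recommended,
                     n_guideline_meds = result$n_guideline_meds),
      phenoconversion = result$phenoconversion,
      provenance = result$provenance)
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), con, useBytes = TRUE)
  } else {
    writeLines(.format_consult_markdown(result), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Reload a JSON consult report
#'
#' Inverse of `write_report(..., format = "json")` for everything the
#' scoring engine produced: ledger rows, PGxBS, interpretation, testing
#' recommendation, and provenance.
#'
#' @param path path to a JSON report.
#' @return a list with elements `ledger`, `pgxbs`, `interpretation`,
#'   `testing_recommended`, `n_guideline_meds`, `phenoconversion`,
#'   `provenance`.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  ledger <- as.data.frame(x$ledger, stringsAsFactors = FALSE)
  if (nrow(ledger) > 0) {
    for (col in c("guideline", "adequate_trial", "problem", "congruency")) {
      ledger[[col]] <- as.integer(ledger[[col]])
    }
  }
  list(ledger = ledger,
       pgxbs = as.integer(x$summary$pgxbs),
       interpretation = x$summary$interpretation,
       testing_recommended = isTRUE(x$summary$testing_recommended),
       n_guideline_meds = as.integer(x$summary$n_guideline_meds),
       phenoconversion = isTRUE(x$phenoconversion),
       provenance = x$provenance)
}

#' Write a case (and genotypes) in the formats read back by the package
#'
#' @param case a `pgx_case`.
#' @param path output YAML path for the case.
#' @param genotypes_path optional TSV path; when given and the case has
#'   genotype results they are written there (and referenced nowhere in the
#'   YAML: the two files are independent inputs, as in practice).
#' @return `path`, invisibly.
#' @export
write_case <- function(case, path, genotypes_path = NULL) {
  stopifnot(inherits(case, "pgx_case"))
  meds <- case$medications
  med_list <- lapply(seq_len(nrow(meds)), function(i) {
    list(name = meds$name[i], status = meds$status[i], dose = meds$dose[i],
         duration = meds$duration[i],
         trial_adequate = meds$trial_adequate[i], outcome = meds$outcome[i])
  })
  payload <- list(patient = case$patient, medications = med_list,
                  comedications = as.list(case$comedications))
  yaml::write_yaml(payload, path)
  if (!is.null(genotypes_path)) {
    geno <- case$genotypes
    if (is.null(geno)) {
      geno <- data.frame(gene = character(), diplotype = character())
    }
    utils::write.table(geno, genotypes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
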