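# Enumerations used across the knowledge base -------------------------------

.gene_categories <- c("exposure", "response", "safety")
.phenotype_systems <- c("metabolizer", "carrier")
.metabolizer_labels <- c("PM", "IM", "NM", "RM", "UM")
.carrier_labels <- c("positive", "negative")
.function_classes <- c("no_function", "decreased", "normal", "increased",
                       "risk", "non_risk")
.cpic_levels <- c("A", "A_B", "B", "other")
.gene_roles <- c("activating", "inactivating", "target", "immune_risk")
.interaction_strengths <- c("strong_inhibitor", "moderate_inhibitor",
                            "strong_inducer", "moderate_inducer")
.outcomes <- c("poor_efficacy", "adverse_effects")

.kb_files <- c(genes = "genes.tsv",
               allele_functions = "allele_functions.tsv",
               phenotype_bins = "phenotype_bins.tsv",
               drug_gene_rules = "drug_gene_rules.tsv",
               interactions = "interactions.tsv")

#' Normalize a drug name
#'
#' Case-folds and trims whitespace so that knowledge-base lookups are exact
#' and deterministic. No fuzzy or synonym matching is performed; synonyms can
#' be listed in the knowledge base as extra rule rows.
#'
#' @param x character vector of drug names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_drug("  Codeine ")
normalize_drug <- function(x) {
  tolower(trimws(as.character(x)))
}

.kb_stop <- function(msg, class = "pgx_kb_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.read_kb_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    fill = TRUE, quote = "", na.strings = c("NA", ""))
}

.check_enum <- function(values, allowed, what, file) {
  bad <- setdiff(unique(values[!is.na(values)]), allowed)
  if (length(bad) > 0) {
    .kb_stop(sprintf("%s: invalid %s value(s): %s (allowed: %s)",
                     file, what, paste(bad, collapse = ", "),
                     paste(allowed, collapse = ", ")))
  }
}

.check_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    .kb_stop(sprintf("%s: missing column(s): %s",
                     file, paste(missing, collapse = ", ")))
  }
}

#' Load and validate a pharmacogenomics knowledge base
#'
#' Reads the five tab-separated tables (`genes.tsv`, `allele_functions.tsv`,
#' `phenotype_bins.tsv`, `drug_gene_rules.tsv`, `interactions.tsv`) from a
#' directory, validates all structural invariants, and returns a `pgx_kb`
#' object. Lines starting with `#` are ignored. An optional single-line
#' `kb_version.txt` pins the snapshot version.
#'
#' Validation covers, among others: gene uniqueness and category/system
#' consistency (safety-category genes must use the carrier system); allele
#' function classes (risk/non_risk only for carrier genes, activity values
#' present exactly for activity-score genes and lying on the 0.25 grid);
#' phenotype bins partitioning the attainable diplotype activity-score range
#' with no overlap; drug-gene rule role/category consistency (immune_risk
#' implies safety, target implies response, activating/inactivating imply
#' exposure); and interaction rows referring to metabolizer-system genes.
#'
#' @param directory_path path to the knowledge-base directory.
#' @param quiet if `TRUE`, suppress the per-table row-count messages.
#' @return an object of class `pgx_kb`: a list with elements `genes`,
#'   `allele_functions`, `phenotype_bins`, `drug_gene_rules`,
#'   `interactions` (data frames) and `version` (string).
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "kb", package = "pgxbs"))
#' kb
load_kb <- function(directory_path, quiet = FALSE) {
  if (!dir.exists(directory_path)) {
    .kb_stop(sprintf("knowledge-base directory not found: %s", directory_path))
  }
  paths <- file.path(directory_path, .kb_files)
  absent <- !file.exists(paths)
  if (any(absent)) {
    .kb_stop(sprintf("missing table file(s): %s",
                     paste(.kb_files[absent], collapse = ", ")))
  }
  tables <- lapply(paths, .read_kb_table)
  names(tables) <- names(.kb_files)

  version_path <- file.path(directory_path, "kb_version.txt")
  version <- if (file.exists(version_path)) {
    trimws(readLines(version_path, n = 1L, warn = FALSE))
  } else {
    "unversioned"
  }

  kb <- structure(c(tables, list(version = version)), class = "pgx_kb")
  kb$drug_gene_rules$drug_name <- normalize_drug(kb$drug_gene_rules$drug_name)
  kb$interactions$perpetrator_drug <- normalize_drug(kb$interactions$perpetrator_drug)
  validate_kb(kb)
  if (!quiet) {
    counts <- vapply(tables, nrow, integer(1))
    message(sprintf("Loaded knowledge base [%s]: %s", version,
                    paste(sprintf("%s=%d", names(counts), counts),
                          collapse = ", ")))
  }
  kb
}

#' Validate a knowledge-base object
#'
#' Checks every structural invariant of a `pgx_kb` (see [load_kb()]).
#' Called automatically on load; exported so edited knowledge bases can be
#' re-checked.
#'
#' @param kb a `pgx_kb` object.
#' @return `kb`, invisibly, if valid; otherwise an error of class
#'   `pgx_kb_error` naming the offending table, row, and rule.
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "pgx_kb"))
  g <- kb$genes
  .check_cols(g, c("gene_symbol", "category", "phenotype_system",
                   "uses_activity_score"), "genes.tsv")
  if (anyDuplicated(g$gene_symbol)) {
    .kb_stop(sprintf("genes.tsv: duplicated gene_symbol: %s",
                     paste(unique(g$gene_symbol[duplicated(g$gene_symbol)]),
                           collapse = ", ")))
  }
  .check_enum(g$category, .gene_categories, "category", "genes.tsv")
  .check_enum(g$phenotype_system, .phenotype_systems, "phenotype_system",
              "genes.tsv")
  bad <- g$gene_symbol[g$category == "safety" & g$phenotype_system != "carrier"]
  if (length(bad) > 0) {
    .kb_stop(sprintf(
      "genes.tsv: safety-category gene(s) must use the carrier system: %s",
      paste(bad, collapse = ", ")))
  }
  bad <- g$gene_symbol[g$uses_activity_score & g$phenotype_system != "metabolizer"]
  if (length(bad) > 0) {
    .kb_stop(sprintf(
      "genes.tsv: only metabolizer-system genes may use activity scores: %s",
      paste(bad, collapse = ", ")))
  }

  af <- kb$allele_functions
  .check_cols(af, c("gene_symbol", "allele", "function_class"),
              "allele_functions.tsv")
  key <- paste(af$gene_symbol, af$allele)
  if (anyDuplicated(key)) {
    .kb_stop(sprintf("allele_functions.tsv: duplicated (gene, allele): %s",
                     paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  .check_enum(af$function_class, .function_classes, "function_class",
              "allele_functions.tsv")
  unknown <- setdiff(af$gene_symbol, g$gene_symbol)
  if (length(unknown) > 0) {
    .kb_stop(sprintf("allele_functions.tsv: unknown gene(s): %s",
                     paste(unknown, collapse = ", ")))
  }
  system_of <- stats::setNames(g$phenotype_system, g$gene_symbol)
  uses_as <- stats::setNames(g$uses_activity_score, g$gene_symbol)
  carrier_only <- af$function_class %in% c("risk", "non_risk")
  bad <- which(carrier_only & system_of[af$gene_symbol] != "carrier")
  if (length(bad) > 0) {
    .kb_stop(sprintf(
      "allele_functions.tsv row %d: risk/non_risk classes are only valid for carrier-system genes",
      bad[1]))
  }
  bad <- which(!carrier_only & system_of[af$gene_symbol] == "carrier")
  if (length(bad) > 0) {
    .kb_stop(sprintf(
      "allele_functions.tsv row %d: carrier-system alleles must be risk/non_risk",
      bad[1]))
  }
  needs_value <- uses_as[af$gene_symbol]
  if (!"activity_value" %in% names(af)) af$activity_value <- NA_real_
  bad <- which(needs_value & is.na(af$activity_value))
  if (length(bad) > 0) {
    .kb_stop(sprintf(
      "allele_functions.tsv row %d: activity_value required for activity-score gene %s",
      bad[1], af$gene_symbol[bad[1]]))
  }
  bad <- which(!needs_value & !is.na(af$activity_value))
  if (length(bad) > 0) {
    .kb_stop(sprintf(
      "allele_functions.tsv row %d: activity_value not allowed for gene %s",
      bad[1], af$gene_symbol[bad[1]]))
  }
  v <- af$activity_value[!is.na(af$activity_value)]
  if (any(v < 0) || any(abs(v / 0.25 - round(v / 0.25)) > 1e-9)) {
    .kb_stop("allele_functions.tsv: activity_value must be a nonnegative multiple of 0.25")
  }

  pb <- kb$phenotype_bins
  .check_cols(pb, c("gene_symbol", "phenotype_label", "lower_bound",
                    "upper_bound"), "phenotype_bins.tsv")
  unknown <- setdiff(pb$gene_symbol, g$gene_symbol)
  if (length(unknown) > 0) {
    .kb_stop(sprintf("phenotype_bins.tsv: unknown gene(s): %s",
                     paste(unknown, collapse = ", ")))
  }
  .check_enum(pb$phenotype_label, .metabolizer_labels, "phenotype_label",
              "phenotype_bins.tsv")
  bad <- setdiff(unique(pb$gene_symbol),
                 g$gene_symbol[g$phenotype_system == "metabolizer"])
  if (length(bad) > 0) {
    .kb_stop(sprintf("phenotype_bins.tsv: bins defined for non-metabolizer gene(s): %s",
                     paste(bad, collapse = ", ")))
  }
  for (gene in unique(pb$gene_symbol)) {
    bins <- pb[pb$gene_symbol == gene, , drop = FALSE]
    if (any(bins$lower_bound > bins$upper_bound)) {
      .kb_stop(sprintf("phenotype_bins.tsv (%s): lower_bound > upper_bound", gene))
    }
    bins <- bins[order(bins$lower_bound), , drop = FALSE]
    n <- nrow(bins)
    if (n > 1 && any(bins$upper_bound[-n] >= bins$lower_bound[-1])) {
      .kb_stop(sprintf(
        "phenotype_bins.tsv (%s): bins overlap; bins must partition the activity-score range",
        gene))
    }
    # every attainable diplotype score must fall in exactly one bin
    vals <- af$activity_value[af$gene_symbol == gene]
    vals <- vals[!is.na(vals)]
    if (length(vals) > 0) {
      sums <- unique(as.vector(outer(vals, vals, `+`)))
      hits <- vapply(sums, function(s)
        sum(s >= bins$lower_bound & s <= bins$upper_bound), integer(1))
      if (any(hits != 1L)) {
        .kb_stop(sprintf(
          "phenotype_bins.tsv (%s): attainable activity score %s falls in %d bins (must be exactly 1)",
          gene, format(sums[hits != 1L][1]), hits[hits != 1L][1]))
      }
    }
  }

  dg <- kb$drug_gene_rules
  .check_cols(dg, c("drug_name", "gene_symbol", "cpic_level", "gene_role"),
              "drug_gene_rules.tsv")
  key <- paste(dg$drug_name, dg$gene_symbol)
  if (anyDuplicated(key)) {
    .kb_stop(sprintf("drug_gene_rules.tsv: duplicated (drug, gene): %s",
                     paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  .check_enum(dg$cpic_level, .cpic_levels, "cpic_level", "drug_gene_rules.tsv")
  .check_enum(dg$gene_role, .gene_roles, "gene_role", "drug_gene_rules.tsv")
  unknown <- setdiff(dg$gene_symbol, g$gene_symbol)
  if (length(unknown) > 0) {
    .kb_stop(sprintf("drug_gene_rules.tsv: unknown gene(s): %s",
                     paste(unknown, collapse = ", ")))
  }
  category_of <- stats::setNames(g$category, g$gene_symbol)
  required <- c(activating = "exposure", inactivating = "exposure",
                target = "response", immune_risk = "safety")
  bad <- which(category_of[dg$gene_symbol] != required[dg$gene_role])
  if (length(bad) > 0) {
    .kb_stop(sprintf(
      "drug_gene_rules.tsv row %d: gene_role %s requires a %s-category gene (%s is %s)",
      bad[1], dg$gene_role[bad[1]], required[dg$gene_role[bad[1]]],
      dg$gene_symbol[bad[1]], category_of[dg$gene_symbol[bad[1]]]))
  }

  ix <- kb$interactions
  .check_cols(ix, c("perpetrator_drug", "gene_symbol", "strength"),
              "interactions.tsv")
  key <- paste(ix$perpetrator_drug, ix$gene_symbol)
  if (anyDuplicated(key)) {
    .kb_stop(sprintf("interactions.tsv: duplicated (perpetrator, gene): %s",
                     paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  .check_enum(ix$strength, .interaction_strengths, "strength",
              "interactions.tsv")
  bad <- setdiff(unique(ix$gene_symbol),
                 g$gene_symbol[g$phenotype_system == "metabolizer"])
  if (length(bad) > 0) {
    .kb_stop(sprintf(
      "interactions.tsv: phenoconversion applies only to metabolizer-system genes; invalid: %s",
      paste(bad, collapse = ", ")))
  }
  invisible(kb)
}

#' Write a knowledge base back to a directory
#'
#' Serializes a `pgx_kb` to the same five-table tab-separated layout read by
#' [load_kb()], so that load -> write -> load round-trips to an identical
#' knowledge base.
#'
#' @param kb a `pgx_kb` object.
#' @param directory_path output directory (created if needed).
#' @return `directory_path`, invisibly.
#' @export
write_kb <- function(kb, directory_path) {
  stopifnot(inherits(kb, "pgx_kb"))
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(.kb_files)) {
    utils::write.table(kb[[nm]], file.path(directory_path, .kb_files[nm]),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  writeLines(kb$version, file.path(directory_path, "kb_version.txt"))
  invisible(directory_path)
}

#' @export
print.pgx_kb <- function(x, ...) {
  cat("Pharmacogenomics knowledge base [", x$version, "]\n", sep = "")
  cat(sprintf("  genes: %d (%d metabolizer, %d carrier)\n", nrow(x$genes),
              sum(x$genes$phenotype_system == "metabolizer"),
              sum(x$genes$phenotype_system == "carrier")))
  cat(sprintf("  allele functions: %d\n", nrow(x$allele_functions)))
  cat(sprintf("  drug-gene rules: %d (%d at CPIC level A/A_B, %d drugs)\n",
              nrow(x$drug_gene_rules),
              sum(x$drug_gene_rules$cpic_level %in% c("A", "A_B")),
              length(unique(x$drug_gene_rules$drug_name))))
  cat(sprintf("  interactions: %d\n", nrow(x$interactions)))
  invisible(x)
}

#' Is a PGx guideline available for a drug?
#'
#' Consult step 2: a guideline is "available" when at least one drug-gene
#' rule for the drug carries CPIC level A or A/B evidence. Unknown drugs
#' return 0 (the "no/unsure" convention), never an error.
#'
#' @param drug_name drug name (normalized internally).
#' @param kb a `pgx_kb`.
#' @return a list with `available` (integer 0/1) and `rules` (the matched
#'   level-A/A_B rule rows; zero rows when `available` is 0).
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "kb", package = "pgxbs"), quiet = TRUE)
#' guideline_available("codeine", kb)$available
guideline_available <- function(drug_name, kb) {
  stopifnot(inherits(kb, "pgx_kb"))
  drug <- normalize_drug(drug_name)
  dg <- kb$drug_gene_rules
  rules <- dg[dg$drug_name == drug & dg$cpic_level %in% c("A", "A_B"), ,
              drop = FALSE]
  list(available = as.integer(nrow(rules) > 0), rules = rules)
}

.gene_def <- function(gene_symbol, kb) {
  row <- kb$genes[kb$genes$gene_symbol == gene_symbol, , drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  as.list(row[1, ])
}

#' Construct a phenotype call
#'
#' Low-level constructor for a `pgx_phenotype` object, used internally by
#' [predict_phenotype()] and exposed for programmatic construction (for
#' example when enumerating the congruency grid in tests).
#'
#' @param gene gene symbol.
#' @param phenotype one of `PM`, `IM`, `NM`, `RM`, `UM`, `positive`,
#'   `negative`, or `indeterminate`.
#' @param diplotype the raw diplotype string (optional).
#' @param activity_score numeric activity score or `NA`.
#' @param system `"metabolizer"` or `"carrier"`.
#' @return a `pgx_phenotype` object.
#' @export
phenotype_call <- function(gene, phenotype, diplotype = NA_character_,
                           activity_score = NA_real_,
                           system = if (phenotype %in% .carrier_labels)
                             "carrier" else "metabolizer") {
  stopifnot(phenotype %in% c(.metabolizer_labels, .carrier_labels,
                             "indeterminate"))
  structure(list(gene = gene, diplotype = diplotype, system = system,
                 activity_score = activity_score, phenotype = phenotype,
                 indeterminate = identical(phenotype, "indeterminate"),
                 phenoconverted = FALSE, perpetrators = NULL,
                 base_phenotype = NULL),
            class = "pgx_phenotype")
}

#' @export
print.pgx_phenotype <- function(x, ...) {
  score <- if (is.na(x$activity_score)) "" else
    sprintf(" (activity score %s)", format(x$activity_score))
  conv <- if (isTRUE(x$phenoconverted))
    sprintf(" [phenoconverted from %s by %s]", x$base_phenotype,
            paste(x$perpetrators$perpetrator_drug, collapse = ", ")) else ""
  cat(sprintf("%s %s: %s%s%s\n", x$gene,
              if (is.na(x$diplotype)) "" else x$diplotype,
              x$phenotype, score, conv))
  invisible(x)
}

.bin_label <- function(gene, score, kb) {
  bins <- kb$phenotype_bins[kb$phenotype_bins$gene_symbol == gene, ,
                            drop = FALSE]
  bins <- bins[order(bins$lower_bound), , drop = FALSE]
  # first bin whose upper bound covers the score; reproduces the half-open
  # consensus convention for off-grid scores produced by phenoconversion
  hit <- which(score <= bins$upper_bound + 1e-9)
  if (length(hit) == 0) return(bins$phenotype_label[nrow(bins)])
  bins$phenotype_label[hit[1]]
}

#' Translate a diplotype into a genotype-predicted phenotype
#'
#' For metabolizer-system genes the diplotype must parse as
#' `"alleleA/alleleB"`; the activity score is the sum of the two allele
#' activity values and the phenotype is the activity-score bin containing
#' that sum. For carrier-system genes the input is a comma-separated list of
#' present alleles (an optional trailing word `present` is tolerated), or
#' `negative`/`none` for no notable alleles; the call is positive iff any
#' risk allele is present.
#'
#' An allele absent from the allele-function table yields an
#' **indeterminate** call (flagged, never silently treated as normal).
#' A malformed diplotype is an error.
#'
#' @param gene_symbol gene symbol present in the knowledge base.
#' @param diplotype diplotype or allele-presence string.
#' @param kb a `pgx_kb`.
#' @return a `pgx_phenotype` object.
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "kb", package = "pgxbs"), quiet = TRUE)
#' predict_phenotype("CYP2D6", "*1/*1x2", kb)
#' predict_phenotype("HLA-B", "B*58:01 present", kb)
predict_phenotype <- function(gene_symbol, diplotype, kb) {
  stopifnot(inherits(kb, "pgx_kb"))
  gdef <- .gene_def(gene_symbol, kb)
  if (is.null(gdef)) {
    return(phenotype_call(gene_symbol, "indeterminate", diplotype,
                          system = "metabolizer"))
  }
  af <- kb$allele_functions[kb$allele_functions$gene_symbol == gene_symbol, ,
                            drop = FALSE]
  diplotype <- trimws(diplotype)
  if (identical(gdef$phenotype_system, "metabolizer")) {
    parts <- trimws(strsplit(diplotype, "/", fixed = TRUE)[[1]])
    if (length(parts) != 2 || any(parts == "")) {
      .kb_stop(sprintf(
        "malformed diplotype for %s: %s (expected \"alleleA/alleleB\")",
        gene_symbol, diplotype), class = "pgx_input_error")
    }
    idx <- match(parts, af$allele)
    if (anyNA(idx)) {
      out <- phenotype_call(gene_symbol, "indeterminate", diplotype,
                            system = "metabolizer")
      return(out)
    }
    score <- sum(af$activity_value[idx])
    phenotype_call(gene_symbol, .bin_label(gene_symbol, score, kb),
                   diplotype, activity_score = score, system = "metabolizer")
  } else {
    cleaned <- sub("\\s+present$", "", diplotype, ignore.case = TRUE)
    if (tolower(cleaned) %in% c("negative", "none", "")) {
      return(phenotype_call(gene_symbol, "negative", diplotype,
                            system = "carrier"))
    }
    alleles <- trimws(strsplit(cleaned, ",", fixed = TRUE)[[1]])
    alleles <- alleles[alleles != ""]
    idx <- match(alleles, af$allele)
    classes <- af$function_class[idx]
    if (any(classes %in% "risk", na.rm = TRUE)) {
      label <- "positive"
    } else if (anyNA(idx)) {
      label <- "indeterminate"
    } else {
      label <- "negative"
    }
    phenotype_call(gene_symbol, label, diplotype, system = "carrier")
  }
}
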