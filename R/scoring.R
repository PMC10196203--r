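.interpretations <- c("possible_pgx_contribution", "pgx_less_likely")

#' Step 3: assess adequacy of a therapeutic trial
#'
#' Binary answer to "did the patient have an adequate therapeutic trial?".
#' Inadequate trials from underdosing or short treatment durations are
#' common; the "no/unsure" convention maps both to 0.
#'
#' @param med a medication record (one-row data frame from [medication()])
#'   or the `trial_adequate` value itself.
#' @return integer 0 or 1.
#' @export
assess_adequacy <- function(med) {
  x <- if (is.data.frame(med)) med$trial_adequate[1] else med
  as.integer(.normalize_trial(x) == "yes")
}

#' Step 4: determine the therapeutic outcome
#'
#' Two types of medication-related problems indicate negative therapeutic
#' outcomes that genetics could explain: unexpected poor efficacy and
#' intolerable adverse effects. Either scores 1; a good or unknown outcome
#' scores 0.
#'
#' @param med a medication record (one-row data frame) or the `outcome`
#'   value itself.
#' @return integer 0 or 1.
#' @export
assess_outcome <- function(med) {
  x <- if (is.data.frame(med)) med$outcome[1] else med
  x <- match.arg(as.character(x), .outcome_levels)
  as.integer(x %in% .outcomes)
}

#' Outcomes mechanistically predicted by a phenotype under a drug-gene rule
#'
#' The direction table behind step-5 congruency. Extreme exposure drives
#' the prediction: for an **activating** role (prodrug), reduced enzyme
#' activity (PM/IM) predicts poor efficacy and excess activity (RM/UM)
#' predicts adverse effects; for an **inactivating** role (clearance) the
#' directions flip. An **immune_risk** carrier predicts adverse effects
#' (severe cutaneous reactions); a **target**-gene non-responder variant
#' carrier predicts poor efficacy. A normal metabolizer, non-carrier, or
#' indeterminate phenotype predicts neither problem.
#'
#' @param rule a one-row drug-gene rule (from `kb$drug_gene_rules` or
#'   [guideline_available()]`$rules`).
#' @param phenotype a `pgx_phenotype` for the rule's gene.
#' @return character vector, a subset of
#'   `c("poor_efficacy", "adverse_effects")` (possibly empty).
#' @export
expected_outcomes <- function(rule, phenotype) {
  stopifnot(inherits(phenotype, "pgx_phenotype"))
  rule <- as.list(as.data.frame(rule)[1, ])
  if (!identical(rule$gene_symbol, phenotype$gene)) {
    stop("rule gene (", rule$gene_symbol, ") and phenotype gene (",
         phenotype$gene, ") differ")
  }
  label <- phenotype$phenotype
  if (identical(label, "indeterminate")) return(character(0))
  switch(rule$gene_role,
    activating = if (label %in% c("PM", "IM")) "poor_efficacy"
                 else if (label %in% c("RM", "UM")) "adverse_effects"
                 else character(0),
    inactivating = if (label %in% c("PM", "IM")) "adverse_effects"
                   else if (label %in% c("RM", "UM")) "poor_efficacy"
                   else character(0),
    immune_risk = if (identical(label, "positive")) "adverse_effects"
                  else character(0),
    target = if (identical(label, "positive")) "poor_efficacy"
             else character(0),
    stop("unknown gene_role: ", rule$gene_role))
}

.phenotype_brief <- function(p) {
  conv <- if (isTRUE(p$phenoconverted))
    sprintf(" phenoconverted from %s", p$base_phenotype) else ""
  note <- if (!is.null(p$note)) sprintf(" (%s)", p$note) else ""
  dip <- if (is.na(p$diplotype) || p$diplotype == "") "" else
    paste0(" ", p$diplotype)
  sprintf("%s%s %s%s%s", p$gene, dip, p$phenotype, conv, note)
}

#' Step 5: adjudicate congruency between a problem and the genotype
#'
#' A medication-related problem is **congruent** (+1) when it is among the
#' outcomes mechanistically predicted by the patient's phenotype for at
#' least one of the drug's guideline genes (any-gene disjunction: for a
#' multi-gene drug one congruent gene carries the call), and
#' **incongruent** (-1) otherwise — including the case where the genotype
#' predicts no problem at all (e.g. a normal metabolizer), since the
#' genotype then fails to explain the problem. If every guideline gene's
#' phenotype is indeterminate the result is 0 (`not_scored`): an unknown
#' genotype cannot contradict an outcome.
#'
#' @param drug drug name with at least one CPIC level A/A_B rule in `kb`.
#' @param phenotypes a `pgx_phenotype` or list of them, covering the drug's
#'   guideline genes (a missing gene is treated as indeterminate).
#' @param observed `"poor_efficacy"` or `"adverse_effects"`.
#' @param kb a `pgx_kb`.
#' @return integer `+1`, `-1`, or `0` (all genes indeterminate), with
#'   attributes `rationale` (string naming genes, phenotypes, and the rule
#'   applied) and `expected` (the union of predicted outcomes).
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "kb", package = "pgxbs"), quiet = TRUE)
#' um <- predict_phenotype("CYP2D6", "*1/*1x2", kb)
#' assess_congruency("codeine", um, "poor_efficacy", kb)
assess_congruency <- function(drug, phenotypes, observed, kb) {
  stopifnot(inherits(kb, "pgx_kb"))
  observed <- match.arg(observed, .outcomes)
  if (inherits(phenotypes, "pgx_phenotype")) phenotypes <- list(phenotypes)
  stopifnot(all(vapply(phenotypes, inherits, logical(1), "pgx_phenotype")))
  g <- guideline_available(drug, kb)
  if (g$available != 1L) {
    stop("assess_congruency requires a drug with a CPIC A/A_B rule; ",
         normalize_drug(drug), " has none")
  }
  rules <- g$rules
  genes <- vapply(phenotypes, function(p) p$gene, character(1))
  expected <- character(0)
  pieces <- character(0)
  n_indeterminate <- 0L
  for (i in seq_len(nrow(rules))) {
    rule <- rules[i, , drop = FALSE]
    j <- match(rule$gene_symbol, genes)
    p <- if (is.na(j)) {
      phenotype_call(rule$gene_symbol, "indeterminate",
                     system = "metabolizer")
    } else {
      phenotypes[[j]]
    }
    if (p$indeterminate) {
      n_indeterminate <- n_indeterminate + 1L
      pieces <- c(pieces, sprintf("%s indeterminate (no interpretable result)",
                                  rule$gene_symbol))
      next
    }
    exp_i <- expected_outcomes(rule, p)
    expected <- union(expected, exp_i)
    pieces <- c(pieces, sprintf("%s (%s role) predicts %s",
                                .phenotype_brief(p), rule$gene_role,
                                if (length(exp_i) == 0) "no problem"
                                else paste(exp_i, collapse = "+")))
  }
  if (n_indeterminate == nrow(rules)) {
    score <- 0L
    verdict <- "not scored: genotype indeterminate for every guideline gene"
  } else if (observed %in% expected) {
    score <- 1L
    verdict <- sprintf("observed %s => congruent (+1)", observed)
  } else {
    score <- -1L
    verdict <- sprintf("observed %s => incongruent (-1)", observed)
  }
  structure(score,
            rationale = paste(c(pieces, verdict), collapse = "; "),
            expected = expected)
}

#' Step 6 threshold: interpret a PGx benefit score
#'
#' Scores of 1 or more indicate a possible contribution of genetics to the
#' patient's medication-related problems; zero and negative scores mean a
#' genetic cause is less likely.
#'
#' @param pgxbs integer score (vectorized).
#' @return character vector: `"possible_pgx_contribution"` or
#'   `"pgx_less_likely"`.
#' @export
interpret_pgxbs <- function(pgxbs) {
  ifelse(pgxbs >= 1, "possible_pgx_contribution", "pgx_less_likely")
}

#' Recommend reactive PGx testing for an untested patient
#'
#' For patients with medication-related problems who have not been tested,
#' two or more medications with PGx guidelines is the suggested cut-off for
#' reactive testing. Counts distinct medications (by normalized name) with
#' at least one CPIC level A/A_B rule.
#'
#' @param case a `pgx_case` (genotypes, if present, are ignored for the
#'   count; the recommendation is meaningful pre-testing).
#' @param kb a `pgx_kb`.
#' @return list with `recommended` (logical) and `n_guideline_meds`
#'   (integer).
#' @export
recommend_testing <- function(case, kb) {
  stopifnot(inherits(case, "pgx_case"), inherits(kb, "pgx_kb"))
  drugs <- unique(normalize_drug(case$medications$name))
  n <- sum(vapply(drugs, function(d) guideline_available(d, kb)$available,
                  integer(1)))
  list(recommended = n >= 2L, n_guideline_meds = as.integer(n))
}

.congruency_labels <- c(`1` = "congruent", `-1` = "incongruent",
                        `0` = "not_scored")

#' Run a structured PGx consult and compute the PGx benefit score
#'
#' Executes the six consult steps for every medication in the case, in
#' input order, and sums the per-medication congruency scores into the
#' PGx benefit score (PGxBS):
#'
#' 1. medication history (current and past medications score identically;
#'    duplicate entries are collapsed to one row by normalized name,
#'    keeping the first);
#' 2. guideline availability — CPIC level A or A/B evidence (0/1);
#' 3. adequacy of the therapeutic trial (0/1; no/unsure scores 0);
#' 4. medication-related problem — unexpected poor efficacy or intolerable
#'    adverse effects (0/1);
#' 5. congruency between the problem and the genotype-predicted phenotype
#'    (+1 congruent / -1 incongruent), only for medications passing steps
#'    2-4 and only when the patient has genotype results;
#' 6. PGxBS = sum of +1/-1 rows; scores >= 1 indicate a possible PGx
#'    contribution.
#'
#' For an untested patient every row is `not_scored` and the reactive
#' testing recommendation (two or more guideline-covered medications) is
#' computed instead.
#'
#' @param case a `pgx_case`.
#' @param genotypes optional data frame (`gene`, `diplotype`) overriding
#'   `case$genotypes`; `NULL` means use the case's own results.
#' @param kb a `pgx_kb`.
#' @param phenoconversion if `TRUE`, score congruency with the
#'   co-medication-adjusted (phenoconverted) phenotype; if `FALSE` (the
#'   default) score with the raw genotype-predicted phenotype and only note
#'   phenoconversion in the rationale.
#' @return an object of class `pgx_consult`: list with `ledger` (one row
#'   per medication: drug, status, the step 2-4 flags, `congruency`
#'   (+1/-1/0), `congruency_label`, `rationale`), `pgxbs`,
#'   `interpretation`, `testing_recommended`, `n_guideline_meds`,
#'   `phenotypes` (per-gene calls actually used), `case`, and `provenance`.
#' @seealso [summary.pgx_consult()], [write_report()]
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "kb", package = "pgxbs"), quiet = TRUE)
#' case <- read_case(system.file("extdata", "example_case.yaml",
#'                               package = "pgxbs"))
#' geno <- read_genotypes(system.file("extdata", "example_genotypes.tsv",
#'                                    package = "pgxbs"))
#' fit <- pgx_consult(case, geno, kb)
#' fit
pgx_consult <- function(case, genotypes = NULL, kb,
                        phenoconversion = FALSE) {
  stopifnot(inherits(case, "pgx_case"), inherits(kb, "pgx_kb"))
  if (is.null(genotypes)) genotypes <- case$genotypes
  if (!is.null(genotypes)) {
    genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
    if (nrow(genotypes) == 0) genotypes <- NULL
  }
  has_genotypes <- !is.null(genotypes)

  meds <- case$medications
  keep <- !duplicated(normalize_drug(meds$name))
  meds <- meds[keep, , drop = FALSE]

  # one phenotype call per tested gene: raw and co-medication-adjusted
  calls <- list()
  if (has_genotypes) {
    for (i in seq_len(nrow(genotypes))) {
      gene <- genotypes$gene[i]
      raw <- predict_phenotype(gene, genotypes$diplotype[i], kb)
      adj <- raw
      if (identical(raw$system, "metabolizer") && !raw$indeterminate &&
          length(case$comedications) > 0) {
        adj <- apply_phenoconversion(raw, case$comedications, kb)
      }
      calls[[gene]] <- list(raw = raw, adjusted = adj)
    }
  }

  lookup_call <- function(gene) {
    entry <- calls[[gene]]
    if (is.null(entry)) {
      return(phenotype_call(gene, "indeterminate", system = "metabolizer"))
    }
    if (phenoconversion) entry$adjusted else entry$raw
  }

  n <- nrow(meds)
  ledger <- data.frame(
    drug = character(n), status = character(n),
    guideline = integer(n), adequate_trial = integer(n),
    problem = integer(n), congruency = integer(n),
    congruency_label = character(n), rationale = character(n),
    stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    med <- meds[i, , drop = FALSE]
    g <- guideline_available(med$name, kb)
    gflag <- g$available
    aflag <- assess_adequacy(med)
    oflag <- assess_outcome(med)
    score <- 0L
    if (gflag == 0L) {
      rationale <- "no CPIC level A/A_B guideline; not scored"
    } else if (aflag == 0L) {
      rationale <- "inadequate or unsure therapeutic trial; not scored"
    } else if (oflag == 0L) {
      rationale <- "no medication-related problem recorded; not scored"
    } else if (!has_genotypes) {
      rationale <- "no genotype results on file; not scored"
    } else {
      phens <- lapply(g$rules$gene_symbol, lookup_call)
      # note phenoconversion in the rationale even when scoring on raw calls
      if (!phenoconversion && length(case$comedications) > 0) {
        for (k in seq_along(phens)) {
          entry <- calls[[phens[[k]]$gene]]
          if (!is.null(entry) && isTRUE(entry$adjusted$phenoconverted)) {
            phens[[k]]$note <- sprintf(
              "functionally %s via %s", entry$adjusted$phenotype,
              paste(entry$adjusted$perpetrators$perpetrator_drug,
                    collapse = ", "))
          }
        }
      }
      score <- assess_congruency(med$name, phens, med$outcome, kb)
      rationale <- attr(score, "rationale")
      score <- as.integer(score)
    }
    ledger[i, ] <- list(normalize_drug(med$name), med$status, gflag, aflag,
                        oflag, score,
                        .congruency_labels[as.character(score)], rationale)
  }

  rec <- recommend_testing(pgx_case(meds), kb)
  pgxbs <- sum(ledger$congruency)
  structure(list(
    ledger = ledger,
    pgxbs = as.integer(pgxbs),
    interpretation = interpret_pgxbs(pgxbs),
    testing_recommended = !has_genotypes && rec$recommended,
    n_guideline_meds = rec$n_guideline_meds,
    phenotypes = calls,
    genotypes = genotypes,
    phenoconversion = phenoconversion,
    case = case,
    provenance = list(
      kb_version = kb$version,
      engine_version = as.character(utils::packageVersion("pgxbs")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      input_digests = attr(case, "digests") %||% list())
  ), class = "pgx_consult")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
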