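#' Default synthetic allele frequencies
#'
#' Round-number frequencies used by [simulate_cases()]. These are synthetic
#' conveniences for exercising every scoring path, **not** population
#' estimates. Metabolizer genes map allele name to sampling frequency
#' (summing to 1); carrier genes map each notable allele to an independent
#' carriage probability.
#'
#' @export
default_allele_frequencies <- list(
  CYP2D6  = c("*1" = 0.40, "*2" = 0.15, "*4" = 0.20, "*10" = 0.10,
              "*41" = 0.10, "*1x2" = 0.05),
  CYP2C19 = c("*1" = 0.60, "*2" = 0.20, "*17" = 0.20),
  CYP2C9  = c("*1" = 0.70, "*2" = 0.20, "*3" = 0.10),
  TPMT    = c("*1" = 0.90, "*3A" = 0.10),
  NUDT15  = c("*1" = 0.95, "*3" = 0.05),
  SLCO1B1 = c("*1" = 0.80, "*5" = 0.20),
  `HLA-B` = c("B*58:01" = 0.05, "B*57:01" = 0.05, "B*15:02" = 0.04),
  IFNL3   = c("rs12979860T" = 0.35)
)

# Congruency direction grid encoded independently of expected_outcomes():
# generator-vs-engine agreement is a genuine two-implementation check.
.sim_direction <- list(
  activating = list(PM = "poor_efficacy", IM = "poor_efficacy",
                    NM = character(0), RM = "adverse_effects",
                    UM = "adverse_effects"),
  inactivating = list(PM = "adverse_effects", IM = "adverse_effects",
                      NM = character(0), RM = "poor_efficacy",
                      UM = "poor_efficacy"),
  immune_risk = list(positive = "adverse_effects", negative = character(0)),
  target = list(positive = "poor_efficacy", negative = character(0))
)

.sim_nonguideline_drugs <- c("paracetamol", "ibuprofen", "metoprolol")

.draw_genotype_row <- function(gene, freqs, system) {
  if (identical(system, "metabolizer")) {
    alleles <- sample(names(freqs), 2, replace = TRUE, prob = freqs)
    paste(alleles, collapse = "/")
  } else {
    present <- names(freqs)[stats::runif(length(freqs)) < freqs]
    if (length(present) == 0) "negative" else paste(present, collapse = ",")
  }
}

#' Generate synthetic consult cases with planted congruency structure
#'
#' Every generated case carries a ground-truth label per medication
#' (congruent / incongruent / not_scored) and the implied expected PGxBS,
#' so the scoring engine can be validated by exact recovery: engine PGxBS
#' must equal planted PGxBS for every case and seed. The planting logic
#' uses its own literal congruency direction grid, independent of the
#' scoring engine's [expected_outcomes()].
#'
#' Per case: genotypes are drawn from `allele_frequencies`; a random subset
#' of drugs is prescribed; each guideline-covered, adequately trialled
#' medication's problem is drawn **from** the outcomes its drawn phenotype
#' predicts with probability `congruent_fraction` (planting congruence) or
#' from the complement otherwise (planting incongruence). A phenotype that
#' predicts no problem (e.g. a normal metabolizer) is planted incongruent,
#' recorded truthfully; a phenotype predicting both problems (possible for
#' multi-gene drugs) forces a congruent plant, recorded truthfully.
#'
#' @param kb a `pgx_kb`.
#' @param n_cases number of cases.
#' @param meds_per_case integer range `c(min, max)` of medications drawn
#'   per case (distinct drugs).
#' @param congruent_fraction probability p of planting congruence for a
#'   scoreable medication.
#' @param fraction_inadequate probability a guideline medication gets an
#'   inadequate/unsure trial (hence not scored).
#' @param fraction_untested probability a case has no genotype results.
#' @param seed integer seed; identical configuration implies identical
#'   cases. The caller's RNG state is restored on exit.
#' @param allele_frequencies per-gene allele frequency map (see
#'   [default_allele_frequencies]); metabolizer-gene frequencies must sum
#'   to 1 (tolerance 1e-9).
#' @return an object of class `pgx_simulation`: list with `cases` (each a
#'   list of `case` (`pgx_case`), `truth` (`labels` data frame and
#'   `expected_pgxbs`)) and `config`.
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "kb", package = "pgxbs"), quiet = TRUE)
#' sim <- simulate_cases(kb, n_cases = 3, seed = 7)
#' sim$cases[[1]]$truth$expected_pgxbs
simulate_cases <- function(kb, n_cases = 100, meds_per_case = c(2, 5),
                           congruent_fraction = 0.5,
                           fraction_inadequate = 0.2,
                           fraction_untested = 0.1, seed = 1,
                           allele_frequencies = default_allele_frequencies) {
  stopifnot(inherits(kb, "pgx_kb"), n_cases >= 1,
            length(meds_per_case) == 2, meds_per_case[1] >= 1,
            meds_per_case[1] <= meds_per_case[2])
  for (p in c(congruent_fraction, fraction_inadequate, fraction_untested)) {
    stopifnot(p >= 0, p <= 1)
  }
  system_of <- stats::setNames(kb$genes$phenotype_system,
                               kb$genes$gene_symbol)
  genes <- intersect(names(allele_frequencies), kb$genes$gene_symbol)
  for (gene in genes) {
    if (identical(system_of[[gene]], "metabolizer")) {
      s <- sum(allele_frequencies[[gene]])
      if (abs(s - 1) > 1e-9) {
        stop("allele frequencies for ", gene, " sum to ", format(s),
             ", not 1")
      }
      unknown <- setdiff(names(allele_frequencies[[gene]]),
                         kb$allele_functions$allele[
                           kb$allele_functions$gene_symbol == gene])
      if (length(unknown) > 0) {
        stop("allele frequencies for ", gene, " name allele(s) absent from ",
             "the knowledge base: ", paste(unknown, collapse = ", "))
      }
    }
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)

  dg <- kb$drug_gene_rules
  guideline_drugs <- sort(unique(dg$drug_name[dg$cpic_level %in% c("A", "A_B")]))
  drug_pool <- c(guideline_drugs,
                 setdiff(.sim_nonguideline_drugs, guideline_drugs))

  cases <- vector("list", n_cases)
  for (ci in seq_len(n_cases)) {
    untested <- stats::runif(1) < fraction_untested
    geno <- data.frame(
      gene = genes,
      diplotype = vapply(genes, function(g)
        .draw_genotype_row(g, allele_frequencies[[g]], system_of[[g]]),
        character(1)),
      stringsAsFactors = FALSE, row.names = NULL)

    # phenotype labels resolved lazily: only genes behind drawn drugs
    label_cache <- new.env(parent = emptyenv())
    label_for <- function(g) {
      if (is.null(label_cache[[g]])) {
        label_cache[[g]] <- predict_phenotype(
          g, geno$diplotype[geno$gene == g], kb)$phenotype
      }
      label_cache[[g]]
    }

    n_meds <- meds_per_case[1] +
      sample.int(meds_per_case[2] - meds_per_case[1] + 1L, 1L) - 1L
    drugs <- sample(drug_pool, min(n_meds, length(drug_pool)))

    med_rows <- vector("list", length(drugs))
    planted <- character(length(drugs))
    for (di in seq_along(drugs)) {
      drug <- drugs[di]
      rules <- dg[dg$drug_name == drug & dg$cpic_level %in% c("A", "A_B"), ,
                  drop = FALSE]
      if (nrow(rules) == 0) {
        trial <- "yes"
        outcome <- sample(c(.outcomes, "none_or_unknown"), 1)
        planted[di] <- "not_scored"
      } else if (stats::runif(1) < fraction_inadequate) {
        trial <- sample(c("no", "unsure"), 1)
        outcome <- sample(.outcomes, 1)
        planted[di] <- "not_scored"
      } else if (untested) {
        trial <- "yes"
        outcome <- sample(.outcomes, 1)
        planted[di] <- "not_scored"
      } else {
        trial <- "yes"
        expected <- character(0)
        for (ri in seq_len(nrow(rules))) {
          lab <- label_for(rules$gene_symbol[ri])
          expected <- union(expected,
                            .sim_direction[[rules$gene_role[ri]]][[lab]])
        }
        complement <- setdiff(.outcomes, expected)
        if (length(expected) == 0) {
          outcome <- sample(.outcomes, 1)
          planted[di] <- "incongruent"
        } else if (length(complement) == 0) {
          outcome <- sample(expected, 1)
          planted[di] <- "congruent"
        } else if (stats::runif(1) < congruent_fraction) {
          outcome <- sample(expected, 1)
          planted[di] <- "congruent"
        } else {
          outcome <- sample(complement, 1)
          planted[di] <- "incongruent"
        }
      }
      med_rows[[di]] <- medication(drug,
                                   status = sample(.status_levels, 1),
                                   trial_adequate = trial, outcome = outcome)
    }

    case <- pgx_case(do.call(rbind, med_rows),
                     genotypes = if (untested) NULL else geno,
                     patient = list(id = sprintf("sim-%04d", ci)))
    truth <- list(
      labels = data.frame(drug = drugs, planted = planted,
                          stringsAsFactors = FALSE),
      expected_pgxbs = sum(planted == "congruent") -
        sum(planted == "incongruent"))
    cases[[ci]] <- list(case = case, truth = truth)
  }

  structure(list(cases = cases,
                 config = list(n_cases = n_cases,
                               meds_per_case = meds_per_case,
                               congruent_fraction = congruent_fraction,
                               fraction_inadequate = fraction_inadequate,
                               fraction_untested = fraction_untested,
                               seed = seed,
                               allele_frequencies = allele_frequencies)),
            class = "pgx_simulation")
}

#' @export
print.pgx_simulation <- function(x, ...) {
  truth <- vapply(x$cases, function(cc) cc$truth$expected_pgxbs, numeric(1))
  cat(sprintf("Synthetic consult batch: %d case(s), seed %d, planted congruent fraction %.2f\n",
              length(x$cases), x$config$seed, x$config$congruent_fraction))
  cat(sprintf("Planted PGxBS: min %d, median %s, max %d\n", min(truth),
              format(stats::median(truth)), max(truth)))
  invisible(x)
}

#' Write a synthetic batch to disk
#'
#' Emits each case in the formats read back by [read_case()] and
#' [read_genotypes()] (`case_NNN.yaml`, `case_NNN_genotypes.tsv`), plus a
#' `truth.json` with the planted labels and expected PGxBS per case.
#'
#' @param sim a `pgx_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cases <- function(sim, dir) {
  stopifnot(inherits(sim, "pgx_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- vector("list", length(sim$cases))
  for (i in seq_along(sim$cases)) {
    stem <- sprintf("case_%03d", i)
    cc <- sim$cases[[i]]
    write_case(cc$case, file.path(dir, paste0(stem, ".yaml")),
               genotypes_path = file.path(dir, paste0(stem, "_genotypes.tsv")))
    truth[[i]] <- list(case = stem,
                       expected_pgxbs = cc$truth$expected_pgxbs,
                       labels = cc$truth$labels)
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
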