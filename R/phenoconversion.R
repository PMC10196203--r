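#' Default phenoconversion multipliers
#'
#' Multiplicative adjustments applied to a genotype-predicted activity score
#' per interacting co-medication: a strong inhibitor abolishes activity
#' (x0), a moderate inhibitor halves it (x0.5), moderate and strong inducers
#' raise it (x1.5 and x2). The map is an ordinary named vector so a caller
#' can supply an edited convention without touching code.
#'
#' @export
phenoconversion_multipliers <- c(strong_inhibitor = 0,
                                 moderate_inhibitor = 0.5,
                                 strong_inducer = 2,
                                 moderate_inducer = 1.5)

#' Adjust a phenotype call for inhibitor/inducer co-medications
#'
#' Phenoconversion: a mismatch between the genotype-predicted and functional
#' enzyme phenotype caused by interacting co-medications. The adjusted
#' activity score is the base score times the product of the multipliers of
#' every matching perpetrator in the knowledge base's interaction table, and
#' the adjusted label is re-binned through the gene's phenotype bins. With
#' no matching perpetrators the call is returned unchanged. Only
#' metabolizer-system calls can be phenoconverted; passing a carrier-system
#' call is an error.
#'
#' @param call a `pgx_phenotype` for a metabolizer-system gene.
#' @param comedications character vector of co-medication names.
#' @param kb a `pgx_kb`.
#' @param multipliers named strength-to-multiplier map
#'   (default [phenoconversion_multipliers]).
#' @return a `pgx_phenotype` with `phenoconverted = TRUE` iff the adjusted
#'   label differs from the base label; `perpetrators` lists the matched
#'   interactions and `base_phenotype` keeps the genotype-predicted label.
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "kb", package = "pgxbs"), quiet = TRUE)
#' nm <- predict_phenotype("CYP2D6", "*1/*1", kb)
#' apply_phenoconversion(nm, "paroxetine", kb)  # NM -> functional PM
apply_phenoconversion <- function(call, comedications, kb,
                                  multipliers = phenoconversion_multipliers) {
  stopifnot(inherits(call, "pgx_phenotype"), inherits(kb, "pgx_kb"))
  if (!identical(call$system, "metabolizer")) {
    stop("phenoconversion applies only to metabolizer-system genes, not ",
         call$gene, " (", call$system, ")")
  }
  if (call$indeterminate || length(comedications) == 0) {
    return(call)
  }
  ix <- kb$interactions
  hits <- ix[ix$gene_symbol == call$gene &
               ix$perpetrator_drug %in% normalize_drug(comedications), ,
             drop = FALSE]
  if (nrow(hits) == 0) {
    return(call)
  }
  adjusted <- call$activity_score * prod(multipliers[hits$strength])
  out <- call
  out$perpetrators <- hits[, c("perpetrator_drug", "strength")]
  out$base_phenotype <- call$phenotype
  out$activity_score <- adjusted
  out$phenotype <- .bin_label(call$gene, adjusted, kb)
  out$phenoconverted <- !identical(out$phenotype, call$phenotype)
  out
}
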