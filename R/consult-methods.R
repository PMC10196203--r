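.display_interpretation <- c(possible_pgx_contribution = "possible PGx contribution",
                             pgx_less_likely = "PGx less likely")

#' @export
print.pgx_consult <- function(x, ...) {
  cat("Structured PGx consult\n")
  if (nrow(x$ledger) == 0) {
    cat("  (no medications)\n")
  } else {
    shown <- x$ledger[, c("drug", "status", "guideline", "adequate_trial",
                          "problem", "congruency_label")]
    names(shown)[6] <- "congruency"
    print(shown, row.names = FALSE)
  }
  cat(sprintf("\nPGxBS: %d (%s)\n", x$pgxbs,
              .display_interpretation[[x$interpretation]]))
  if (is.null(x$genotypes)) {
    cat(sprintf("Untested patient: %d guideline-covered medication(s); reactive PGx testing %s\n",
                x$n_guideline_meds,
                if (x$testing_recommended) "recommended (cut-off: >= 2)"
                else "not indicated"))
  }
  invisible(x)
}

#' Summarize a PGx consult
#'
#' @param object a `pgx_consult`.
#' @param ... unused.
#' @return an object of class `summary.pgx_consult` with per-row rationale
#'   and score bookkeeping (counts of congruent, incongruent, and
#'   not-scored medications).
#' @export
summary.pgx_consult <- function(object, ...) {
  tab <- table(factor(object$ledger$congruency_label,
                      levels = c("congruent", "incongruent", "not_scored")))
  structure(list(consult = object,
                 n_medications = nrow(object$ledger),
                 n_congruent = unname(tab[["congruent"]]),
                 n_incongruent = unname(tab[["incongruent"]]),
                 n_not_scored = unname(tab[["not_scored"]])),
            class = "summary.pgx_consult")
}

#' @export
print.summary.pgx_consult <- function(x, ...) {
  print(x$consult)
  cat(sprintf("\n%d medication(s): %d congruent, %d incongruent, %d not scored\n",
              x$n_medications, x$n_congruent, x$n_incongruent,
              x$n_not_scored))
  scored <- x$consult$ledger[x$consult$ledger$congruency != 0L, , drop = FALSE]
  if (nrow(scored) > 0) {
    cat("\nRationale:\n")
    for (i in seq_len(nrow(scored))) {
      cat(sprintf("  %s (%+d): %s\n", scored$drug[i], scored$congruency[i],
                  scored$rationale[i]))
    }
  }
  invisible(x)
}

#' Extract the consult ledger as a data frame
#'
#' @param x a `pgx_consult`.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return the ledger data frame, one row per medication in input order.
#' @export
as.data.frame.pgx_consult <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  x$ledger
}
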