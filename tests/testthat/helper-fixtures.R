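# Shared fixtures: the shipped knowledge base (loaded once) and the worked
# example case built in code.

test_kb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_kb(system.file("extdata", "kb", package = "pgxbs"),
                        quiet = TRUE)
    }
    cache
  }
})

example_case <- function(genotypes = TRUE) {
  pgx_case(
    rbind(
      medication("codeine", trial_adequate = "yes",
                 outcome = "poor_efficacy"),
      medication("clomipramine", trial_adequate = "yes",
                 outcome = "poor_efficacy")),
    genotypes = if (genotypes) {
      data.frame(gene = c("CYP2D6", "CYP2C19"),
                 diplotype = c("*1/*1x2", "*1/*1"))
    } else NULL,
    patient = list(id = "example-001", age = 42))
}

# Brute-force congruency oracle: an explicit enumeration of the
# gene-role x phenotype x observed-outcome grid, written independently of
# the engine. Returns +1 (congruent), -1 (incongruent), 0 (indeterminate).
oracle_grid <- list(
  activating = list(PM = "poor_efficacy", IM = "poor_efficacy",
                    NM = "", RM = "adverse_effects", UM = "adverse_effects",
                    indeterminate = NA),
  inactivating = list(PM = "adverse_effects", IM = "adverse_effects",
                      NM = "", RM = "poor_efficacy", UM = "poor_efficacy",
                      indeterminate = NA),
  immune_risk = list(positive = "adverse_effects", negative = "",
                     indeterminate = NA),
  target = list(positive = "poor_efficacy", negative = "",
                indeterminate = NA)
)

oracle_congruency <- function(role, label, observed) {
  predicted <- oracle_grid[[role]][[label]]
  if (length(predicted) == 1 && is.na(predicted)) return(0L)
  if (identical(observed, predicted)) 1L else -1L
}

# single-gene fixture drug for each mechanistic role
role_drugs <- c(activating = "codeine", inactivating = "warfarin",
                immune_risk = "allopurinol", target = "peginterferon")
role_genes <- c(activating = "CYP2D6", inactivating = "CYP2C9",
                immune_risk = "HLA-B", target = "IFNL3")
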