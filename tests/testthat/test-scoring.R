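test_that("step 3 and step 4 binary assessments follow the no/unsure convention", {
  expect_identical(assess_adequacy(medication("x", trial_adequate = "yes")), 1L)
  expect_identical(assess_adequacy(medication("x", trial_adequate = "no")), 0L)
  expect_identical(assess_adequacy(medication("x", trial_adequate = "unsure")), 0L)
  expect_identical(assess_adequacy(TRUE), 1L)

  expect_identical(assess_outcome(medication("x", outcome = "poor_efficacy")), 1L)
  expect_identical(assess_outcome(medication("x", outcome = "adverse_effects")), 1L)
  expect_identical(assess_outcome(medication("x", outcome = "none_or_unknown")), 0L)
})

test_that("expected outcomes follow the mechanistic direction table", {
  kb <- test_kb()
  rule_for <- function(drug, gene) {
    dg <- kb$drug_gene_rules
    dg[dg$drug_name == drug & dg$gene_symbol == gene, , drop = FALSE]
  }
  um2d6 <- phenotype_call("CYP2D6", "UM")
  # prodrug (activating): excess activation -> toxicity
  expect_identical(expected_outcomes(rule_for("codeine", "CYP2D6"), um2d6),
                   "adverse_effects")
  # clearance (inactivating): excess clearance -> subtherapeutic exposure
  expect_identical(expected_outcomes(rule_for("clomipramine", "CYP2D6"), um2d6),
                   "poor_efficacy")
  # HLA risk-allele carrier -> severe reaction
  expect_identical(
    expected_outcomes(rule_for("allopurinol", "HLA-B"),
                      phenotype_call("HLA-B", "positive")),
    "adverse_effects")
  # normal metabolizer and non-carrier predict no problem
  expect_length(expected_outcomes(rule_for("codeine", "CYP2D6"),
                                  phenotype_call("CYP2D6", "NM")), 0)
  expect_length(expected_outcomes(rule_for("allopurinol", "HLA-B"),
                                  phenotype_call("HLA-B", "negative")), 0)
  # indeterminate predicts nothing
  expect_length(expected_outcomes(rule_for("codeine", "CYP2D6"),
                                  phenotype_call("CYP2D6", "indeterminate")), 0)
  # gene mismatch is a contract error
  expect_error(expected_outcomes(rule_for("codeine", "CYP2D6"),
                                 phenotype_call("CYP2C19", "NM")),
               "differ")
})

test_that("congruency adjudication reproduces the documented calls", {
  kb <- test_kb()
  um <- predict_phenotype("CYP2D6", "*1/*1x2", kb)
  nm19 <- predict_phenotype("CYP2C19", "*1/*1", kb)
  pm <- phenotype_call("CYP2D6", "PM")

  # UM fails to explain poor analgesia with a prodrug opioid
  expect_identical(as.integer(
    assess_congruency("codeine", um, "poor_efficacy", kb)), -1L)
  # UM explains poor efficacy of a CYP2D6-cleared tricyclic; the NM
  # second gene does not override (any-gene disjunction)
  expect_identical(as.integer(
    assess_congruency("clomipramine", list(um, nm19), "poor_efficacy", kb)),
    1L)
  # PM with opioid toxicity on a prodrug contradicts the mechanism
  expect_identical(as.integer(
    assess_congruency("tramadol", pm, "adverse_effects", kb)), -1L)
  # PM toxicity on a cleared thiopurine is the classic congruent call
  expect_identical(as.integer(
    assess_congruency("azathioprine", phenotype_call("TPMT", "PM"),
                      "adverse_effects", kb)), 1L)
  # rationale names the genes and the rule applied
  r <- assess_congruency("codeine", um, "poor_efficacy", kb)
  expect_match(attr(r, "rationale"), "CYP2D6")
  expect_match(attr(r, "rationale"), "activating")

  # NM-only genotype cannot explain a problem: incongruent
  expect_identical(as.integer(
    assess_congruency("codeine", phenotype_call("CYP2D6", "NM"),
                      "poor_efficacy", kb)), -1L)
  # all genes indeterminate: not scored (0), not incongruent
  expect_identical(as.integer(
    assess_congruency("codeine", phenotype_call("CYP2D6", "indeterminate"),
                      "poor_efficacy", kb)), 0L)
  # a drug without an A/A_B rule violates the precondition
  expect_error(assess_congruency("paracetamol", um, "poor_efficacy", kb),
               "A/A_B")
})

test_that("congruency matches the brute-force grid oracle", {
  kb <- test_kb()
  for (role in names(oracle_grid)) {
    drug <- role_drugs[[role]]
    gene <- role_genes[[role]]
    for (label in names(oracle_grid[[role]])) {
      for (observed in c("poor_efficacy", "adverse_effects")) {
        phen <- phenotype_call(gene, label,
                               system = if (label %in% c("positive", "negative"))
                                 "carrier" else "metabolizer")
        engine <- as.integer(assess_congruency(drug, phen, observed, kb))
        expect_identical(engine, oracle_congruency(role, label, observed),
                         label = sprintf("%s x %s x %s", role, label,
                                         observed))
      }
    }
  }
})

test_that("the interpretation threshold sits between 0 and 1", {
  expect_identical(interpret_pgxbs(0), "pgx_less_likely")
  expect_identical(interpret_pgxbs(1), "possible_pgx_contribution")
  expect_identical(interpret_pgxbs(-3), "pgx_less_likely")
})

test_that("reactive testing is recommended at two or more guideline drugs", {
  kb <- test_kb()
  case <- example_case(genotypes = FALSE)
  rec <- recommend_testing(case, kb)
  expect_true(rec$recommended)
  expect_identical(rec$n_guideline_meds, 2L)
  # either medication alone falls below the cut-off
  for (i in 1:2) {
    rec1 <- recommend_testing(
      pgx_case(case$medications[i, , drop = FALSE]), kb)
    expect_false(rec1$recommended)
    expect_identical(rec1$n_guideline_meds, 1L)
  }
  rec0 <- recommend_testing(pgx_case(NULL), kb)
  expect_false(rec0$recommended)
  expect_identical(rec0$n_guideline_meds, 0L)
  # duplicate entries count once
  dup <- pgx_case(rbind(medication("codeine"), medication("Codeine ")))
  expect_identical(recommend_testing(dup, kb)$n_guideline_meds, 1L)
})

test_that("the full consult reproduces the worked example ledger", {
  kb <- test_kb()
  fit <- pgx_consult(example_case(), kb = kb)
  led <- as.data.frame(fit)
  expect_identical(led$drug, c("codeine", "clomipramine"))
  expect_identical(led$guideline, c(1L, 1L))
  expect_identical(led$adequate_trial, c(1L, 1L))
  expect_identical(led$problem, c(1L, 1L))
  expect_identical(led$congruency, c(-1L, 1L))
  expect_identical(fit$pgxbs, 0L)
  expect_identical(fit$interpretation, "pgx_less_likely")
  expect_false(fit$testing_recommended)
})

test_that("consult edge cases: empty case, untested patient, gating", {
  kb <- test_kb()
  # zero medications: empty ledger, score 0
  empty <- pgx_consult(pgx_case(NULL), kb = kb)
  expect_identical(nrow(empty$ledger), 0L)
  expect_identical(empty$pgxbs, 0L)

  # untested patient: every row not_scored, testing recommendation computed
  untested <- pgx_consult(example_case(genotypes = FALSE), kb = kb)
  expect_true(all(untested$ledger$congruency == 0L))
  expect_identical(untested$pgxbs, 0L)
  expect_true(untested$testing_recommended)
  expect_identical(untested$n_guideline_meds, 2L)

  # rows failing any of steps 2-4 are not scored, with a reason
  case <- pgx_case(rbind(
    medication("paracetamol", trial_adequate = "yes",
               outcome = "poor_efficacy"),              # no guideline
    medication("codeine", trial_adequate = "unsure",
               outcome = "poor_efficacy"),              # inadequate trial
    medication("warfarin", trial_adequate = "yes",
               outcome = "none_or_unknown"),            # no problem
    medication("azathioprine", trial_adequate = "yes",
               outcome = "adverse_effects")),           # scoreable
    genotypes = data.frame(gene = c("CYP2D6", "CYP2C9", "TPMT", "NUDT15"),
                           diplotype = c("*1/*1x2", "*1/*1", "*2/*3A",
                                         "*1/*1")))
  fit <- pgx_consult(case, kb = kb)
  expect_identical(fit$ledger$congruency, c(0L, 0L, 0L, 1L))
  expect_identical(fit$ledger$congruency_label[1:3],
                   rep("not_scored", 3))
  expect_match(fit$ledger$rationale[1], "guideline")
  expect_match(fit$ledger$rationale[2], "trial")
  expect_match(fit$ledger$rationale[3], "problem")
  expect_identical(fit$pgxbs, 1L)
  expect_identical(fit$interpretation, "possible_pgx_contribution")

  # drug whose only guideline gene is untyped: not scored, flagged
  case2 <- pgx_case(rbind(medication("allopurinol", trial_adequate = "yes",
                                     outcome = "adverse_effects")),
                    genotypes = data.frame(gene = "CYP2D6",
                                           diplotype = "*1/*1"))
  fit2 <- pgx_consult(case2, kb = kb)
  expect_identical(fit2$ledger$congruency, 0L)
  expect_match(fit2$ledger$rationale, "indeterminate")

  # duplicate medication entries collapse to the first-listed row
  dup <- pgx_case(rbind(
    medication("codeine", trial_adequate = "yes", outcome = "poor_efficacy"),
    medication("CODEINE", trial_adequate = "yes",
               outcome = "adverse_effects")),
    genotypes = data.frame(gene = "CYP2D6", diplotype = "*1/*1x2"))
  fitd <- pgx_consult(dup, kb = kb)
  expect_identical(nrow(fitd$ledger), 1L)
  expect_identical(fitd$ledger$congruency, -1L)
})

test_that("score conservation, bounds, and gate monotonicity hold on random cases", {
  kb <- test_kb()
  sim <- simulate_cases(kb, n_cases = 25, seed = 11,
                        fraction_untested = 0.2)
  for (cc in sim$cases) {
    fit <- pgx_consult(cc$case, kb = kb)
    led <- fit$ledger
    # conservation: PGxBS = #congruent - #incongruent
    expect_identical(fit$pgxbs,
                     sum(led$congruency == 1L) - sum(led$congruency == -1L))
    # bound: |PGxBS| <= number of fully gated rows
    gated <- sum(led$guideline * led$adequate_trial * led$problem == 1L)
    expect_lte(abs(fit$pgxbs), gated)
    # congruency only after passing every gate
    scored <- led$congruency != 0L
    expect_true(all(led$guideline[scored] == 1L &
                      led$adequate_trial[scored] == 1L &
                      led$problem[scored] == 1L))
    expect_true(all(nzchar(led$rationale[scored])))
  }

  # gate monotonicity: flipping one trial to "no" zeroes that row only
  cc <- sim$cases[[which(vapply(sim$cases, function(x)
    abs(x$truth$expected_pgxbs) > 0, logical(1)))[1]]]
  fit <- pgx_consult(cc$case, kb = kb)
  scored_idx <- which(fit$ledger$congruency != 0L)[1]
  case2 <- cc$case
  case2$medications$trial_adequate[scored_idx] <- "no"
  fit2 <- pgx_consult(case2, kb = kb)
  expect_identical(fit2$ledger$congruency[scored_idx], 0L)
  expect_identical(fit2$ledger$congruency[-scored_idx],
                   fit$ledger$congruency[-scored_idx])
  expect_identical(fit2$ledger$rationale[-scored_idx],
                   fit$ledger$rationale[-scored_idx])

  # removing a medication without an A/A_B rule never changes the score
  case3 <- pgx_case(rbind(
    cc$case$medications,
    medication("paracetamol", trial_adequate = "yes",
               outcome = "adverse_effects")),
    genotypes = cc$case$genotypes)
  expect_identical(pgx_consult(case3, kb = kb)$pgxbs, fit$pgxbs)
})

test_that("phenoconversion flag decides which phenotype is scored", {
  kb <- test_kb()
  # genotype NM; paroxetine converts CYP2D6 NM -> functional PM.
  # codeine + poor efficacy: raw NM -> incongruent; converted PM -> congruent
  case <- pgx_case(rbind(medication("codeine", trial_adequate = "yes",
                                    outcome = "poor_efficacy")),
                   comedications = "paroxetine",
                   genotypes = data.frame(gene = "CYP2D6",
                                          diplotype = "*1/*1"))
  raw <- pgx_consult(case, kb = kb, phenoconversion = FALSE)
  conv <- pgx_consult(case, kb = kb, phenoconversion = TRUE)
  expect_identical(raw$ledger$congruency, -1L)
  expect_identical(conv$ledger$congruency, 1L)
  # the raw-scored rationale still surfaces the functional phenotype
  expect_match(raw$ledger$rationale, "functionally PM")
  expect_match(conv$ledger$rationale, "phenoconverted from NM")
})
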