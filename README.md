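# pgxbs — the pharmacogenomics benefit score as a consult engine

Patients are referred to clinical pharmacology with histories of
medication-related problems at standard doses — unexpected poor efficacy or
intolerable adverse effects — and the question "is pharmacogenomics the
answer?". The **pharmacogenomics benefit score (PGxBS)** answers it with a
structured, reproducible consult rather than a drug-by-drug narrative:

1. list current and past medications;
2. for each, is CPIC level A or A/B guideline evidence available? (1 = yes,
   0 = no/unsure);
3. did the patient have an adequate therapeutic trial? (1/0);
4. was there a medication-related problem — unexpected poor efficacy or
   intolerable adverse effects? (1/0);
5. for medications passing steps 2–4, is the problem *congruent* with the
   genotype-predicted phenotype (+1) or *incongruent* (−1)?
6. **PGxBS = Σ (±1)**. Scores ≥ 1 indicate a possible PGx contribution to
   the patient's problems; 0 and negative scores mean PGx is less likely.

Congruency in step 5 is adjudicated mechanistically. For a metabolizer gene
the star-allele diplotype is translated into an activity score
`AS = v(allele₁) + v(allele₂)` and binned into a phenotype
(PM/IM/NM/RM/UM); for an HLA-type safety gene the patient is a risk-allele
carrier or not. An *activating* gene role (prodrug, e.g. codeine→morphine
via CYP2D6) predicts poor efficacy for PM/IM and adverse effects for RM/UM;
an *inactivating* role (clearance, e.g. clomipramine via CYP2D6/CYP2C19)
predicts the reverse; an *immune-risk* carrier predicts severe adverse
reactions; a *target-gene* non-responder variant predicts poor efficacy. A
normal metabolizer or non-carrier predicts no problem — so a problem on an
NM-only genotype is incongruent (the genotype fails to explain it). For
untested patients, **two or more guideline-covered medications** is the
cut-off recommending reactive PGx testing.

The package ships a curated knowledge-base snapshot (12+ drug–gene pairs
spanning all four roles), activity-score **phenoconversion** for
inhibitor/inducer co-medications, report writers (CSV ledger, JSON,
Markdown), a CLI, and a synthetic case generator with planted congruency
structure used to validate the engine by exact score recovery.

## Worked example

```r
library(pgxbs)
kb   <- load_kb(system.file("extdata", "kb", package = "pgxbs"), quiet = TRUE)
case <- read_case(system.file("extdata", "example_case.yaml", package = "pgxbs"))
geno <- read_genotypes(system.file("extdata", "example_genotypes.tsv", package = "pgxbs"))
fit  <- pgx_consult(case, geno, kb)
fit
```

```
Structured PGx consult
         drug  status guideline adequate_trial problem  congruency
      codeine current         1              1       1 incongruent
 clomipramine current         1              1       1   congruent

PGxBS: 0 (PGx less likely)
```

The 42-year-old's CYP2D6 `*1/*1x2` diplotype (activity score 3.0) is an
ultrarapid metabolizer. For codeine, a prodrug, UM predicts opioid
*toxicity* — so the observed poor analgesic response is incongruent (−1).
For clomipramine, which CYP2D6 clears, UM predicts subtherapeutic exposure
— congruent with the lack of improvement in mental state (+1); the CYP2C19
`*1/*1` NM second gene predicts no problem and the any-gene rule lets the
CYP2D6 call carry. The PGxBS is 0: no known genetic cause for his poor
responses was found. `summary(fit)` prints the per-row rationale,
`write_report(fit, "csv", path)` emits the consult ledger spreadsheet.

Pre-testing, the same case has two guideline-covered medications, so
`pgx_consult(case, kb = kb)$testing_recommended` is `TRUE`.

A shell interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","pgxbs.R",package="pgxbs"))') \
  score --case case.yaml --genotypes geno.tsv --kb kbdir --out ledger.csv
```

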