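---
title: "Scoring medication-problem/genotype congruency: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring medication-problem/genotype congruency: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxbs)
```

## The score and its assumptions

The pharmacogenomics benefit score (PGxBS) is a patient-level sum of
per-medication congruency judgements. Each medication contributes +1 when
its observed problem (unexpected poor efficacy or intolerable adverse
effects at standard doses) is among the outcomes its guideline genes
mechanistically predict for the patient's phenotype, −1 when it is not, and
0 when any gate fails (no CPIC level A/A_B evidence, inadequate or unsure
therapeutic trial, no problem recorded, or no interpretable genotype). The
interpretation threshold sits between 0 and 1: a score of at least 1 flags
a possible PGx contribution; 0 or less means PGx is less likely to matter
for this patient.

The mechanistic assumption is the standard dose–exposure–response chain:
persistently low exposure to an active moiety produces poor efficacy, and
extreme exposure produces toxicity. Gene *roles* encode the direction on
that chain:

| role | PM/IM (or carrier-positive) | NM (or negative) | RM/UM |
|---|---|---|---|
| activating (prodrug) | poor efficacy | — | adverse effects |
| inactivating (clearance) | adverse effects | — | poor efficacy |
| immune_risk (HLA carrier) | adverse effects | — | n/a |
| target (non-responder variant) | poor efficacy | — | n/a |

Three consequences are deliberate. An NM-only genotype with a problem
scores −1, because the genotype *fails to explain* the problem — the score
measures explanatory congruency, not genotype abnormality. An
indeterminate phenotype (unknown allele, untyped gene) predicts nothing,
and a medication whose guideline genes are *all* indeterminate is not
scored rather than −1: an unknown genotype cannot contradict an outcome.
Multi-gene drugs use an any-gene disjunction: one congruent gene carries
the +1 even when a second gene predicts nothing, as in the worked
clomipramine example (CYP2D6 UM congruent, CYP2C19 NM silent).

Further scoring conventions where the procedure leaves room: a medication
passing steps 2–3 with a good or unknown outcome is not a
medication-related problem and contributes 0; current and past medications
score identically (status is display-only); duplicate entries collapse to
one row by normalized name, keeping the first-listed outcome; a drug whose
problems recur over separate episodes scores once. Exactly one problem
type is recorded per medication — a drug causing both poor efficacy and
adverse effects must be entered with whichever the clinician judges
primary.

## Genotype translation

Metabolizer-system genes translate a star-allele diplotype `a/b` into an
activity score, the sum of the two allele activity values, and the score
into a phenotype via per-gene bins stored as data
(`phenotype_bins.tsv`), not code. CYP2D6 follows the consensus convention
0 → PM, (0, 1] → IM, (1, 2.25] → NM, > 2.25 → UM, which makes the worked
example's `*1/*1x2` (activity 3.0) an ultrarapid metabolizer. Bins are
stored with inclusive bounds on the 0.25 grid of attainable diplotype
scores, and load-time validation enumerates every formable diplotype to
prove each score lands in exactly one bin. Off-grid scores only arise
through phenoconversion; they are binned by the first bin whose upper
bound covers the score, which reproduces the half-open convention (so
1.125 is NM for CYP2D6). Activity values are validated as nonnegative
multiples of 0.25, which admits increased-function alleles such as
CYP2C19 `*17` (1.5) alongside copy-number products.

Carrier-system genes (HLA safety alleles; the target-gene non-responder
variant) are positive iff any listed allele is a risk allele. An allele
absent from the function table makes the call indeterminate — never
silently normal — while a risk allele dominates an unknown one.

## Phenoconversion

Strong inhibitors among the co-medications abolish the relevant enzyme's
activity (×0), moderate inhibitors halve it (×0.5), moderate and strong
inducers scale it ×1.5 and ×2; multipliers compose multiplicatively, so
the adjustment is order-independent, inhibitors can only lower and
inducers only raise the score, and the adjusted label is re-binned through
the same bin table (capped at the top bin). The multiplier map is a
documented default argument rather than a sixth knowledge-base table, so a
different convention is a call-site edit. Perpetrator–gene pairs live in
`interactions.tsv`. Whether the *raw* or the *phenoconverted* phenotype
feeds the congruency score is a run flag (`phenoconversion` in
`pgx_consult()`), defaulting to raw with the functional phenotype surfaced
in the rationale: the raw call is what a laboratory report asserts, while
the functional call depends on a co-medication list whose completeness the
consult cannot verify.

## The knowledge base

The shipped snapshot is a curated fixture pinned by a version string; it
spans all four gene roles across 12+ guideline drugs (opioid prodrugs,
tricyclics, clopidogrel, warfarin, thiopurines, statin transport, three
HLA-B-mediated severe-reaction drugs, and an interferon response
biomarker) plus a level-B rule to exercise the evidence filter. It claims
no currency with any live guideline release. Drug matching is exact after
case-folding and trimming; determinism is preferred over fuzzy synonym
resolution, and synonyms can be added as explicit rule rows.

## The synthetic generator

`simulate_cases()` exists so every scoring path is testable with known
ground truth and no real patient data. It draws genotypes from per-gene
allele frequencies — round synthetic numbers, not population estimates —
prescribes a random subset of drugs, gates a configurable fraction behind
inadequate trials or absent genotype results, and *plants* each remaining
medication's problem: drawn from the phenotype's predicted outcome set
with probability `congruent_fraction`, from its complement otherwise. A
phenotype predicting no problem is planted incongruent, and one predicting
both problems (possible for multi-gene drugs) forces a congruent plant;
both are recorded truthfully in the emitted labels, so the planted
expected PGxBS is exact, not probabilistic. The planting logic carries its
own literal direction grid, independent of the engine's
`expected_outcomes()`, making engine-equals-truth a genuine
two-implementation check; the test suite asserts exact recovery over 500
cases across five seeds (and the acceptance checks re-run it), alongside
conservation (#congruent − #incongruent), the |PGxBS| ≤ scoreable-rows
bound, and allele-frequency recovery over 10,000 draws within binomial
99% intervals. Problem sizes in the suite (tens to a few hundred cases,
5,000 for frequency checks) keep the full run around half a minute.

What the generator does **not** emulate: realistic prescription sequences,
comorbidity structure, recall bias in trial-adequacy judgements, assay
failure modes, or phenoconversion (co-medication lists are generated
empty). Passing the recovery tests therefore shows the engine implements
the scoring rule exactly; it says nothing about the clinical validity of
the score, which is out of scope here.

## Numerical and degenerate-input choices

Scores are integers throughout; the only real arithmetic is activity
summation and multiplier products, compared against bin bounds with a 1e−9
tolerance. An empty medication list yields an empty ledger and PGxBS 0. An
untested patient scores 0 on every row and instead receives the reactive
testing recommendation (≥ 2 guideline-covered medications). Unknown drugs
answer step 2 with 0 — "no/unsure" — never an error, while malformed
diplotypes and schema-invalid case files are errors with field context.
The canonical CSV ledger excludes timestamps so regeneration from the same
inputs is byte-identical.

## Limitations

The score inherits the subjectivity of steps 3–4 (trial adequacy and
problem type are supplied clinical judgements, not inferred from text);
the knowledge base is a static snapshot; dual problems per medication are
unsupported; and the PGxBS is not a validated decision instrument — the
package computes it reproducibly, which is a different claim.
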