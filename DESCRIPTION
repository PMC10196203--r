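Package: pgxbs
Title: Pharmacogenomics Benefit Score Consult Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the pharmacogenomics benefit score (PGxBS), a
    patient-centred measure of congruency between medication-related
    problems (unexpected poor efficacy or intolerable adverse effects)
    and genotype-predicted phenotypes. Provides a curated drug-gene
    knowledge base with star-allele activity-score translation,
    activity-score phenoconversion for inhibitor/inducer co-medications,
    a structured six-step consult engine producing a per-medication
    ledger, a reactive-testing recommendation, report writers
    (CSV/JSON/Markdown), and a synthetic case generator with planted
    congruency structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
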