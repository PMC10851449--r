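Package: meddraicd
Title: MedDRA to ICD Terminology Mapping, Coverage and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates crosswalks between the Medical Dictionary for
    Regulatory Activities (MedDRA) and the International Classification of
    Diseases (ICD-9-CM / ICD-10-CM). Extracts mapped pairs from UMLS
    Metathesaurus files by concept-identifier (CUI) join and from OMOP
    standardized vocabulary tables via direct and SNOMED-mediated indirect
    relationships, aggregates lowest-level terms (LLT) to preferred terms (PT),
    computes mapping coverage overall, per system organ class (SOC) and across
    vocabulary snapshots, ranks candidate ICD codes for unmapped PT terms with
    a BM25 retrieval model over a CUI-grouped synonym dictionary, and evaluates
    mapping quality with a semantic relation schema, stratified sampling and
    Cohen's kappa. A synthetic vocabulary generator emulates the licensed
    UMLS/MedDRA/OMOP distributions so the whole pipeline is testable with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
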