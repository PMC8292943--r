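Package: hitmapper
Title: Content Mapping of Health Demand, Informatics Supply and
    Technological Applications in the Biomedical Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies biomedical publications by their MeSH (Medical
    Subject Headings) major topics into health demand (H, the Diseases,
    Health and Public Health branches), informatics supply (I, the
    Information Science branch) and technological applications (T, the
    Techniques and Equipment branch); computes fractional per-article
    H-I-T scores; bins corpora on a tribin-subdivided ternary simplex;
    rolls topics up to first-level branches to build co-occurrence
    interaction matrices and Sankey edge lists; and maps ICD-10 disease
    entries to MeSH subtrees to relate disease burden (DALYs) to
    informatics research effort through a through-origin regression.
    Ships loaders for MeSH descriptor XML, MEDLINE/PubMed citation XML
    and compact tabular dialects, plus a seeded synthetic-corpus
    generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
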