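Package: pkddi
Title: Text Mining of Pharmacokinetic Drug-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for mining pharmacokinetic (PK) drug-drug interaction
    (DDI) evidence from biomedical abstracts. Provides controlled
    vocabularies for PK parameters, CYP450 enzymes, transporters and probe
    drugs; a rule-based tagger for six classes of key terms (drugs,
    metabolites, enzymes, PK parameters, numbers, mechanism and change
    cues); a three-level annotated-corpus data model with XML input and
    output; a rule-based classifier that maps fold-change, inhibition
    constant and linguistic-cue evidence to six interaction labels;
    Krippendorff's alpha for inter-annotator reliability; and an all-paths
    graph-kernel pipeline with a maximum-margin classifier for sentence
    level DDI extraction. A synthetic-corpus generator produces fully
    ground-truthed fixtures so the whole pipeline can be exercised without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    kernlab,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
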