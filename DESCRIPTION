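Package: btmdcnet
Title: Differential Co-Expression Network Analysis of Blood Transcription Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and compares blood transcription module (BTM) co-expression
    networks from longitudinal vaccine-response transcriptomes in two subject
    groups. Computes module eigengenes, selects network nodes by a
    subject-blocked timepoint ANOVA with FDR correction and Jaccard redundancy
    filtering, constructs group-level and single-subject Pearson networks,
    derives Fisher-Z difference networks with a six-class edge taxonomy and
    family-level summaries, ranks gene targets from regulatory-network
    differences with preranked gene-set enrichment and leading-edge
    extraction, estimates immune cell proportions by signature-based
    deconvolution with rank-sum comparisons, and reproduces cohort summary
    statistics. Includes a synthetic cohort generator with ground truth for
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    lme4,
    fgsea,
    optparse
Config/testthat/edition: 3
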