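Package: cnpipe
Title: Copy-Number Inference from Sequencing Coverage and qPCR in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects gene amplification in haploid yeast strains from
    whole-genome sequencing coverage and quantitative PCR. Estimates
    centromeric-plasmid copy number as the depth ratio between
    plasmid-specific sequence and the genome-wide mean, calls
    whole-chromosome disomies and local segmental duplications from
    normalized binned coverage, screens small-variant calls for
    cross-strain recurrence while flagging shared-homology artifacts,
    quantifies relative copy number by the delta-delta-Ct method, and
    measures concordance between sequencing- and qPCR-derived estimates.
    Includes a synthetic-data generator with recorded ground truth so the
    whole inference chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
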