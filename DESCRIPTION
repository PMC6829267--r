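Package: cbfsurvey
Title: CBF Transcription-Factor Family Identification and Cold-Responsive
    Target-Gene Survey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and characterization of C-repeat binding factor
    (CBF/DREB1) transcription-factor families and a survey of their putative
    cold-responsive target genes. Provides homology plus signature-sequence
    candidate screening, ProtParam-style protein physicochemical profiling
    (molecular weight, isoelectric point, GRAVY, instability and aliphatic
    indices), neighbor-joining phylogenies with bootstrap support, extraction
    of upstream promoter windows and degenerate CRT/DRE (RCCGAC) and
    cis-element scanning, FPKM and 2^-ddCt expression analysis, the
    two-criterion target-gene survey with keyword-based functional
    classification and hypergeometric enrichment, and seeded synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
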