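Package: hfeRFLP
Title: In Silico Multiplex PCR-RFLP Genotyping of HFE with Digestion
    Controls, STR Identity Tracking and Contamination Detection
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A computational twin of a multiplex PCR-RFLP assay for the
    HFE variants C282Y and H63D. Provides a declarative S4 model of the
    assay panel (enzymes, fluorescent primers, RFLP markers, STR loci,
    internal digestion control, thresholds), an IUPAC-aware in-silico
    restriction digestion engine with synthetic template generation, a
    capillary-electrophoresis peak-table simulator (noise floor,
    analytical threshold, saturation, DNA-input response, STR stutter,
    two-person mixtures), a rule-based genotype caller that validates
    the FZD1 digestion controls before calling alleles, and QC tools for
    stutter statistics, contamination detection via the mean + 2 SD
    stutter rule, and STR identity matching with Hardy-Weinberg match
    probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Genetics, SNP, Software, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
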