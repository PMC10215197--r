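Package: cysredox
Title: Quantitative Redox Proteomics of Mitochondrial Cysteines
Version: 0.1.0
Authors@R: person("Mito", "Redox Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for competitive cysteine-reactivity profiling
    (isoTOP-ABPP light:heavy ratio analysis across an oxidant dose series)
    and differential-alkylation percent-oxidation quantification (OxICAT),
    together with a synthetic-data generator that emulates both platforms
    from a shared per-site ground truth. Includes in-silico tryptic
    digestion, isotopically labeled peptide mass calculation, extracted-ion
    chromatogram integration with co-elution quality control, replicate
    aggregation with coefficient-of-variation and dispersion filters,
    dose-response sensitivity classification, mitochondrial annotation
    filtering, pathway binning, and hypergeometric overrepresentation
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
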