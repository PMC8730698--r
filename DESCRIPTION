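Package: complexomics
Title: Complexome Profiling Analysis of BN-PAGE Migration Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of complexome profiling experiments, in which a
    blue-native (BN) PAGE lane is cut into gel slices and proteins in each
    slice are quantified by mass spectrometry, yielding a migration profile
    per protein.  Provides a SummarizedExperiment-derived container for
    slice-resolved protein intensities, total-ion-intensity normalization
    with a proteotypic-peptide filter, replicate-averaged migration
    profiles, Welch tests on whole-lane abundances, amplitude-adjusted
    Euclidean profile distances, band-resolved complex subunit ratio
    tables with medians, multi-criterion co-migration and band-enrichment
    screens for novel complex-associated proteins, and a synthetic
    complexome generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, tools, grDevices, S4Vectors, jsonlite,
    pheatmap
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Normalization, Software
RoxygenNote: 7.3.3
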