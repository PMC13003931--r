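Package: psiquant
Title: Targeted Pseudouridine Stoichiometry and Editing Assay Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies site-specific RNA pseudouridylation from targeted
    amplicon sequencing. Implements the CMC reverse-transcription deletion
    signature pipeline (UMI collapse by first occurrence, perfect 8-mer
    anchor matching around an N-psi-N target, deletion and mutation rates,
    normalization to 100 percent PsiTP synthetic standards), per-position
    deletion-rate quantification for bisulfite-induced deletion (BID-seq)
    amplicons, and the supporting assay statistics: delta-Cq relative
    expression and nuclear/cytosolic enrichment ratios, molar-adjusted gel
    percent-spliced-in, Sanger-trace A-to-I editing fractions, dual
    luciferase ratios, and construct performance-ratio correlation. A
    seeded synthetic-data generator produces amplicon reads with known
    pseudouridine stoichiometry, PCR duplicates sharing UMIs, sequencing
    error, calibration standards, and all assay tables, so every
    quantification step is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
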