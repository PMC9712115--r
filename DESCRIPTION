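Package: cas13design
Title: Design and Quantification Toolkit for Cas13a-Assisted Phage Genome Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering bacteriophage genomes with RNA-targeting
    Cas13a counterselection: design of 31-nt crRNA spacers against phage
    transcripts (CDS-start, ribosome-binding-site, mid-CDS and
    deletion-verification targeting modes) with host off-target and crRNA
    hairpin screens; silent (synonymous) recoding of protospacers at single-
    codon, seed-region or full-protospacer scope under codon-usage
    constraints; homologous-recombination donor design (gene deletions,
    coordinate-span deletions, recodings) with golden-gate (BsaI/BbsI) oligo
    and fragment chemistry; in-silico application and verification of edits;
    plaque-assay quantification (serial-dilution titres with a
    lysis-from-without upper bound, efficiency of plaquing, editing
    penetrance, MOI arithmetic); and a small counterselection-enrichment
    simulator. A deterministic synthetic-genome generator makes every module
    testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
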