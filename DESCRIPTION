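Package: hbrscout
Title: Unique Peptide Segments and Heparin-Binding Region Screening in
    Protein Families
Version: 1.0.0
Authors@R:
    person("hbrscout", "Maintainers", email = "maintainers@hbrscout.example.org",
           role = c("aut", "cre"))
Description: Discovers member-unique peptide segments in a protein family by
    k-mer carrier counting and bottom-up merging, nominates cationic
    heparin-binding region (HBR) candidates by scanning basic-residue-rich
    windows over the unique segments, and computes motif-level and
    whole-protein percent-identity tables (positional identity over fixed
    10-mers and Needleman-Wunsch global alignment with affine gaps under
    BLOSUM62). Ships the printed human ribonuclease A superfamily motif
    tables as fixtures, a seeded synthetic-family generator with planted
    ground truth for end-to-end validation, and a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
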