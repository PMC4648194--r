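Package: rhizoglob
Title: Identification, Promoter Scanning, Phenetics and Heme-Pocket Geometry of Rhizobial Globins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for the bioinformatic characterization of
    globin genes in rhizobial genome scaffolds. Detects open reading frames,
    scores candidates against a reference set of eight globin queries with a
    permutation Z on affine-gap global alignment scores, classifies accepted
    globins into the M/S/T families (flavohemoglobin, single-domain globin,
    globin-coupled sensor, truncated hemoglobin classes 1-3), scans 130-nt
    upstream windows for -10/-35/Fnr/Shine-Dalgarno elements with
    mismatch-tolerant matching, maps gene neighborhoods within 5 kb, builds
    percent-identity UPGMA phenograms, and quantifies heme-pocket geometry
    (Fe-residue distances, side-chain dihedrals, coordination calls) in PDB
    structure models. A synthetic-data module generates scaffolds, upstream
    regions and toy heme-pocket structures with machine-readable ground truth
    so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    grDevices,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
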