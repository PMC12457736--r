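Package: lipscan
Title: Detection of Light Interfaces of High Polarity (LIPs) in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies LIPs (Light Interfaces of high Polarity) in protein
    structures: buried interfaces that combine an unusually high ratio of
    polar to apolar buried surface with low atomic packing density.  A
    sliding eight-residue probe builds per-residue polarity-ratio and
    Voronoi packing-density profiles for each chain (against the rest of
    the same chain, or against an entire partner chain in oligomers);
    contiguous segments passing the peak, baseline and packing thresholds
    are reported as mLIPs, and the residues they pack against (selected by
    the solvent accessibility they gain when the segment is cropped out)
    as cLIPs.  Includes a deterministic Shrake-Rupley solvent-accessible
    surface area engine, bisector-plane Voronoi atomic volumes, amino-acid
    enrichment and exposure statistics, mean-difference analyses over
    external per-residue score tables, a synthetic-structure generator for
    testing, profile plotting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
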