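Package: alphastrand
Title: Detection of Alpha-Strand Backbone Conformations in Protein
    Structures and Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting the alpha-strand motif, a run of
    successive residues whose backbone dihedrals alternate between the
    right-handed (alpha-R) and left-handed (alpha-L) helical quadrants of
    the Ramachandran plot.  Provides backbone dihedral computation from
    coordinates, Ramachandran-sign classification, alternating-pattern
    scanning of single conformations and of frame-by-frame trajectories
    (per-window counts, first-appearance times, peptide-plane flip
    detection), sequence-motif-restricted mining of structure
    collections, an internal-coordinate synthetic backbone builder, a
    stochastic two-state trajectory simulator with planted ground truth,
    and an experiment-manifest encoding for the amyloid-beta 1-42
    simulation campaign the method was developed on.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
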