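Package: pericytemorph
Title: Ultrastructural Morphometry of Pericyte-Endothelial Cell Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement pipeline for segmented serial-section transmission
    electron microscopy (ssTEM) stacks of capillary cross-sections: vessel
    diameter from the basement-membrane outer perimeter, pericyte and
    basement-membrane volume fractions, skeleton-based pericyte coverage and
    direct pericyte-endothelial contact length classification, peg-and-socket
    protrusion depth and area via morphological closing and an exact Euclidean
    distance transform, alpha-SMA branch coverage on fluorescence vessel
    networks, and a nonparametric group-comparison layer (Kruskal-Wallis with
    Dunn post-hoc). Includes a synthetic segmented-vessel generator with
    analytic ground truth for validation, TIFF/JSON stack input-output, and an
    end-to-end cohort demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    igraph,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
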