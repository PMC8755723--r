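Package: deepseep
Title: Comparative Metagenomics of Deep Continental Subsurface Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative genome-resolved metagenomics of deep
    subsurface ecosystems: in situ replication indices from origin-to-terminus
    sequencing-coverage trends, codon-usage-bias predictions of minimal
    generation times, majority-vote scaffold taxonomy, library-normalized
    chemolithoautotrophic pathway abundance matrices, gene-sharing networks
    and rare-gene (gene loss / horizontal transfer) screens, distance-decay
    biogeography on the WGS84 ellipsoid with fragment-based average
    nucleotide identity, a geyser carbon mass balance, and the statistical
    layer (depth trends, group tests, power-bounded equivalence testing)
    tying them together. Includes seeded synthetic-community generators with
    known ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
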