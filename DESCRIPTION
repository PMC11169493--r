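Package: excitonet
Title: Excitation Energy Transfer Networks in Pigment-Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes excitation energy transfer (EET) rates and pathway maps
    for chlorophyll-binding photosynthetic supercomplexes from atomic
    structures. Parses PDB/mmCIF files to extract pigment cofactors
    (chlorophyll a/c, pheophytin, carotenoids), computes pigment census
    statistics, screened transition-charge (TrEsp) electronic couplings,
    Gaussian spectral overlaps, pairwise Forster rates and
    generalized-Forster aggregate-to-aggregate rates via thermally weighted
    exciton states. Includes a synthetic-structure generator (dimers, linear
    antenna belts, C2-symmetric supercomplexes) with recorded ground truth,
    a directed-network pathway analysis, and a reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
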