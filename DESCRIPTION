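Package: lineagelink
Title: Linked Visualization and Analysis of Cell Lineage Trees and 3D Cell Positions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joining a developmental cell-lineage tree with the 3D
    positions, annotations and gene expression of the same cells. Parses
    lineage trees in Newick or hierarchical JSON with relative or absolute
    branch lengths, extracts cell clones by ancestor, division depth or
    developmental time, computes lineage-relationship levels between cells,
    imports MaMuT/TrackMate-style tracking XML, simulates synthetic lineages
    with spatially coherent cell placements, and exports deterministic static
    (SVG/PNG) and standalone interactive (HTML) linked views of the lineage
    tree and the 3D cell cloud. A command-line interface wires the pieces
    together for batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
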