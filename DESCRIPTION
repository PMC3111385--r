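Package: mipscan
Title: Classification and Sequence Analysis of Plant and Algal Major Intrinsic Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing and classifying plant and algal Major
    Intrinsic Proteins (MIPs, aquaporins). Queries are aligned to a
    structure-anchored reference alignment so that annotated structural
    elements, anchor residue numbering and the four aromatic/arginine (ar/R)
    selectivity-filter columns transfer to the query; NPA motifs, the ar/R
    filter, subfamily-diagnostic motifs, loop lengths and C-terminal charge
    are then extracted and combined with neighbor-joining bootstrap placement
    into a subfamily call with an auto-proposed isoform name. Additional
    modules project intron positions from gene models onto alignment columns
    with codon phase and detect conserved intron positions, compute
    sampling-based position-specific residue enrichment (iceLogo-style
    statistics), and generate ground-truth-labelled synthetic MIP families
    for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
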