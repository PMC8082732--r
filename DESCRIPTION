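Package: dcjindel
Title: DCJ-Indel Rearrangement Distance of Natural Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the exact double-cut-and-join (DCJ) distance with
    insertions and deletions between two natural genomes, i.e. genomes in
    which any marker may occur an arbitrary number of times and chromosomes
    may be linear or circular. The distance is obtained by building the
    capped multi-relational diagram of the two genomes and solving an
    integer linear program for an optimal consistent cycle decomposition;
    for singular genomes a closed-form distance based on runs, the indel
    potential and chained path recombinations is provided. The package also
    ships brute-force reference implementations (exhaustive matching
    enumeration and a breadth-first DCJ sorter), a genome evolution
    simulator with DCJs, duplications, insertions and deletions, parsers
    and writers for UniMoG-style genome files, PHYLIP distance-matrix
    output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: GLPK standalone solver (glpsol) for ILP-based distances
Config/testthat/edition: 3
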