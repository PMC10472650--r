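Package: mvspop
Title: Reference-Free Metavariant Species Delineation and Seascape
    Genetic Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delineates plankton taxa directly from reference-free
    metagenomic SNPs by clustering loci on the covariation of their
    sequencing depth of coverage, quantifies population differentiation
    with allele-frequency based F_ST, estimates seascape connectivity as
    Lagrangian most-likely-path travel times from surface-drifter
    trajectories, partitions the variance of pairwise F_ST over
    environmental and oceanographic distance predictors with a
    variance-component mixed model, and classifies taxa by their dominant
    connectivity driver. A synthetic-data generator with planted ground
    truth (negative-binomial coverage, Balding-Nichols allele
    frequencies, toy ocean currents, smooth environmental gradients)
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
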