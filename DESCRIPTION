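Package: felidelim
Title: Molecular Species-Delimitation Evidence Chain for Neotropical Cats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multi-marker molecular evidence chain used to
    delimit small spotted cat (Leopardus) lineages: Kimura 2-parameter
    mitochondrial distances with delta-method standard errors and
    species-threshold flagging, haplotype condensation and median-joining
    network construction with rho-statistic divergence dating under
    mutation-rate calendars, microsatellite allele-frequency statistics
    (delta-mu-squared, squared-Euclidean individual encoding) with Ward and
    unrooted neighbour-joining trees, principal coordinate analysis with a
    minimum spanning tree overlay, and fixed diagnostic-site (synapomorphy)
    detection in reference coordinates. Includes sequence and stepwise
    microsatellite simulators so every stage is testable without external
    data, and a one-call pipeline producing a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
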