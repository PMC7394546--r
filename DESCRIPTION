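Package: eb1comet
Title: Directional Analysis of EB1 Comet Tracks in Neuronal Somas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the direction of microtubule growth from
    EB1 comet trajectories recorded in the soma of Drosophila dendritic
    arborisation neurons. Measures initial growth angles relative to the axon
    entry site, summarises per-Golgi-stack directional concentration with
    normalised resultant vectors against a Monte-Carlo uniform-angle null,
    classifies comet interactions with axon and dendrite entry zones
    (approach, entry, turning, proximal-dendrite polarity), and provides the
    accompanying proportion inference (Wilson intervals, one-way and 2x2
    chi-squared tests, exact binomial tails). A synthetic comet-track
    generator with ground-truth labels makes the full pipeline testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
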