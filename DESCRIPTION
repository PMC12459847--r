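Package: esfringe
Title: Ecosystem-Service Trade-Offs and Synergies Along Urban-Fringe-Rural Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing how ecosystem-service (ES) trade-offs and
    synergies respond to urban-fringe-rural spatial-structure change on
    gridded landscapes. The pipeline classifies 1-km cells into urban,
    fringe and rural zones from six socio-economic and landscape features
    using a multilayer-perceptron classifier, types zone transitions
    between two dates, computes eight fine-scale ecosystem-service layers
    (food production from Miami/Thornthwaite-Memorial climate potentials,
    soil conservation from USLE factors, water yield, carbon storage,
    nitrogen and phosphorus export, habitat quality, landscape aesthetics),
    aggregates them to village units, and analyses their interactions with
    Spearman correlation matrices, a coupling-coordination degree model
    with six coordination levels, standard deviational ellipses, and
    self-organizing-map ES bundles selected by the Davies-Bouldin index.
    A seeded synthetic-landscape generator produces two-date scenarios
    with planted gradients, water bodies, village tessellations and bundle
    archetypes so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
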