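Package: ageTraits
Title: Building a Compendium of Age-Related Diseases and Traits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies age-related diseases and traits (ARDs/ARTs) from
    prevalence-versus-age profiles using unimodality and late-peak criteria,
    harmonizes trait vocabulary to MeSH and ICD code sets, extracts
    symptom-shared disease subnetworks from a disease-similarity edge list,
    detects significantly genetically correlated phenotype pairs with
    Benjamini-Hochberg false discovery rate control and clusters phenotypes
    by genetic correlation using hierarchical clustering with a dynamic tree
    cut, and computes the death coverage of the resulting disease set against
    a leading-causes-of-death table. A synthetic-data generator with known
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
biocViews: Clustering, Network, GraphAndNetwork, Epidemiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
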