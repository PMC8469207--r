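Package: littora
Title: Community Bioassessment of Freshwater Littoral Habitats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing littoral communities of aquatic organisms
    across habitat groups (reference data, background and impacted sites):
    biotope-confinement scoring of dominant taxa and key-species selection,
    Pantle-Buck/Sladecek saprobity with saprobic-zone classification,
    Shannon diversity, eutrophication guild ratios (E/O, M/E), k-dominance
    (abundance-biomass comparison) curves with a three-state stress
    classification, Ward clustering and PCA ordination of dominant taxa,
    and a seeded synthetic community generator for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
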