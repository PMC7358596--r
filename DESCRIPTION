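Package: gpcrtriage
Title: Agonist/Antagonist Triage of GPCR Ligands from Docking Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies G-protein-coupled receptor (GPCR) ligands as
    agonists, partial agonists, or antagonists from docking free energies
    of the liganded receptor bound to the GDP-loaded G-alpha subunit.
    Provides a from-scratch canonical linear discriminant with
    Wilks-lambda backward elimination, weighted-centroid class cutoffs, a
    frozen published classification rule, posterior classification,
    evaluation against bibliographic labels, group-comparison statistics
    (one-way ANOVA, Tukey HSD) and cAMP-assay normalisation, a
    class-conditional Gaussian synthetic-data generator, packaged
    verification tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
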