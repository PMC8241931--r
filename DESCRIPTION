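Package: rhizoSIP
Title: DNA Stable-Isotope-Probing Analysis of Root-Exudate-Feeding Bacteria
Version: 0.1.0
Authors@R:
    person("Park", "Rowan", email = "rowan.park@example.org", role = c("aut", "cre"))
Description: A tested pipeline for 13CO2 DNA stable isotope probing (SIP) of
    plant root microbiomes: qPCR standard-curve quantification of 16S rRNA gene
    copies across CsCl buoyant-density gradient fractions, heavy/light fraction
    window selection and equal-quantity pooling, autotroph exclusion from
    unplanted 13CO2 controls, dual two-fold enrichment classification of
    root-exudate-metabolizing genera, supporting community ecology statistics
    (Shannon diversity, Bray-Curtis, PCoA, PERMANOVA), and CFU-based root
    colonization statistics (two-way ANOVA, Tukey HSD). Includes a synthetic
    data generator that simulates isotopic labeling, isopycnic gradient
    fractionation, amplicon sequencing and colonization assays so every stage
    is testable at desk scale without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
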