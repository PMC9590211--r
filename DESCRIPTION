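Package: rhizovir
Title: Detection, Activity and Ecology of Soil Viral Populations from
    Virome, Metagenome and Metatranscriptome Count Data
Version: 0.1.0
Authors@R:
    person("Rhizovir", "Developers", email = "rhizovir@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing soil viral communities from read-mapping
    summaries of DNA viromes, total metagenomes and metatranscriptomes.
    Calls viral population (vOTU) presence from breadth of coverage,
    normalises abundances (CPM/TPM), classifies transcriptionally active
    vOTUs, identifies rhizosphere "priming" vOTUs, applies lifestyle and
    ssRNA-phage completeness rules, and provides self-contained community
    statistics (Shannon diversity, Bray-Curtis, NMDS, PERMANOVA, Mantel,
    two-way ANOVA with Tukey HSD, random-intercept mixed models) together
    with a simplified negative-binomial differential-activity test. A
    synthetic-data generator produces complete input bundles with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
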