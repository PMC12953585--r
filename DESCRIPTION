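Package: lupuspg
Title: Population-Genomic Inference for Admixture, Inbreeding and Genetic Load
    in Structured Wolf Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of the population-genomic inference
    stack used in continent-wide grey-wolf studies: ABBA-BABA D statistics
    with block-jackknife standard errors, twisst-style topology weighting
    over 100-SNP windows stratified by recombination rate, HMM detection of
    runs of homozygosity with ROH-length inbreeding timing, per-individual
    heterozygosity and inbreeding coefficients, two-outgroup polarized
    genetic-load accounting (total, realized and masked load), and folded
    3D site-frequency-spectrum demographic model comparison by composite
    likelihood and AIC. Includes a structured-coalescent cohort simulator
    emulating three deeply diverged wolf lineages with a recently admixed
    population, canid outgroups, planted autozygous tracts and
    deleterious-site annotations, so every stage is exercisable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    phangorn,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
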