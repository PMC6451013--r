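Package: congenstatus
Title: Integrated Genetic and Geospatial Conservation Status Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the conservation status of rare plant
    species from codominant microsatellite genotypes and georeferenced
    occurrence records. Implements per-population diversity statistics
    (allelic richness by rarefaction, unbiased expected heterozygosity,
    Weir-Cockerham inbreeding coefficients with permutation tests),
    AMOVA-based F(ST)/R(ST) differentiation, a Bayesian admixture model
    with Evanno delta-K model choice and replicate-run label alignment,
    heterozygosity-excess bottleneck tests under IAM/TPM/SMM mutation
    models, coancestry-based contemporary effective population size,
    IUCN criterion-B red-listing from extent of occurrence and area of
    occupancy, a minimal surface-range-envelope distribution model with
    AUC/TSS evaluation, and a forward-time population simulator for
    power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
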