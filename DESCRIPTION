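Package: eggbanksim
Title: Forward-Time Simulation of Colonization Genetics in Cyclically
    Parthenogenetic Zooplankton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, two-locality simulator of the colonization genetics
    of cyclically parthenogenetic zooplankton (rotifers, cladocerans).  Two
    populations are founded by a few diapausing eggs drawn from an infinite
    Hardy-Weinberg source, grow clonally under a shared-carrying-capacity
    logistic model, reproduce sexually by panmictic random union of gametes,
    and exchange diapausing eggs through sediment egg banks with annual
    survival and hatching fractions.  Neutral marker loci can be physically
    linked to loci under locality-reversed additive selection, allowing the
    study of persistent founder effects, migration, drift, local adaptation
    and genetic hitchhiking through Nei-style FST (neutral loci) and FSTQ
    (selected loci) trajectories.  Includes experiment presets, a tidy CSV
    results format and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    readr,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
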