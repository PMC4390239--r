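Package: photoidnet
Title: Social Network Analysis of Photo-Identification Sighting Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the social structure of photo-identified
    animal populations from encounter (sighting) databases. Implements
    gambit-of-the-group dyad counting and the half-weight association index
    (HWI), sociogram construction and community partitioning by connected
    components, secondary community assignment of less-marked individuals via
    their permanently marked associates, contingency-table comparisons of mark
    severity and fin-damage rates between communities (Pearson chi-square with
    Bonferroni-corrected pairwise tests), distance-from-shore computation and
    Mann-Whitney rank tests for spatial segregation, and a synthetic
    fission-fusion sighting-data generator with ground truth for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
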