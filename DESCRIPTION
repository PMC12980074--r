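Package: knnancestry
Title: Genetic Ancestry Profiles by k-Nearest-Neighbor Regression on
    Principal Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates individual-level genetic ancestry profiles against a
    set of predefined source populations by k-nearest-neighbor regression in
    the space of principal (or haplotype) components of genetic structure.
    Distances are Euclidean with per-component eigenvalue weights; neighbor
    profiles are averaged either uniformly or with inverse-distance weights
    under a minimum-distance floor. Reference samples may carry continuous
    ancestry profiles, not only discrete single-population assignments.
    Includes total-variation-distance evaluation of profile sets, (k, p)
    grid optimization under discrete/continuous reference scenarios with
    cross-validated selection, a population mix-up diagnostic based on
    signed marginal differences, and a seeded synthetic admixture simulator
    providing ground truth for testing. Reads PLINK-style .eigenvec and
    .eigenval files and tab-delimited profile tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
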