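Package: equivProfiles
Title: Equivalence Testing and Clustering of Feature Lists via Functional Profiles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compares gene or feature lists through their multinomial
    "functional profiles" at a fixed level of an ontology such as the Gene
    Ontology.  Implements expanded and contracted profiles, a one-sided
    equivalence test for the squared Euclidean distance between two profiles
    based on an interval-inclusion rule with a delta-method standard error,
    Holm-Bonferroni familywise control for sets of pairwise comparisons, an
    iterative algorithm that assigns each pair of lists its minimal
    equivalence threshold, and complete-linkage dendrograms built from the
    resulting threshold matrix.  A simulation engine with geometric expanded
    profiles reproduces power and type-I-error curves of the test, and a
    small ontology toolkit slices an OBO graph at a fixed depth to project
    feature annotations onto that level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
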