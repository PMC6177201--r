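Package: nestedmvpa
Title: Subclass-Aware Permutation Testing for Cross-Validated Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multivariate pattern analysis (MVPA) when trials are
    organised in subclasses nested within the classes of interest (repeated
    stimuli, subjects, sessions, recording blocks). Nested subclasses inflate
    cross-validated correct classification rates (CCRs) of linear classifiers
    even when no class effect exists. The package provides a multilevel
    Gaussian trial simulator with class, subclass and within-subclass variance
    components; mean-difference linear discriminant and linear support vector
    machine classifiers with trial-wise k-fold and leave-one-subclass-out
    cross-validation; trial-wise and balanced subclass-wise (block) permutation
    null distributions with exact enumeration for small designs and group-level
    aggregation across subjects; closed-form and quadrature expressions for the
    expected chance-level CCR as a function of the number of subclasses and the
    intraclass correlation; and Monte-Carlo experiments quantifying the
    significance bias of trial-wise permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
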