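Package: mpmap
Title: Mental Profile Mapping for Single-Candidate Authorship Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for psychological authorship verification of the
    "did this one candidate write this text?" kind. Documents are scored
    against a dictionary of psychological word categories (LIWC-style .dic
    files are read and written), the resulting feature variables are grouped
    into 13 clusters of psychological processes, and each document's squared
    Mahalanobis distance from the candidate author's bootstrapped
    "psychological center" is mapped through the chi-square upper tail to a
    0-100 typicality score per cluster. The median of the 13 cluster scores
    is the grand profile score; low scores flag documents that sit far from
    the author's multivariate norm. Also included are insertion analyses
    (scoring a questioned or known-bogus work inside a candidate's map), an
    independent "unmasking" baseline (degradation of linear-SVM accuracy
    under iterative elimination of the most discriminative features, with a
    meta-learner over the degradation curves), internal-consistency
    psychometrics (Cronbach's alpha), 2-D map projections, and seeded
    synthetic-corpus generators for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
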