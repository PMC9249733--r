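Package: abpareto
Title: Co-Optimization of Antibody Affinity and Specificity from Sorted-Library Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for co-optimizing antibody affinity and
    specificity (non-specific binding) from yeast-display library sorting and
    deep sequencing. Assigns binary affinity/specificity labels from replicated
    sorted-sample read counts, encodes heavy-chain variable-domain sequences as
    one-hot vectors, physicochemical descriptors, or recurrent-network
    embeddings, trains two-class projection models (linear discriminant
    analysis, a neural projector, and a k-nearest-neighbor baseline) whose
    one-dimensional projections serve as continuous property metrics,
    identifies Pareto-optimal variants in the affinity/non-specificity plane,
    and designs novel single mutants under a BLOSUM62 conservation filter.
    Includes a gated sort-and-sequence simulator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
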