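Package: anthersom
Title: Stage-Delay Transcriptome Analysis of Anther Development via
    Self-Organizing Map Displacement
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of stage-programmed gene expression in developing rice
    anthers of wild-type and autophagy-deficient plants. Implements trimmed
    mean of M-values (TMM) count normalization, negative-binomial generalized
    linear models with likelihood-ratio tests defining stage-dependent and
    genotype-dependent differential-expression classes, batch-trained
    rectangular self-organizing maps on per-genotype scaled stage profiles,
    a wild-type-to-mutant cluster displacement network with a one-stage
    delay score, hypergeometric term enrichment, sample-level ordination
    (correlation matrices, multidimensional scaling, principal components),
    and 2^-ddCt relative quantification of qPCR data. A negative-binomial
    simulator with a controllable one-stage mutant expression delay
    generates ground-truthed data so the whole chain can be validated at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
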