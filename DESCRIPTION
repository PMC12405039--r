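Package: brainstates
Title: Brain Spaces from Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Represents functional brain states as region-of-interest
    connectivity matrices and embeds a cohort of states into a
    low-dimensional "brain space" by multidimensional scaling of
    inter-matrix Frobenius distances.  Provides axis attribution (pair-axis
    correlations, pair-variance rankings and per-region impacts),
    difference operators between states in full connectome space and in
    the reduced space (with per-dimension percentage variation and
    per-pair axis contributions), convex-region models of diagnosis
    subspaces with membership, separation and trajectory-stability tests,
    and a synthetic cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
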