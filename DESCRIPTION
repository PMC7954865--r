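Package: istrack
Title: Clonal Tracking of Lymphoid Progenitors from Vector Integration Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal clonal tracking of gene-modified
    lymphoid progenitors using retroviral integration sites (IS) as
    heritable clonal barcodes. Provides IS table ingestion with a
    cross-patient 10-fold collision filter, construction of IS-by-sample
    abundance matrices, clonal diversity indices (Shannon, Simpson,
    inverse Simpson), IS sharing and recapture statistics with
    Pearson-correlation sharing networks, closed-population log-linear
    capture-recapture estimation of progenitor clone abundance (M0, Mt,
    and Chao lower-bound heterogeneity models with BIC-based selection),
    T-cell receptor (TCR) repertoire diversity, sharing, recapture and
    CDR3 window distance matrices, nearest-gene annotation with
    proto-oncogene locus surveillance, and a synthetic clonal
    hematopoiesis simulator with known ground truth for validating the
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
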