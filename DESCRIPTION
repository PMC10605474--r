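Package: ogmstr
Title: Sizing Short Tandem Repeat Expansions from Optical Genome Mapping
    Molecule Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and sizes large short-tandem-repeat expansions (such as
    the pentanucleotide expansion in the second intron of RFC1 that causes
    CANVAS) from optical genome mapping molecule alignments.  Per-molecule
    intermarker distances are extracted from Bionano-style XMAP/CMAP files,
    outliers are removed by one-dimensional DBSCAN with an epsilon chosen
    automatically from the knee of the k-nearest-neighbour distance curve,
    and alleles are resolved by fitting one- and two-component univariate
    Gaussian mixtures selected by BIC together with a minimum component
    weight rule.  Also provides cross-platform concordance statistics
    (ordinary least squares regression of optical mapping sizes on Southern
    blot sizes, relative deviations against long-read medians), a molecule
    level simulator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
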