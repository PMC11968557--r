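Package: auci
Title: Time-Resolved Differential Expression with Penalized-Spline Models
    and AUCI Effect Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models gene expression over developmental time with per-gene
    penalized regression splines (one smooth per concentration level plus
    level offsets), simulates the fitted coefficients from their posterior
    to obtain treatment-minus-control difference bands, and summarises each
    gene's response as the signed area under the 95% confidence interval of
    the difference (AUCI95%), normalised per hour of exposure.  Includes the
    surrounding toolkit for time-resolved toxicogenomics studies: expression
    table import, replicate-probe collapsing, log2-CPM transformation,
    cyclic loess normalisation, four-metric sample quality control,
    effect-size cutoff calibration from labelled curves, time-window
    aggregation and DEG overlap analytics, hierarchical clustering of
    response patterns, hypergeometric overrepresentation analysis with
    ortholog mapping, and a synthetic time-course generator emulating the
    2-control/1-treatment replicate design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    limma,
    jsonlite,
    yaml,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse,
    edgeR
Config/testthat/edition: 3
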