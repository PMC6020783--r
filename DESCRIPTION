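Package: erpstats
Title: Randomization Statistics for Multichannel Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-free randomization statistics for averaged multichannel
    event-related potential (ERP) data. Implements the topographic consistency
    test (TCT), topographic analysis of variance (TANOVA) on the global field
    power of difference maps, a parallel GFP test for amplitude effects, global
    count, duration and Fisher-combined corrections for multiple testing over
    time that recycle the permutation null, channel-wise post-hoc t-maps,
    multidimensional-scaling outlier screening, and microstate analysis
    (modified k-means and atomize-and-agglomerate hierarchical clustering,
    cross-validated selection of the number of classes, label smoothing and
    randomization tests on microstate quantifiers). Includes ASCII import and
    export of time-by-channel matrices and electrode coordinate files, an
    experimental-design model with up to two within-subject factors and one
    between-subject factor, and a synthetic-data generator with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, graphics, signal, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
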