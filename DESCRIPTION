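Package: rhythm4C
Title: Rhythmicity Analysis of Time-Resolved 4C-seq Contact Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of 24-hour rhythms in chromatin contact profiles
    measured by circular chromosome conformation capture sequencing (4C-seq)
    around a fixed bait. Implements sample- and fragment-level quality
    filters, cis-chromosome normalization with log variance stabilization,
    locally weighted multilinear regression smoothing with fragment and
    condition effects, Fourier-coefficient chi-square rhythmicity testing,
    two-condition differential-contact statistics, and phase-to-color
    encoding of rhythmic coverage tracks for genome-browser display. A
    synthetic-data generator produces fragment maps, overdispersed contact
    counts with planted stable or oscillating interaction peaks, and
    cosine-modulated binned signal tracks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
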