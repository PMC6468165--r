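Package: uindel
Title: Editing-Progression Analysis for Kinetoplastid U-Indel RNA Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the progression of uridine insertion/deletion
    (U-indel) RNA editing in kinetoplastid mitochondrial mRNAs from merged
    amplicon deep-sequencing reads. Reads are collapsed, anchored to
    never-edited flanks, and aligned to pre-edited and fully edited templates
    in editing-site (ES) coordinates; each transcript is classified as
    pre-edited, partially edited or fully edited and landmarked by its editing
    stop site (ESS) and junction bounds. Populations are normalized to a
    common scale, intrinsic pause sites (IPSs) are called per replicate with a
    Tukey outlier threshold and combined by replicate consensus, and
    exacerbated pause sites (EPSs) are detected between induced and uninduced
    sample sets with Student's t-tests and Benjamini-Hochberg correction.
    Junction sequences can be ranked and binned by length, and candidate guide
    RNAs evaluated by antiparallel duplex alignment with G:U wobble pairing,
    including templated-insertion prediction and a single-base bulge
    (misalignment) mode. A synthetic read generator with known ground truth
    supports validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
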