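Package: sipcaecum
Title: RNA Stable-Isotope-Probing Analysis of Gut Microbial Substrate Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for in vivo 16S rRNA stable isotope probing
    (RNA-SIP) experiments: density calibration and per-fraction RNA
    distributions of isopycnic CsTFA gradients, identification of
    13C-labeled taxa from heavy-versus-light fraction abundances by
    permutation ANOVA with baseline exclusion, Faith's phylogenetic
    diversity with rarefaction, and quantification of 13C enrichment
    (atom percent excess) of short-chain fatty acids from two-mass GC-MS
    isotopologue intensities. Includes a forward simulator of the whole
    experiment (community, isotope incorporation, buoyant-density shift,
    gradient fractionation, amplicon sequencing, qPCR totals, metabolite
    isotopologues) with known ground truth, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
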