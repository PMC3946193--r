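Package: conpromo
Title: Identification of Constitutive Sigma-70 Promoters from Holoenzyme
    Binding Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating bacterial constitutive promoters, i.e.
    promoters recognized in vitro by the RNA polymerase sigma-70 (RpoD)
    holoenzyme without supporting transcription factors. Implements
    tiling-array peak calling of holoenzyme-binding sites (relative-height
    cutoff plus consecutive-probe support), orientation-based classification
    of intergenic spacers into divergent, codirectional and convergent
    types, a consensus-hexamer promoter scan scoring matches to TTGACA and
    TATAAT with a spacer-length bonus, conservation cross-tabulation and
    sequence-logo information content, H-NS silencer overlap accounting,
    and extraction of binding-level and opening-rate parameters from
    single-round mixed-transcription time courses. A synthetic-data module
    generates genomes, gene layouts, planted promoter motifs, probe-level
    binding signal and kinetic time courses with known ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
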