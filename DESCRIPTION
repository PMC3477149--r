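Package: gametolog
Title: Divergence, Gene Conversion and Dating of X/Y Gametologs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the early differentiation of mammalian sex
    chromosomes from codon alignments of X- and Y-linked gametologs.
    Implements synonymous divergence estimation by the unweighted
    Nei-Gojobori method with Jukes-Cantor multiple-hit correction,
    neighbor-joining trees on synonymous distances with codon bootstrap,
    detection of ectopic gene conversion (two-sample runs test on
    phylogenetically informative sites, a permutation global fragment test,
    and delineation of significantly low-divergence windows), divergence
    dating under a male-biased mutation-rate model, and a forward simulator
    of gametolog evolution with recombination arrest, sex-biased rates and
    conversion tracts for validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
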