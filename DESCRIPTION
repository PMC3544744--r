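Package: ppmap
Title: Mapping Pollen-Part Mutations by Segregation Distortion in
    Gametophytic Self-Incompatibility Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genetic analysis of S-locus-independent pollen-part mutations
    (modifier loci) conferring self-compatibility in gametophytic
    self-incompatible species such as apricot. Implements the gametophytic
    pollen-selection transmission model (gamete enumeration, S-haplotype
    pollen rejection with a gametophytically acting modifier, expected
    progeny ratios under competing hypotheses), chi-square goodness-of-fit
    tests of Mendelian segregation ratios, segregation-distortion-locus
    (SDL) scans over SSR genotype tables with coupling-allele-loss
    localization, F3 progeny-test classification of F2 recombinants (1:1
    versus 1:2:1 segregation), physical-interval arithmetic against a
    reference genome, Nei genetic distance from multilocus allele profiles,
    and a seeded forward simulator of crosses with pollen selection over a
    marker map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
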