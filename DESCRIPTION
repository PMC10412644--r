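Package: paleocline
Title: F-Statistics, Kinship and Cost-Surface Cline Analysis for Ancient
    Pseudohaploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genetic analysis of low-coverage ancient
    genomes represented as pseudohaploid genotype calls over ascertained SNP
    panels. Implements f2/f3/f4 statistics with a weighted block jackknife,
    f4-ratio and constrained least-squares admixture-proportion estimation,
    outgroup-f3 continuity scans, conditional nucleotide diversity on
    temporally ordered pseudohaploid pairs, an anchor-individual test of
    genetic continuity, READ-style pairwise-mismatch kinship classification
    with enumeration of trio genealogies consistent with uniparental
    haplogroups, least-cost-path analysis over reclassified cost surfaces
    with an anisotropic vertical factor, and isolation-by-distance admixture
    cline regression. Ships synthetic-data generators (admixture-graph
    allele frequencies, pedigrees, spatial clines, raster fixtures) with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
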