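Package: lineagescope
Title: Lineage-Private Allele Analysis and Core Selection for Two-Lineage SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Population-genomic analysis of diploid biallelic SNP panels drawn
    from two deeply diverged, highly inbred lineages, as arises in crop wild
    relatives such as Aegilops tauschii and its derived bread-wheat D genome.
    Provides genotype matrix input/output (VCF and HapMap-style tables),
    quality-control filtering with an exact-test screen for non-allelic tags,
    Nei gene diversity and Hudson F_ST, relationship-matrix principal
    components and neighbor-joining clustering, lineage-private allele
    discovery with hybrid classification, chromosome painting, parentage
    matching and consensus introgression calling, greedy maximization-strategy
    core-collection selection, and a fully specified synthetic panel generator
    with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
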