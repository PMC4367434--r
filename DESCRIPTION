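Package: NeTrend
Title: Effective Population Size Trajectories from SNP Linkage Disequilibrium
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates trends in recent effective population size (Ne) over
    past generations from genome-wide SNP linkage disequilibrium. Reads PLINK
    text genotype data (.ped/.map) or pre-computed pairwise-LD tables,
    computes pairwise r2 between intra-chromosomal SNP pairs (haplotype- or
    genotype-count based), applies sample-size, phase and mutation
    corrections, maps physical to recombinational distance (linear, Haldane,
    Kosambi or user-registered mapping functions), bins pairs by distance
    with a power-law binning scheme, and inverts Sved's drift-recombination
    expectation E(r2) = 1/(1 + 4*Ne*c) into an Ne-versus-generations
    trajectory. Includes a Wright-Fisher forward simulator with
    recombination for validation against known ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, LinkageDisequilibrium, Genetics
RoxygenNote: 7.3.3
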