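Package: ypopgen
Title: Paternal Population Structure and Chronology from Y-Chromosome Haplogroup and Sequence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paternal (Y-chromosome) population structure from
    haplogroup frequencies and haploid sequence alignments: within-population
    diversity and neutrality statistics (mean pairwise differences, Watterson's
    theta, Tajima's D, Fu's FS, haplotype and haplogroup diversity), hierarchical
    analysis of molecular variance (AMOVA) with permutation tests and pairwise
    Phi-st, principal component analysis of haplogroup frequency tables, UPGMA
    trees from genetic distance matrices, identification of highly differentiated
    haplogroups, dated-tree chronology (clade TMRCA, branching-events-through-time,
    shared-lineage detection, SNP-based placement of low-coverage queries),
    Getis-Ord Gi* spatial hotspot detection with false-discovery-rate control,
    median-joining haplotype networks, and subsistence-strategy lineage profiles.
    A seeded synthetic-data module (coalescent genealogies with exponential
    growth, infinite-sites mutations, Dirichlet-multinomial haplogroup counts
    with latitudinal clines, planted spatial hotspots, noisy low-coverage query
    genotypes) generates every input the pipeline consumes, so all stages are
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils,
    tools,
    withr,
    geosphere,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
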