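Package: stomatrend
Title: Temporal Genomics of Stomatal Development Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links coding variation in stomatal-development genes to predicted
    stomatal-density change across herbarium (historical) and contemporary
    genome cohorts. Provides effect-annotated variant handling with
    SnpEff-style classification and site-quality filtering, per-gene
    population-genetic screens (nucleotide diversity, Watterson's theta,
    windowed Tajima's D, Weir-Cockerham F_ST) against length-matched control
    gene sets with empirical outlier tests, geodesic historical-modern sample
    pairing, monthly climate-series trend decomposition and classification,
    and a cumulative functional stomatal-density score with signed-rank,
    permutation and counterfactual (Fisher odds) inference. A synthetic-data
    module generates annotated VCF, GFF3, gene-effect, sample-metadata and
    climate inputs with controllable allele-frequency clines and temporal
    shifts so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    geosphere,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    withr
Config/testthat/edition: 3
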