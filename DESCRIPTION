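Package: chipcoreg
Title: Transcription Factor Co-Regulation Analysis from ChIP-Seq and
    Knockdown Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit and simulation workflow for linking a
    ubiquitous transcription factor to a lineage-restricted partner from
    ChIP-seq and shRNA-knockdown expression data. Implements peak calling
    under a Skellam null for the ChIP-minus-control window count difference
    with local background estimation and excluded-region filtering;
    pooled-rank differential-expression scoring by the minimum
    hypergeometric statistic (RSA style) with Storey q-values;
    co-regulation statistics (bagged lowess curves with a randomized-x
    null envelope, and Fisher's exact overlap of top-k gene lists);
    position-weight-matrix motif enrichment with a per-motif score cutoff
    chosen to minimize the binomial p-value; and binding-site interval
    analyses (overlap fractions, cell-line-specificity filtering, nearest
    peak to TSS, and TSS-window/intron gene assignment). A synthetic-data
    module generates ChIP read tracks with planted peaks, replicate
    fold-change tables with planted gene classes, sequences with planted
    motifs, and paired peak sets with controlled overlap, so every stage
    can be benchmarked against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    IRanges,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
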