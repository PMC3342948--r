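test_that("overlap fraction counts each A interval once", {
  a <- genomic_intervals(c("chr1", "chr1"), c(0, 200), c(100, 300))
  b <- genomic_intervals("chr1", 50, 60)
  expect_equal(overlap_fraction(a, b)$fraction, 0.5)
  expect_equal(overlap_fraction(a, a)$fraction, 1.0)
  b2 <- genomic_intervals("chr9", 0, 1000)
  expect_equal(overlap_fraction(a, b2)$fraction, 0.0)
  expect_error(overlap_fraction(a[0, ], b), "empty")

  # multiple B hits on one A interval still count it once
  b3 <- genomic_intervals(rep("chr1", 3), c(0, 10, 20), c(5, 15, 25))
  expect_equal(overlap_fraction(a, b3)$n_a_overlapping, 1)
})

test_that("overlap fraction equals the all-pairs oracle on random sets", {
  withr::local_seed(15)
  for (i in 1:5) {
    a <- random_intervals(400)
    b <- random_intervals(300)
    for (minbp in c(1, 50)) {
      got <- overlap_fraction(a, b, min_overlap_bp = minbp)
      want <- oracle_overlap_any(a, b, minbp)
      expect_identical(got$overlapping, want)
      expect_equal(got$fraction, mean(want))
    }
  }
})

test_that("specificity filter applies the inclusive 5-kb summit rule", {
  target <- genomic_intervals("chr1", c(1000, 50000), c(1200, 50200))
  expect_identical(specific_sites(target, list()), target)

  # summit distance exactly 5000 is "within 5 kb" and removed
  other <- genomic_intervals("chr1", 1100 + 5000 - 100, 1100 + 5000 + 100)
  kept <- specific_sites(target, other, distance = 5000)
  expect_equal(kept$start, 50000)
  # one bp farther and the site survives
  other2 <- genomic_intervals("chr1", 1100 + 5001 - 100, 1100 + 5001 + 100)
  expect_equal(nrow(specific_sites(target, other2, distance = 5000)), 2)
})

test_that("specificity filter retains exactly the planted survivors", {
  withr::local_seed(20)
  # 100 targets at 20-kb spacing; decoys within 4 kb of the first 30
  tstart <- seq(0, by = 2e4, length.out = 100)
  targets <- genomic_intervals("chr1", tstart, tstart + 200,
                               name = sprintf("t%d", 1:100))
  decoy_start <- tstart[1:30] + 100 + sample(500:4000, 30, replace = TRUE) - 100
  decoys <- genomic_intervals("chr1", decoy_start, decoy_start + 200)
  kept <- specific_sites(targets, decoys, distance = 5000)
  expect_equal(nrow(kept), 70)
  expect_setequal(kept$name, sprintf("t%d", 31:100))

  # antitone in distance: a larger radius keeps a subset
  kept_wide <- specific_sites(targets, decoys, distance = 15000)
  expect_true(all(kept_wide$name %in% kept$name))
})

test_that("nearest peak to TSS signs distances in gene orientation", {
  peaks <- genomic_intervals("chr1", c(400, 4900), c(600, 5100))
  gplus <- gene_models("gp", "chr1", "+", 1000, 2000)
  res <- nearest_peak_to_tss(peaks, gplus[1, ])
  expect_equal(res$signed_distance, -500)
  gminus <- gene_models("gm", "chr1", "-", 0, 1001)   # tss at 1000
  res_m <- nearest_peak_to_tss(genomic_intervals("chr1", 400, 601), gminus[1, ])
  expect_equal(res_m$signed_distance, +500)

  at_tss <- genomic_intervals("chr1", 900, 1101)      # summit = 1000
  expect_equal(nearest_peak_to_tss(at_tss, gplus[1, ])$signed_distance, 0)

  # equidistant summits break toward the smaller coordinate
  tie <- genomic_intervals("chr1", c(600, 1200), c(800, 1400))  # summits 700, 1300
  expect_equal(nearest_peak_to_tss(tie, gplus[1, ])$peak$start, 600)
})

test_that("peak-gene assignment follows the TSS-window / intron rule", {
  g <- gene_models("g1", "chr1", "+", 10000, 20000,
                   exons = list(cbind(start = c(10000, 15000),
                                      end = c(11000, 16000))))
  # summit 3 kb upstream of the TSS
  up <- genomic_intervals("chr1", 6900, 7100)
  res <- assign_peaks_to_genes(up, g)
  expect_equal(nrow(res), 1)
  expect_equal(res$relation, "tss_window")
  expect_equal(res$signed_distance_to_tss, -3000)

  # summit inside exon 2, intron mode: the body rule does not fire
  in_exon <- genomic_intervals("chr1", 15400, 15600)
  expect_equal(nrow(assign_peaks_to_genes(in_exon, g, tss_window = 1000)), 0)
  # ... but gene_body mode assigns it
  res_body <- assign_peaks_to_genes(in_exon, g, tss_window = 1000,
                                    mode = "gene_body")
  expect_equal(res_body$relation, "exon")

  # intronic summit fires in both modes
  in_intron <- genomic_intervals("chr1", 12900, 13100)
  expect_equal(assign_peaks_to_genes(in_intron, g, tss_window = 1000)$relation,
               "intron")
})

test_that("assignment matches the all-pairs oracle and modes nest", {
  genes <- simulate_gene_models(n_genes = 20, genome = c(chr1 = 8e5), seed = 33)
  withr::local_seed(34)
  starts <- floor(runif(50, 0, 8e5 - 400))
  peaks <- genomic_intervals("chr1", starts, starts + 400,
                             name = sprintf("p%d", 1:50))
  for (mode in c("intron", "gene_body")) {
    got <- assign_peaks_to_genes(peaks, genes, tss_window = 5000, mode = mode)
    want <- oracle_assignments(peaks, genes, tss_window = 5000, mode = mode)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$peak_name, got$gene_id),
                    paste(sprintf("p%d", want$peak), want$gene_id))
  }
  got_intron <- assign_peaks_to_genes(peaks, genes, mode = "intron")
  got_body <- assign_peaks_to_genes(peaks, genes, mode = "gene_body")
  expect_true(all(paste(got_intron$peak_name, got_intron$gene_id) %in%
                    paste(got_body$peak_name, got_body$gene_id)))
})
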