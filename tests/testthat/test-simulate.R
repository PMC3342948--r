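test_that("peak-free ChIP simulation is uniform at the expected rate", {
  spec <- chip_sim_spec(genome = c(chr1 = 2e5), n_peaks = 0,
                        chip_depth = 5e4, ctrl_depth = 3e4, seed = 5)
  sim <- simulate_chipseq(spec)
  expect_equal(nrow(sim$truth_peaks), 0)
  for (track in list(sim$chip, sim$ctrl)) {
    counts <- count_windows(track, 200, 200)$count
    expected <- track$total_depth * 200 / 2e5
    se <- sqrt(expected / length(counts))
    expect_lt(abs(mean(counts) - expected), 3 * se)
  }
})

test_that("ChIP simulation is a pure function of its seed", {
  spec <- chip_sim_spec(genome = c(chr1 = 5e4), n_peaks = 5, peak_width = 200,
                        chip_depth = 5e3, ctrl_depth = 3e3, seed = 11)
  s1 <- simulate_chipseq(spec)
  s2 <- simulate_chipseq(spec)
  expect_identical(s1$chip$positions, s2$chip$positions)
  expect_identical(s1$ctrl$positions, s2$ctrl$positions)
  expect_identical(s1$truth_peaks, s2$truth_peaks)
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_track_bed(s1$chip, p1)
  write_track_bed(s2$chip, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("ChIP simulation enriches planted peaks and respects capacity", {
  spec <- chip_sim_spec(genome = c(chr1 = 2e5), n_peaks = 10, peak_width = 500,
                        enrichment = 10, chip_depth = 1e5, ctrl_depth = 5e4,
                        seed = 3)
  sim <- simulate_chipseq(spec)
  in_peak <- sum(vapply(seq_len(nrow(sim$truth_peaks)), function(i) {
    p <- sim$truth_peaks[i, ]
    count_in(sim$chip$positions[[p$chrom]], p$start, p$end)
  }, 0))
  # expected share of reads in peaks: E*w_pk / (G + (E-1)*w_pk)
  w_pk <- 10 * 500
  frac <- 10 * w_pk / (2e5 + 9 * w_pk)
  expect_lt(abs(in_peak / 1e5 - frac), 3 * sqrt(frac * (1 - frac) / 1e5))

  expect_error(simulate_chipseq(chip_sim_spec(genome = c(chr1 = 1e3),
                                              n_peaks = 50, peak_width = 200)),
               "too small")
})

test_that("expression simulation recovers the planted class means", {
  spec <- expr_sim_spec(n_genes = 1200,
                        class_sizes = c(co_activated = 200, co_repressed = 200,
                                        mitf_only = 100, yy1_only = 100,
                                        antagonistic = 100),
                        effect = 1.5, noise_sd = 0.3, seed = 21)
  sim <- simulate_expression(spec)
  expect_equal(dim(sim$mitf), c(1200, 6))
  expect_equal(dim(sim$yy1), c(1200, 4))
  means_a <- c(co_activated = -1.5, co_repressed = 1.5, mitf_only = -1.5,
               yy1_only = 0, antagonistic = -1.5, null = 0)
  means_b <- c(co_activated = -1.5, co_repressed = 1.5, mitf_only = 0,
               yy1_only = -1.5, antagonistic = 1.5, null = 0)
  for (cls in unique(sim$truth$class)) {
    idx <- sim$truth$gene_id[sim$truth$class == cls]
    tol <- 3 * 0.3 / sqrt(length(idx))
    expect_lt(abs(mean(colMeans(sim$mitf[idx, , drop = FALSE])) - means_a[[cls]]), tol)
    expect_lt(abs(mean(colMeans(sim$yy1[idx, , drop = FALSE])) - means_b[[cls]]), tol)
  }
})

test_that("expression simulation with zero effect still labels classes", {
  spec <- expr_sim_spec(n_genes = 300, class_sizes = c(co_activated = 50),
                        effect = 0, noise_sd = 0.5, seed = 2)
  sim <- simulate_expression(spec)
  expect_equal(sum(sim$truth$class == "co_activated"), 50)
  expect_lt(abs(mean(sim$mitf)), 3 * 0.5 / sqrt(length(sim$mitf)))
  s2 <- simulate_expression(spec)
  expect_identical(sim$mitf, s2$mitf)
})

test_that("sequence simulation plants motifs at the requested rates", {
  consensus <- consensus_pwm("CATGTG", n = 1e6, pseudocount = 1e-9)
  spec <- motif_sim_spec(n_fg = 40, n_bg = 10, region_length = 60,
                         gc = 0.5, pwm = consensus, plant_rate_fg = 1,
                         plant_rate_bg = 0, seed = 9)
  sim <- simulate_sequences(spec)
  expect_true(all(grepl("CATGTG", sim$fg) | grepl("CACATG", sim$fg)))
  expect_true(all(sim$truth$set == "fg"))
  expect_equal(nrow(sim$truth), 40)
  # planted offsets are where the instance really sits
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    inst <- substr(sim$fg[[tr$region]], tr$offset + 1, tr$offset + 6)
    if (tr$strand == "-") {
      inst <- paste(rev(strsplit(chartr("ACGT", "TGCA", inst), "")[[1]]),
                    collapse = "")
    }
    expect_equal(inst, "CATGTG")
  }

  none <- simulate_sequences(motif_sim_spec(n_fg = 5, n_bg = 5,
                                            region_length = 50,
                                            plant_rate_fg = 0,
                                            plant_rate_bg = 0, seed = 1))
  expect_equal(nrow(none$truth), 0)
})

test_that("background sequence composition matches the requested GC", {
  spec <- motif_sim_spec(n_fg = 50, n_bg = 50, region_length = 100, gc = 0.5,
                         plant_rate_fg = 0, plant_rate_bg = 0, seed = 14)
  sim <- simulate_sequences(spec)
  all_seq <- paste(c(sim$fg, sim$bg), collapse = "")
  gc_obs <- mean(strsplit(all_seq, "")[[1]] %in% c("G", "C"))
  expect_gt(gc_obs, 0.47)
  expect_lt(gc_obs, 0.53)
})

test_that("paired peak sets hit the overlap target exactly", {
  sets <- simulate_peak_sets(100, 100, 0.3, genome = c(chr1 = 2e6),
                             width = 200, seed = 4)
  expect_equal(overlap_fraction(sets$a, sets$b)$fraction, 0.30)
  expect_equal(simulate_peak_sets(20, 20, 1, genome = c(chr1 = 1e6),
                                  width = 100, seed = 1) |>
                 (\(s) overlap_fraction(s$a, s$b)$fraction)(), 1.0)
  expect_equal(simulate_peak_sets(20, 20, 0, genome = c(chr1 = 1e6),
                                  width = 100, seed = 1) |>
                 (\(s) overlap_fraction(s$a, s$b)$fraction)(), 0.0)
})

test_that("simulated gene models satisfy the model invariants", {
  g <- simulate_gene_models(n_genes = 15, genome = c(chr1 = 5e5), seed = 6)
  expect_equal(nrow(g), 15)
  expect_true(all(ifelse(g$strand == "+", g$tss == g$gene_start,
                         g$tss == g$gene_end - 1)))
  for (i in seq_len(nrow(g))) {
    ex <- g$exons[[i]]
    expect_true(all(diff(ex[, 1]) > 0))
    expect_true(all(ex[, 2] > ex[, 1]))
    expect_gte(ex[1, 1], g$gene_start[i])
    expect_lte(ex[nrow(ex), 2], g$gene_end[i])
  }
})
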