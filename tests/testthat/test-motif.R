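test_that("PWM construction and scoring follow the log-odds contract", {
  m <- consensus_pwm("CATGTG")
  p <- pwm_probs(m)
  expect_equal(colSums(p), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(p > 0))

  # consensus window maximises the score and scores positive
  sc_cons <- pssm_score(m, "CATGTG")
  expect_gt(sc_cons, 0)
  others <- c("AATGTG", "CTTGTG", "CATGTA", "TTTTTT")
  expect_true(all(vapply(others, function(w) pssm_score(m, w), 0) < sc_cons))

  expect_equal(pssm_score(m, "NNNNNN"), 0)
  expect_error(pssm_score(m, "CATG"), "length")

  # random PWM / window against a per-column hand summation
  withr::local_seed(4)
  for (i in 1:20) {
    counts <- matrix(rpois(4 * 8, 20), nrow = 4)
    pw <- pwm(counts, background = c(0.3, 0.2, 0.2, 0.3))
    win <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    lo <- log2(pwm_probs(pw) / pw$background)
    hand <- sum(vapply(1:8, function(j) lo[substr(win, j, j), j], 0))
    expect_equal(pssm_score(pw, win), hand, tolerance = 1e-12)
  }
})

test_that("scan_best finds the planted window with the documented tie-breaks", {
  m <- consensus_pwm("CATGTG")
  hit <- scan_best(m, "GGCATGTGAA")
  expect_equal(hit$offset, 2)
  expect_equal(hit$strand, "+")

  exact <- scan_best(m, "CATGTG")
  expect_equal(exact$offset, 0)
  expect_equal(exact$strand, "+")

  # strand symmetry of the best score
  withr::local_seed(6)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    expect_equal(scan_best(m, s)$score, scan_best(m, rc)$score,
                 tolerance = 1e-12)
  }
  expect_error(scan_best(m, "CAT"), "length")
})

test_that("scan_best equals the brute-force scan on random cases", {
  withr::local_seed(10)
  for (i in 1:30) {
    L <- sample(4:9, 1)
    pw <- pwm(matrix(rpois(4 * L, 15), nrow = 4))
    s <- paste(sample(c("A", "C", "G", "T"), sample(15:60, 1), replace = TRUE),
               collapse = "")
    got <- scan_best(pw, s)
    want <- oracle_scan_best(pw, s)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
  }
})

test_that("adaptive-cutoff enrichment detects planted signal and is minimal", {
  sim <- simulate_sequences(motif_sim_spec(n_fg = 300, n_bg = 300,
                                           plant_rate_fg = 0.4,
                                           plant_rate_bg = 0.05, seed = 5))
  m <- ebox_pwm()
  fg <- scan_best_scores(m, sim$fg)
  bg <- scan_best_scores(m, sim$bg)
  res <- optimal_cutoff_binomial(fg, bg)
  expect_equal(res$direction, "over")
  expect_lt(res$p_binomial, 1e-6)
  expect_gt(res$fg_hits / res$fg_total, res$bg_hits / res$bg_total)

  # minimality: reported p is <= the binomial p at every candidate cutoff
  cuts_all <- sort(unique(c(fg, bg)))
  for (cut in cuts_all[seq(1, length(cuts_all), by = 7)]) {
    f <- sum(fg >= cut); b <- sum(bg >= cut)
    rate <- min(max(b / 300, 1 / 600), 1 - 1 / 600)
    p_cut <- min(pbinom(f - 1, 300, rate, lower.tail = FALSE),
                 pbinom(f, 300, rate))
    expect_lte(res$p_binomial, p_cut + 1e-15)
  }

  # direction flips when foreground and background are exchanged
  res_swap <- optimal_cutoff_binomial(bg, fg)
  expect_equal(res_swap$direction, "under")

  # identical lists carry no signal
  res_same <- optimal_cutoff_binomial(fg, fg)
  expect_gte(res_same$p_binomial, 0.2)
  expect_warning(optimal_cutoff_binomial(rep(1, 10), rep(1, 10)), "identical")
})

test_that("the all-separated case reduces to the closed form", {
  fg <- c(10, 11, 12); bg <- c(1, 2, 3)
  res <- optimal_cutoff_binomial(fg, bg)
  expect_equal(res$fg_hits, 3)
  expect_equal(res$bg_hits, 0)
  # rate clamps to 1/(2B); all F successes: p = (1 - (1-rate)^0 ...) = rate-free
  expect_equal(res$p_binomial,
               pbinom(2, 3, 1 / 6, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("label permutation calibrates the adaptive cutoff honestly", {
  sim <- simulate_sequences(motif_sim_spec(n_fg = 150, n_bg = 150,
                                           plant_rate_fg = 0.5,
                                           plant_rate_bg = 0.02, seed = 8))
  m <- ebox_pwm()
  fg <- scan_best_scores(m, sim$fg)
  bg <- scan_best_scores(m, sim$bg)
  p_cal <- calibrate_by_label_permutation(fg, bg, n_perm = 100, seed = 2)
  expect_lte(p_cal, 2 / 101)

  # floor of the estimator
  expect_gte(p_cal, 1 / 101)

  # calibration is deterministic under a fixed seed
  expect_identical(p_cal,
                   calibrate_by_label_permutation(fg, bg, n_perm = 100, seed = 2))
})

test_that("matched random regions preserve the length multiset and avoid excludes", {
  withr::local_seed(13)
  regions <- random_intervals(10, genome = c(chr1 = 5e4), max_width = 800)
  genome <- c(chr1 = 5e4, chr2 = 5e4)
  rand <- matched_random_regions(regions, genome, seed = 3)
  expect_equal(sort(rand$end - rand$start), sort(regions$end - regions$start))

  excl <- genomic_intervals("chr1", 0, 5e4 - 1000)
  rand2 <- matched_random_regions(regions[1:3, ], c(chr1 = 5e4), seed = 3,
                                  exclude = excl)
  expect_false(any(oracle_overlap_any(rand2, excl)))

  # the study-scale count: 814 regions, none touching the exclude set
  many <- genomic_intervals(rep("chr1", 814), seq(0, by = 60, length.out = 814),
                            seq(0, by = 60, length.out = 814) + 50)
  excl2 <- genomic_intervals("chr2", 0, 2e4)
  rand814 <- matched_random_regions(many, c(chr1 = 1e6, chr2 = 1e6), seed = 7,
                                    exclude = excl2)
  expect_equal(nrow(rand814), 814)
  expect_false(any(oracle_overlap_any(rand814, excl2)))
})

test_that("JASPAR-style matrices and FASTA round-trip", {
  m <- ebox_pwm()
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar_pwm(m, path)
  back <- read_jaspar_pwms(path)[[1]]
  expect_equal(back$motif_id, m$motif_id)
  expect_equal(back$counts, m$counts)

  seqs <- c(r1 = "ACGTACGT", r2 = "GGGCCC")
  fp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, fp)
  expect_equal(read_fasta(fp), seqs)
})
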