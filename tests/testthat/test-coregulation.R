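test_that("bagged lowess interpolates exact linear and constant data", {
  withr::local_seed(1)
  x <- runif(500, -2, 2)
  fit <- bagged_lowess(x, x, n_boot = 20, seed = 1)
  expect_lt(max(abs(fit$bagged - fit$grid)), 1e-6)

  fit_const <- bagged_lowess(x, rep(3.5, 500), n_boot = 10, seed = 1)
  expect_equal(fit_const$bagged, rep(3.5, length(fit_const$grid)))

  expect_error(bagged_lowess(rep(1, 50), rnorm(50)), "degenerate")
})

test_that("bagged lowess recovers a linear trend under noise", {
  withr::local_seed(3)
  x <- runif(1000, -1, 1)
  y <- 2 * x + rnorm(1000, 0, 0.1)
  fit <- bagged_lowess(x, y, n_boot = 50, seed = 3)
  slope <- coef(lm(fit$bagged ~ fit$grid))[2]
  expect_gte(slope, 1.9)
  expect_lte(slope, 2.1)
})

test_that("randomization envelope collapses on constant y and nests in n_perm", {
  withr::local_seed(2)
  x <- runif(200, -1, 1)
  env <- randomization_envelope(x, rep(2, 200), n_perm = 20, seed = 5)
  expect_equal(env$env_lo, rep(2, length(env$grid)))
  expect_equal(env$env_hi, rep(2, length(env$grid)))

  y <- rnorm(200)
  grid <- seq(-0.8, 0.8, length.out = 40)
  e_small <- randomization_envelope(x, y, n_perm = 25, grid = grid, seed = 11)
  e_big <- randomization_envelope(x, y, n_perm = 100, grid = grid, seed = 11)
  expect_true(all(e_big$env_lo <= e_small$env_lo + 1e-12))
  expect_true(all(e_big$env_hi >= e_small$env_hi - 1e-12))

  # bit-identical under a fixed seed
  e_rep <- randomization_envelope(x, y, n_perm = 25, grid = grid, seed = 11)
  expect_identical(e_small, e_rep)
})

test_that("planted co-activation exits the envelope; a global null stays inside", {
  spec <- expr_sim_spec(seed = 11)
  sim <- simulate_expression(spec)
  x <- rowMeans(sim$mitf); y <- rowMeans(sim$yy1)
  curve <- coreg_curve(x, y, n_boot = 50, n_perm = 200, seed = 11)
  lower_left <- curve$grid < -0.5
  expect_true(any(curve$outside[lower_left] &
                    curve$bagged[lower_left] < curve$env_lo[lower_left]))

  null_spec <- expr_sim_spec(effect = 0, seed = 11)
  null_sim <- simulate_expression(null_spec)
  null_curve <- coreg_curve(rowMeans(null_sim$mitf), rowMeans(null_sim$yy1),
                            n_boot = 50, n_perm = 200, seed = 11)
  expect_gte(mean(!null_curve$outside), 0.95)
})

test_that("top-k overlap p equals the exact hypergeometric tail", {
  # worked case: universe 100, k = 10, overlap 5
  genes <- sprintf("g%03d", 1:100)
  rec_a <- data.frame(gene_id = genes, p_down = (1:100) / 101,
                      p_up = rev(1:100) / 101)
  # top-10 of b shares exactly genes 1..5 with top-10 of a
  perm <- c(1:5, 51:55, setdiff(1:100, c(1:5, 51:55)))
  rec_b <- data.frame(gene_id = genes[perm], p_down = (1:100) / 101,
                      p_up = rev(1:100) / 101)
  res <- quadrant_overlap_test(rec_a, rec_b, k = 10, mode = "co_activated")
  expect_equal(res$overlap, 5)
  expect_equal(res$fisher_p, 6.716277e-4, tolerance = 1e-6)
  expect_equal(res$fisher_p, oracle_overlap_p(5, 10, 100), tolerance = 1e-12)
  # agreement with stats::fisher.test (one-sided) on the same 2x2 table
  ft <- fisher.test(matrix(c(5, 5, 5, 85), 2), alternative = "greater")
  expect_equal(res$fisher_p, ft$p.value, tolerance = 1e-9)

  # identical rankings: maximal overlap and the minimal achievable p
  res_id <- quadrant_overlap_test(rec_a, rec_a, k = 7, mode = "co_activated")
  expect_equal(res_id$overlap, 7)
  expect_equal(res_id$fisher_p, oracle_overlap_p(7, 7, 100), tolerance = 1e-12)

  # saturation: k = universe forces overlap = universe and p = 1
  res_sat <- quadrant_overlap_test(rec_a, rec_b, k = 100, mode = "co_repressed")
  expect_equal(res_sat$overlap, 100)
  expect_equal(res_sat$fisher_p, 1)
  expect_error(quadrant_overlap_test(rec_a, rec_b, k = 101, mode = "co_activated"),
               "exceeds")

  # randomized cross-check against the enumeration oracle
  withr::local_seed(17)
  for (i in 1:10) {
    k <- sample(3:30, 1)
    rec_r <- data.frame(gene_id = sample(genes), p_down = (1:100) / 101,
                        p_up = rev(1:100) / 101)
    r <- quadrant_overlap_test(rec_a, rec_r, k = k, mode = "co_activated")
    expect_equal(r$fisher_p, oracle_overlap_p(r$overlap, k, 100),
                 tolerance = 1e-12)
  }
})

test_that("overlap curve reproduces the co-regulation significance pattern", {
  spec <- expr_sim_spec(class_sizes = c(co_activated = 150, co_repressed = 150),
                        seed = 13)
  sim <- simulate_expression(spec)
  rec_m <- rsa_rank(sim$mitf)
  rec_y <- rsa_rank(sim$yy1)
  curve <- overlap_significance_curve(rec_m, rec_y,
                                      k_grid = c(100, 200, 300, 400, 500))
  co <- curve$mode %in% c("co_activated", "co_repressed")
  expect_true(all(curve$fisher_p[co] < 1e-6))
  expect_true(all(curve$fisher_p[!co] > 0.01))
  expect_true(all(curve$overlap <= curve$k))
})

test_that("overlap curve is non-significant on permuted gene labels", {
  spec <- expr_sim_spec(n_genes = 500,
                        class_sizes = c(co_activated = 50, co_repressed = 50),
                        seed = 23)
  sim <- simulate_expression(spec)
  rec_m <- rsa_rank(sim$mitf)
  withr::local_seed(29)
  n_nonsig <- 0
  n_runs <- 20
  for (i in seq_len(n_runs)) {
    shuffled <- sim$yy1
    rownames(shuffled) <- sample(rownames(shuffled))
    rec_y <- rsa_rank(shuffled)
    curve <- overlap_significance_curve(rec_m, rec_y, k_grid = c(50, 100))
    if (all(curve$fisher_p > 0.001)) n_nonsig <- n_nonsig + 1
  }
  expect_gte(n_nonsig / n_runs, 0.95)
})
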