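#' Default pipeline configuration
#'
#' One nested list drives the full synthetic benchmark: simulation specs
#' for every input type, peak-caller geometry, RSA cutoffs,
#' co-regulation curve parameters, motif-enrichment settings and
#' interval-analysis windows. All values can be overridden by supplying
#' a partial list to [run_all()] (deep-merged over these defaults).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    genome = c(chr1 = 1e6, chr2 = 1e6),
    chip = list(n_peaks = 50, peak_width = 300, enrichment = 8,
                chip_depth = 4e5, ctrl_depth = 2.5e5),
    expr = list(n_genes = 2000,
                class_sizes = c(co_activated = 150, co_repressed = 150,
                                mitf_only = 100, yy1_only = 100),
                effect = 1.5, noise_sd = 0.3),
    peaksets = list(n_a = 100, n_b = 100, overlap_target = 0.3, width = 200),
    genes = list(n_genes = 20),
    callpeaks = list(window_size = 200, step = 50, p_cutoff = 1e-6),
    rsa = list(q_cutoff = 0.01, lambda = 0.5),
    coreg = list(n_boot = 100, n_perm = 1000, span = 0.3, grid_size = 100,
                 k_grid = c(100, 200, 300, 400, 500)),
    motif = list(n_fg = 300, n_bg = 300, region_length = 300, gc = 0.41,
                 plant_rate_fg = 0.4, plant_rate_bg = 0.05, n_perm = 200),
    intervals = list(tss_window = 5000, specificity_distance = 5000,
                     mode = "intron")
  )
}

#' Derive per-stage sub-seeds from a master seed
#'
#' Stage seeds are drawn once from the master-seeded RNG stream, so each
#' stage can be re-run in isolation yet reproducibly: stage `i` always
#' receives `derive_stage_seeds(seed)[i]`.
#'
#' @param seed Master seed.
#' @param n Number of stage seeds.
#' @return Integer vector of `n` sub-seeds (each below 2^31).
#' @export
derive_stage_seeds <- function(seed, n = 8) {
  with_seed(seed, sample.int(2^31 - 2, n))
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full synthetic co-regulation benchmark
#'
#' Executes every stage in dependency order with one master seed:
#' simulate all inputs; call peaks against the planted truth; score both
#' knockdowns with RSA; build the co-regulation curve, envelope and
#' top-k overlap tests; run motif enrichment with permutation
#' calibration; and run the interval analyses (overlap fraction,
#' specificity filter, gene assignment, nearest-peak-to-TSS). Per-stage
#' sub-seeds are drawn once from the master seed, so stages are
#' individually reproducible. All artefacts are written under `outdir`,
#' one directory per stage, and summarised in a manifest with md5
#' digests: a re-run with the same config and seed reproduces identical
#' digests.
#'
#' @param config Partial configuration merged over [default_config()].
#' @param seed Master seed.
#' @param outdir Output directory (created; default a fresh tempdir).
#' @return The manifest: list with `config`, `seed`, `stage_seeds`,
#'   `summary` (per-stage key numbers), `files` (md5 digests), plus the
#'   in-memory stage results in `$results`.
#' @export
run_all <- function(config = list(), seed = 42,
                    outdir = tempfile("chipcoreg_run_")) {
  cfg <- merge_config(default_config(), config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage_seeds <- derive_stage_seeds(seed)
  paths <- character(0)
  stage_dir <- function(name) {
    d <- file.path(outdir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }

  ## stage 1: simulate -----------------------------------------------------
  d1 <- stage_dir("simulate")
  sim_chip <- simulate_chipseq(do.call(chip_sim_spec, c(
    list(genome = cfg$genome, seed = stage_seeds[1]), cfg$chip)))
  sim_expr <- simulate_expression(do.call(expr_sim_spec, c(
    list(seed = stage_seeds[2]), cfg$expr)))
  sim_seq <- simulate_sequences(do.call(motif_sim_spec, c(
    list(seed = stage_seeds[3]),
    cfg$motif[setdiff(names(cfg$motif), "n_perm")])))
  sim_sets <- do.call(simulate_peak_sets, c(
    list(genome = cfg$genome, seed = stage_seeds[4]), cfg$peaksets))
  sim_genes <- do.call(simulate_gene_models, c(
    list(genome = cfg$genome, seed = stage_seeds[5]), cfg$genes))
  write_track_bed(sim_chip$chip, file.path(d1, "chip_reads.bed"))
  write_track_bed(sim_chip$ctrl, file.path(d1, "ctrl_reads.bed"))
  write_bed(sim_chip$truth_peaks, file.path(d1, "truth_peaks.bed"))
  write_foldchange_table(sim_expr$mitf, file.path(d1, "foldchange_mitf.tsv"))
  write_foldchange_table(sim_expr$yy1, file.path(d1, "foldchange_yy1.tsv"))
  data.table::fwrite(sim_expr$truth, file.path(d1, "expr_truth.tsv"), sep = "\t")
  write_fasta(sim_seq$fg, file.path(d1, "foreground.fa"))
  write_fasta(sim_seq$bg, file.path(d1, "background.fa"))
  data.table::fwrite(sim_seq$truth, file.path(d1, "motif_truth.tsv"), sep = "\t")
  write_bed(sim_sets$a, file.path(d1, "peakset_a.bed"))
  write_bed(sim_sets$b, file.path(d1, "peakset_b.bed"))
  write_bed12_genes(sim_genes, file.path(d1, "genes.bed12"))
  paths <- c(paths, list.files(d1, full.names = TRUE))

  ## stage 2: peak calling -------------------------------------------------
  d2 <- stage_dir("callpeaks")
  peaks <- do.call(call_peaks, c(list(chip = sim_chip$chip, ctrl = sim_chip$ctrl),
                                 cfg$callpeaks))
  truth <- sim_chip$truth_peaks
  truth_hit <- if (nrow(peaks) > 0) {
    intervals_overlap_any(truth, peaks)
  } else rep(FALSE, nrow(truth))
  peak_is_tp <- if (nrow(peaks) > 0) {
    intervals_overlap_any(peaks, truth)
  } else logical(0)
  peak_summary <- list(
    n_peaks = nrow(peaks),
    recall = if (nrow(truth) > 0) mean(truth_hit) else NA_real_,
    false_positives = sum(!peak_is_tp),
    depth_ratio = sim_chip$chip$total_depth / sim_chip$ctrl$total_depth,
    params = cfg$callpeaks)
  write_bed(peaks[, c("chrom", "start", "end", "name", "score", "strand")],
            file.path(d2, "peaks.bed"))
  jsonlite::write_json(peak_summary, file.path(d2, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, list.files(d2, full.names = TRUE))

  ## stage 3: RSA ----------------------------------------------------------
  d3 <- stage_dir("rsa")
  rsa_mitf <- rsa_rank(sim_expr$mitf, lambda = cfg$rsa$lambda)
  rsa_yy1 <- rsa_rank(sim_expr$yy1, lambda = cfg$rsa$lambda)
  sig_down_mitf <- significant_genes(rsa_mitf, cfg$rsa$q_cutoff, "down")
  sig_down_yy1 <- significant_genes(rsa_yy1, cfg$rsa$q_cutoff, "down")
  truth_down_mitf <- sim_expr$truth$gene_id[
    sim_expr$truth$class %in% c("co_activated", "mitf_only", "antagonistic")]
  rsa_summary <- list(
    N = attr(rsa_mitf, "N"), m = attr(rsa_mitf, "m"),
    pi0_down_mitf = attr(rsa_mitf, "pi0_down"),
    n_sig_down_mitf = length(sig_down_mitf),
    n_sig_up_mitf = length(significant_genes(rsa_mitf, cfg$rsa$q_cutoff, "up")),
    n_sig_down_yy1 = length(sig_down_yy1),
    precision_down_mitf = if (length(sig_down_mitf) > 0)
      mean(sig_down_mitf %in% truth_down_mitf) else NA_real_,
    recall_down_mitf = if (length(truth_down_mitf) > 0)
      mean(truth_down_mitf %in% sig_down_mitf) else NA_real_,
    q_cutoff = cfg$rsa$q_cutoff)
  write_rsa_records(rsa_mitf, file.path(d3, "rsa_mitf.tsv"))
  write_rsa_records(rsa_yy1, file.path(d3, "rsa_yy1.tsv"))
  jsonlite::write_json(rsa_summary, file.path(d3, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, list.files(d3, full.names = TRUE))

  ## stage 4: co-regulation ------------------------------------------------
  d4 <- stage_dir("coreg")
  x <- rowMeans(sim_expr$mitf)
  y <- rowMeans(sim_expr$yy1)
  curve <- coreg_curve(x, y, n_boot = cfg$coreg$n_boot,
                       n_perm = cfg$coreg$n_perm, span = cfg$coreg$span,
                       grid_size = cfg$coreg$grid_size, seed = stage_seeds[6])
  ov_curve <- overlap_significance_curve(rsa_mitf, rsa_yy1,
                                         k_grid = cfg$coreg$k_grid)
  mode_p <- vapply(split(ov_curve$fisher_p, ov_curve$mode), max, 0)
  coreg_summary <- list(
    n_outside = sum(curve$outside),
    n_outside_lower_left = sum(curve$outside & curve$grid < 0 &
                                 curve$bagged < curve$env_lo),
    max_p_co_activated = unname(mode_p[["co_activated"]]),
    max_p_co_repressed = unname(mode_p[["co_repressed"]]),
    max_p_antagonistic_1 = unname(mode_p[["antagonistic_1"]]),
    max_p_antagonistic_2 = unname(mode_p[["antagonistic_2"]]),
    min_p_antagonistic = min(ov_curve$fisher_p[startsWith(ov_curve$mode, "antagonistic")]),
    k_grid = cfg$coreg$k_grid)
  data.table::fwrite(curve, file.path(d4, "coreg_curve.tsv"), sep = "\t")
  data.table::fwrite(ov_curve, file.path(d4, "overlap_curve.tsv"), sep = "\t")
  jsonlite::write_json(coreg_summary, file.path(d4, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, list.files(d4, full.names = TRUE))

  ## stage 5: motif enrichment ---------------------------------------------
  d5 <- stage_dir("motif")
  motif <- ebox_pwm()
  fg_scores <- scan_best_scores(motif, sim_seq$fg)
  bg_scores <- scan_best_scores(motif, sim_seq$bg)
  enr <- optimal_cutoff_binomial(fg_scores, bg_scores, motif_id = motif$motif_id)
  p_cal <- calibrate_by_label_permutation(fg_scores, bg_scores,
                                          n_perm = cfg$motif$n_perm,
                                          seed = stage_seeds[7])
  motif_summary <- c(enr, list(p_calibrated = p_cal))
  data.table::fwrite(data.frame(region = names(sim_seq$fg), score = fg_scores),
                     file.path(d5, "fg_scores.tsv"), sep = "\t")
  data.table::fwrite(data.frame(region = names(sim_seq$bg), score = bg_scores),
                     file.path(d5, "bg_scores.tsv"), sep = "\t")
  jsonlite::write_json(motif_summary, file.path(d5, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, list.files(d5, full.names = TRUE))

  ## stage 6: interval analyses --------------------------------------------
  d6 <- stage_dir("intervals")
  ovf <- overlap_fraction(sim_sets$a, sim_sets$b)
  spec_retained <- specific_sites(sim_sets$a, list(sim_sets$b),
                                  distance = cfg$intervals$specificity_distance)
  assignments <- assign_peaks_to_genes(peaks, sim_genes,
                                       tss_window = cfg$intervals$tss_window,
                                       mode = cfg$intervals$mode)
  nearest <- if (nrow(peaks) > 0 &&
                 any(peaks$chrom == sim_genes$chrom[1])) {
    nearest_peak_to_tss(peaks, sim_genes[1, , drop = FALSE])
  } else NULL
  interval_summary <- list(
    overlap_fraction = ovf$fraction,
    n_a = ovf$n_a, n_a_overlapping = ovf$n_a_overlapping,
    n_specific_retained = nrow(spec_retained),
    n_assignments = nrow(assignments),
    nearest_peak_distance = if (is.null(nearest)) NA_real_ else
      nearest$signed_distance)
  data.table::fwrite(assignments, file.path(d6, "gene_assignments.tsv"), sep = "\t")
  write_bed(spec_retained[, c("chrom", "start", "end", "name", "score", "strand")],
            file.path(d6, "specific_sites.bed"))
  jsonlite::write_json(interval_summary, file.path(d6, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, list.files(d6, full.names = TRUE))

  ## manifest ---------------------------------------------------------------
  digests <- tools::md5sum(paths)
  names(digests) <- file.path(basename(dirname(paths)), basename(paths))
  manifest <- list(
    config = cfg, seed = seed, stage_seeds = stage_seeds,
    summary = list(peaks = peak_summary, rsa = rsa_summary,
                   coreg = coreg_summary, motif = motif_summary,
                   intervals = interval_summary),
    files = as.list(digests),
    versions = list(package = as.character(utils::packageVersion("chipcoreg"))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$results <- list(
    sim_chip = sim_chip, sim_expr = sim_expr, sim_seq = sim_seq,
    sim_sets = sim_sets, sim_genes = sim_genes, peaks = peaks,
    rsa_mitf = rsa_mitf, rsa_yy1 = rsa_yy1, curve = curve,
    overlap_curve = ov_curve, enrichment = enr, assignments = assignments)
  manifest$outdir <- outdir
  invisible(manifest)
}

#' One-page human-readable run report
#'
#' @param manifest Output of [run_all()].
#' @return Character vector of report lines (also printed).
#' @export
report <- function(manifest) {
  s <- manifest$summary
  if (is.null(s$peaks) || is.null(s$rsa) || is.null(s$coreg) ||
      is.null(s$motif) || is.null(s$intervals)) {
    stop("incomplete manifest: missing stage summaries")
  }
  fmt_p <- function(p) formatC(p, format = "e", digits = 2)
  lines <- c(
    sprintf("chipcoreg run (seed %d)", manifest$seed),
    "",
    "-- peak calling (Skellam null) --",
    sprintf("  peaks called: %d   depth ratio r = %.3f", s$peaks$n_peaks,
            s$peaks$depth_ratio),
    if (!is.na(s$peaks$recall))
      sprintf("  vs truth: recall %.3f, false positives %d", s$peaks$recall,
              s$peaks$false_positives),
    "-- RSA differential expression --",
    sprintf("  N = %d pooled values, m = %d; pi0(down, MITF-side) = %.3f",
            s$rsa$N, s$rsa$m, s$rsa$pi0_down_mitf),
    sprintf("  significant at q <= %g: %d down / %d up (MITF), %d down (YY1)",
            s$rsa$q_cutoff, s$rsa$n_sig_down_mitf, s$rsa$n_sig_up_mitf,
            s$rsa$n_sig_down_yy1),
    if (!is.na(s$rsa$precision_down_mitf))
      sprintf("  vs truth: precision %.3f, recall %.3f",
              s$rsa$precision_down_mitf, s$rsa$recall_down_mitf),
    "-- co-regulation --",
    sprintf("  bagged curve outside the null envelope at %d grid points (%d in the co-activated quadrant)",
            s$coreg$n_outside, s$coreg$n_outside_lower_left),
    sprintf("  overlap curve: co-activated max p %s, co-repressed max p %s, antagonistic min p %s",
            fmt_p(s$coreg$max_p_co_activated), fmt_p(s$coreg$max_p_co_repressed),
            fmt_p(s$coreg$min_p_antagonistic)),
    "-- motif enrichment --",
    sprintf("  %s: %s-represented, cutoff %.3f, fg %d/%d vs bg %d/%d, binomial p %s, calibrated p %s",
            s$motif$motif_id, s$motif$direction, s$motif$cutoff,
            s$motif$fg_hits, s$motif$fg_total, s$motif$bg_hits,
            s$motif$bg_total, fmt_p(s$motif$p_binomial),
            fmt_p(s$motif$p_calibrated)),
    "-- interval analyses --",
    sprintf("  peak-set overlap fraction: %.3f (%d / %d)",
            s$intervals$overlap_fraction, s$intervals$n_a_overlapping,
            s$intervals$n_a),
    sprintf("  specificity filter retained %d sites; %d peak-gene assignments",
            s$intervals$n_specific_retained, s$intervals$n_assignments),
    if (!is.na(s$intervals$nearest_peak_distance))
      sprintf("  nearest peak to the first gene's TSS: %+d bp",
              as.integer(s$intervals$nearest_peak_distance))
  )
  lines <- lines[!vapply(lines, is.null, TRUE)]
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
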