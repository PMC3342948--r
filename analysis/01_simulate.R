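#!/usr/bin/env Rscript

# Stage 1 -- simulate every input the downstream analyses need, with the
# statistical structure the real study's data carries: ChIP/control read
# tracks with planted binding sites and a realistic depth ratio, paired
# knockdown fold-change tables with planted co-regulated gene classes,
# sequence sets with planted E-box instances, paired peak sets with a
# controlled overlap fraction, and multi-exon gene models.

suppressMessages(library(chipcoreg))

master_seed <- as.integer(Sys.getenv("CHIPCOREG_SEED", "42"))
seeds <- derive_stage_seeds(master_seed)
cfg <- default_config()
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
message("master seed ", master_seed, "; stage seeds ",
        paste(seeds[1:5], collapse = ", "))

sim_chip <- simulate_chipseq(do.call(chip_sim_spec, c(
  list(genome = cfg$genome, seed = seeds[1]), cfg$chip)))
write_track_bed(sim_chip$chip, file.path(out, "chip_reads.bed"))
write_track_bed(sim_chip$ctrl, file.path(out, "ctrl_reads.bed"))
write_bed(sim_chip$truth_peaks, file.path(out, "truth_peaks.bed"))
message("ChIP-seq: ", sim_chip$chip$total_depth, " ChIP / ",
        sim_chip$ctrl$total_depth, " control reads, ",
        nrow(sim_chip$truth_peaks), " planted peaks")

sim_expr <- simulate_expression(do.call(expr_sim_spec, c(
  list(seed = seeds[2]), cfg$expr)))
write_foldchange_table(sim_expr$mitf, file.path(out, "foldchange_mitf.tsv"))
write_foldchange_table(sim_expr$yy1, file.path(out, "foldchange_yy1.tsv"))
data.table::fwrite(sim_expr$truth, file.path(out, "expr_truth.tsv"), sep = "\t")
message("expression: ", nrow(sim_expr$mitf), " genes; classes: ",
        paste(names(table(sim_expr$truth$class)),
              table(sim_expr$truth$class), collapse = ", "))

sim_seq <- simulate_sequences(do.call(motif_sim_spec, c(
  list(seed = seeds[3]), cfg$motif[setdiff(names(cfg$motif), "n_perm")])))
write_fasta(sim_seq$fg, file.path(out, "foreground.fa"))
write_fasta(sim_seq$bg, file.path(out, "background.fa"))
data.table::fwrite(sim_seq$truth, file.path(out, "motif_truth.tsv"), sep = "\t")
message("sequences: ", length(sim_seq$fg), " fg / ", length(sim_seq$bg),
        " bg regions, ", nrow(sim_seq$truth), " planted motif instances")

sim_sets <- do.call(simulate_peak_sets, c(
  list(genome = cfg$genome, seed = seeds[4]), cfg$peaksets))
write_bed(sim_sets$a, file.path(out, "peakset_a.bed"))
write_bed(sim_sets$b, file.path(out, "peakset_b.bed"))

sim_genes <- do.call(simulate_gene_models, c(
  list(genome = cfg$genome, seed = seeds[5]), cfg$genes))
write_bed12_genes(sim_genes, file.path(out, "genes.bed12"))
message("peak sets (target overlap ", cfg$peaksets$overlap_target, ") and ",
        nrow(sim_genes), " gene models written under ", out)
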