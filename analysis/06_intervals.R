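#!/usr/bin/env Rscript

# Stage 6 -- binding-site interval analyses: the overlap fraction
# between two peak sets, the cell-line-specificity filter (summits more
# than 5 kb from every other-set summit survive), assignment of called
# peaks to genes by the TSS-window / intron rule, and the nearest peak
# to each gene's TSS.

suppressMessages(library(chipcoreg))

cfg <- default_config()
sim <- "results/01_simulate"
out <- "results/06_intervals"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

set_a <- read_bed(file.path(sim, "peakset_a.bed"))
set_b <- read_bed(file.path(sim, "peakset_b.bed"))
peaks <- read_bed("results/02_call_peaks/peaks.bed")
genes <- read_bed12_genes(file.path(sim, "genes.bed12"))

ovf <- overlap_fraction(set_a, set_b)
message(sprintf("overlap fraction of set A in set B: %.3f (%d/%d)",
                ovf$fraction, ovf$n_a_overlapping, ovf$n_a))

kept <- specific_sites(set_a, list(set_b),
                       distance = cfg$intervals$specificity_distance)
write_bed(kept, file.path(out, "specific_sites.bed"))
message(sprintf("specificity filter (%d bp): %d of %d sites retained",
                cfg$intervals$specificity_distance, nrow(kept), nrow(set_a)))

assignments <- assign_peaks_to_genes(peaks, genes,
                                     tss_window = cfg$intervals$tss_window,
                                     mode = cfg$intervals$mode)
data.table::fwrite(assignments, file.path(out, "gene_assignments.tsv"),
                   sep = "\t")
message(sprintf("%d peak-gene assignments (mode %s, TSS window %d bp)",
                nrow(assignments), cfg$intervals$mode,
                cfg$intervals$tss_window))

nearest <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
  g <- genes[i, , drop = FALSE]
  if (!any(peaks$chrom == g$chrom)) return(NULL)
  res <- nearest_peak_to_tss(peaks, g)
  data.frame(gene_id = g$gene_id, peak_name = res$peak$name,
             signed_distance = res$signed_distance)
}))
data.table::fwrite(nearest, file.path(out, "nearest_peaks.tsv"), sep = "\t")
summary <- list(overlap_fraction = ovf$fraction,
                n_specific_retained = nrow(kept),
                n_assignments = nrow(assignments),
                median_abs_tss_distance = stats::median(abs(nearest$signed_distance)))
jsonlite::write_json(summary, file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("median |nearest-peak TSS distance| over %d genes: %d bp",
                nrow(nearest), as.integer(summary$median_abs_tss_distance)))
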