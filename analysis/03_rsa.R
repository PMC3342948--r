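#!/usr/bin/env Rscript

# Stage 3 -- score differential expression for each knockdown by the
# RSA pooled-rank statistic: pool all replicate log fold-changes, rank
# them, take each gene's minimum hypergeometric tail probability in the
# down and up directions, and convert to Storey q-values.

suppressMessages(library(chipcoreg))

cfg <- default_config()
sim <- "results/01_simulate"
out <- "results/03_rsa"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mitf <- read_foldchange_table(file.path(sim, "foldchange_mitf.tsv"))
yy1 <- read_foldchange_table(file.path(sim, "foldchange_yy1.tsv"))
truth <- read.delim(file.path(sim, "expr_truth.tsv"))

rec_m <- rsa_rank(mitf, lambda = cfg$rsa$lambda)
rec_y <- rsa_rank(yy1, lambda = cfg$rsa$lambda)
write_rsa_records(rec_m, file.path(out, "rsa_mitf.tsv"))
write_rsa_records(rec_y, file.path(out, "rsa_yy1.tsv"))

sig_m <- significant_genes(rec_m, cfg$rsa$q_cutoff, "down")
sig_y <- significant_genes(rec_y, cfg$rsa$q_cutoff, "down")
truth_down <- truth$gene_id[truth$class %in% c("co_activated", "mitf_only",
                                               "antagonistic")]
summary <- list(
  N = attr(rec_m, "N"), m = attr(rec_m, "m"),
  pi0_down_mitf = attr(rec_m, "pi0_down"),
  n_sig_down_mitf = length(sig_m), n_sig_down_yy1 = length(sig_y),
  precision_down_mitf = mean(sig_m %in% truth_down),
  recall_down_mitf = mean(truth_down %in% sig_m),
  q_cutoff = cfg$rsa$q_cutoff)
jsonlite::write_json(summary, file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf(
  "MITF-side: %d genes down at q <= %g (precision %.3f, recall %.3f); YY1-side: %d",
  length(sig_m), cfg$rsa$q_cutoff, summary$precision_down_mitf,
  summary$recall_down_mitf, length(sig_y)))
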