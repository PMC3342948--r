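# Independent oracles used across the suite. These deliberately use the
# most transparent algorithm available (truncated convolutions, exhaustive
# enumeration, brute-force loops) rather than the package's code paths.

# Skellam pmf by truncated convolution of two Poisson pmfs.
oracle_skellam_pmf <- function(k, mu1, mu2, n_terms = 200) {
  j <- 0:n_terms
  sum(dpois(j + k, mu1) * dpois(j, mu2))
}

# Upper tail by summing the convolution pmf well past the mode.
oracle_skellam_sf <- function(d, mu1, mu2, extra = 400) {
  sum(vapply(d:(d + extra), oracle_skellam_pmf, 0, mu1 = mu1, mu2 = mu2))
}

# Minimum hypergeometric rank statistic by exhaustive enumeration of all
# C(N, m) equally likely placements of the gene's m values.
oracle_rsa_p <- function(ranks, N) {
  m <- length(ranks)
  subsets <- combn(N, m)
  tail_p <- function(j, r) {
    mean(apply(subsets, 2, function(s) sum(s <= r) >= j))
  }
  min(vapply(seq_len(m), function(j) tail_p(j, ranks[j]), 0))
}

# Hypergeometric upper tail for the top-k overlap, by direct summation of
# the 2x2-table probabilities C(k,x) C(U-k, k-x) / C(U, k).
oracle_overlap_p <- function(overlap, k, universe) {
  x <- overlap:k
  sum(choose(k, x) * choose(universe - k, k - x)) / choose(universe, k)
}

# Brute-force best PWM hit: every window, both strands, per-column sums.
oracle_scan_best <- function(x, sequence) {
  lo <- log2(chipcoreg::pwm_probs(x) / x$background)
  L <- ncol(lo)
  score_window <- function(s) {
    bases <- strsplit(s, "")[[1]]
    sum(vapply(seq_len(L), function(j) {
      if (bases[j] %in% rownames(lo)) lo[bases[j], j] else 0
    }, 0))
  }
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  n <- nchar(sequence)
  best <- list(score = -Inf, offset = NA, strand = NA)
  for (strand in c("+", "-")) {
    for (off in 0:(n - L)) {
      win <- substr(sequence, off + 1, off + L)
      if (strand == "-") win <- rc(win)
      sc <- score_window(win)
      better <- sc > best$score ||
        (sc == best$score && (off < best$offset ||
                                (off == best$offset && strand == "+" && best$strand == "-")))
      if (better) best <- list(score = sc, offset = off, strand = strand)
    }
  }
  best
}

# All-pairs interval overlap check.
oracle_overlap_any <- function(a, b, minbp = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
          pmin(b$end, a$end[i]) - pmax(b$start, a$start[i]) >= minbp)
  }, TRUE)
}

# All-pairs peak-to-gene assignment by the TSS-window / body rule.
oracle_assignments <- function(peaks, genes, tss_window, mode) {
  summits <- floor((peaks$start + peaks$end) / 2)
  if ("summit" %in% names(peaks)) summits <- peaks$summit
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (g in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[g]) next
      s <- summits[i]
      ex <- genes$exons[[g]]
      in_tss <- abs(s - genes$tss[g]) <= tss_window
      in_span <- s >= genes$gene_start[g] && s < genes$gene_end[g]
      in_exon <- any(ex[, 1] <= s & s < ex[, 2])
      ok <- in_tss || (mode == "intron" && in_span && !in_exon) ||
        (mode == "gene_body" && in_span)
      if (ok) {
        rows[[length(rows) + 1]] <- data.frame(
          peak = i, gene_id = genes$gene_id[g], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(peak = integer(0), gene_id = character(0)))
  }
  do.call(rbind, rows)
}

# Random interval frame for property tests.
random_intervals <- function(n, genome = c(chr1 = 1e5, chr2 = 1e5),
                             max_width = 500) {
  chrom <- sample(names(genome), n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  start <- floor(runif(n, 0, genome[chrom] - width))
  genomic_intervals(chrom, start, start + width,
                    name = sprintf("iv%d", seq_len(n)),
                    score = round(runif(n, 0, 100), 2),
                    strand = sample(c("+", "-", "."), n, replace = TRUE))
}
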