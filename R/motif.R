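#' Construct a position weight matrix
#'
#' Counts are regularised with a background-proportional pseudocount
#' (`pseudocount` times the column total, split by the background base
#' frequencies) before conversion to probabilities, so zero-count cells
#' never produce infinite log-odds.
#'
#' @param counts 4 x L non-negative matrix, rows A, C, G, T.
#' @param motif_id Label for the motif.
#' @param pseudocount Fraction of the column total added as pseudocount.
#' @param background Base frequencies (A, C, G, T), strictly positive,
#'   summing to 1.
#' @return A `pwm` object (list with `motif_id`, `counts`, `pseudocount`,
#'   `background`).
#' @export
pwm <- function(counts, motif_id = "motif", pseudocount = 0.01,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 1, all(counts >= 0),
            length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-8, pseudocount > 0)
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, counts = counts,
                 pseudocount = pseudocount,
                 background = stats::setNames(background, c("A", "C", "G", "T"))),
            class = "pwm")
}

#' Probability matrix of a PWM
#'
#' @param x A [pwm()].
#' @return 4 x L matrix of per-position base probabilities (columns sum
#'   to 1).
#' @export
pwm_probs <- function(x) {
  tot <- colSums(x$counts)
  tot[tot == 0] <- 1
  p <- sweep(x$counts + outer(x$background, tot * x$pseudocount),
             2, tot * (1 + x$pseudocount), "/")
  rownames(p) <- c("A", "C", "G", "T")
  p
}

# log2-odds scoring matrix
pwm_logodds <- function(x) {
  log2(pwm_probs(x) / x$background)
}

#' PWM for a one-hot motif consensus
#'
#' @param consensus Consensus string over A/C/G/T.
#' @param n Count assigned to the consensus base per column.
#' @param ... Passed to [pwm()].
#' @return A [pwm()].
#' @export
consensus_pwm <- function(consensus, n = 100, ...) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  m <- matrix(0, 4, length(bases), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- n
  pwm(m, motif_id = paste0("consensus_", consensus), ...)
}

#' Default E-box motif
#'
#' CATGTG-core E-box (the CANNTG family bound by basic helix-loop-helix
#' factors such as MITF), with modest degeneracy at the central
#' positions.
#'
#' @return A [pwm()].
#' @export
ebox_pwm <- function() {
  counts <- matrix(c(
    # C    A    T    G    T    G
    2, 90, 4, 2, 2, 2,      # A
    90, 4, 2, 4, 4, 2,      # C
    4, 4, 4, 90, 4, 92,     # G
    4, 2, 90, 4, 90, 4      # T
  ), nrow = 4, byrow = TRUE)
  pwm(counts, motif_id = "Ebox_CATGTG")
}

seq_to_code <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
}

revcomp <- function(sequence) {
  paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", sequence), "")[[1]]),
        collapse = "")
}

#' Score one window against a PWM
#'
#' Log2 odds of the window under the motif model vs the background:
#' `sum_i log2(p_i(base_i) / background(base_i))`. Ambiguous bases (N and
#' friends) contribute 0 (background odds).
#'
#' @param x A [pwm()].
#' @param window String of length `L` (the motif width).
#' @return Log-odds score.
#' @export
pssm_score <- function(x, window) {
  lo <- pwm_logodds(x)
  code <- seq_to_code(window)
  if (length(code) != ncol(lo)) {
    stop("window length ", length(code), " != motif width ", ncol(lo))
  }
  contrib <- lo[cbind(code, seq_along(code))]
  sum(contrib[!is.na(code)])
}

# all window scores along one strand; NA bases contribute 0
scan_scores_one <- function(lo, code) {
  L <- ncol(lo)
  n <- length(code)
  if (n < L) stop("sequence shorter than motif width")
  sc <- numeric(n - L + 1)
  for (j in seq_len(L)) {
    idx <- code[j:(j + n - L)]
    v <- lo[idx, j]
    v[is.na(idx)] <- 0
    sc <- sc + v
  }
  sc
}

#' Best PWM score on a sequence
#'
#' Scans every window on the forward sequence and, when `both_strands`,
#' on the reverse complement, and reports the maximum score with its
#' location. Offsets are 0-based on the forward strand (for a `-` hit,
#' the offset of the leftmost base of the matched window). Ties break
#' deterministically: smaller offset first, then `+` before `-`.
#'
#' @param x A [pwm()].
#' @param sequence DNA string, length >= motif width.
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return List with `score`, `offset`, `strand`.
#' @export
scan_best <- function(x, sequence, both_strands = TRUE) {
  lo <- pwm_logodds(x)
  L <- ncol(lo)
  code_f <- seq_to_code(sequence)
  n <- length(code_f)
  if (n < L) stop("sequence length ", n, " < motif width ", L)
  sc_f <- scan_scores_one(lo, code_f)
  offs <- seq_along(sc_f) - 1
  cand <- data.frame(score = sc_f, offset = offs, strand = "+")
  if (both_strands) {
    code_r <- seq_to_code(revcomp(sequence))
    sc_r <- scan_scores_one(lo, code_r)
    # rc window starting at o (1-based) covers forward bases [n-o-L+2, n-o+1]
    offs_r <- n - (seq_along(sc_r) - 1) - L
    cand <- rbind(cand, data.frame(score = sc_r, offset = offs_r, strand = "-"))
  }
  cand <- cand[order(-cand$score, cand$offset, cand$strand), ]
  list(score = cand$score[1], offset = cand$offset[1], strand = cand$strand[1])
}

#' Best scores of a PWM over a set of sequences
#'
#' @param x A [pwm()].
#' @param sequences Character vector of sequences.
#' @param both_strands Passed to [scan_best()].
#' @return Numeric vector of per-sequence best scores.
#' @export
scan_best_scores <- function(x, sequences, both_strands = TRUE) {
  vapply(sequences, function(s) scan_best(x, s, both_strands)$score, 0,
         USE.NAMES = FALSE)
}

#' Motif enrichment with an adaptive score cutoff
#'
#' Every distinct observed best score is a candidate cutoff; at each, a
#' foreground region is a hit iff its best score reaches the cutoff, and
#' the foreground hit count is tested against the background hit rate
#' with an exact binomial test in both directions (over- and
#' under-representation; the background rate is clamped away from 0 and
#' 1 by half a count). The reported cutoff/direction minimise the
#' binomial p-value; because of this minimisation the p-value is
#' selection-biased and [calibrate_by_label_permutation()] provides the
#' honest version.
#'
#' @param fg_best_scores,bg_best_scores Per-region best scores (see
#'   [scan_best_scores()]).
#' @param motif_id Label carried into the result.
#' @return List: `motif_id`, `cutoff`, `fg_hits`, `fg_total`, `bg_hits`,
#'   `bg_total`, `direction` (`"over"`/`"under"`), `p_binomial`, and the
#'   per-direction `p_over`/`p_under` at the chosen cutoff, plus
#'   `n_candidate_cutoffs`.
#' @export
optimal_cutoff_binomial <- function(fg_best_scores, bg_best_scores,
                                    motif_id = "motif") {
  stopifnot(length(fg_best_scores) > 0, length(bg_best_scores) > 0)
  FF <- length(fg_best_scores); BB <- length(bg_best_scores)
  cuts <- sort(unique(c(fg_best_scores, bg_best_scores)))
  if (length(cuts) == 1) {
    warning("all scores identical: degenerate enrichment result")
    return(list(motif_id = motif_id, cutoff = cuts, fg_hits = FF,
                fg_total = FF, bg_hits = BB, bg_total = BB,
                direction = "over", p_binomial = 1, p_over = 1, p_under = 1,
                n_candidate_cutoffs = 1L))
  }
  fg_sorted <- sort(fg_best_scores)
  bg_sorted <- sort(bg_best_scores)
  f <- FF - findInterval(cuts - 1e-12, fg_sorted)   # #fg >= cutoff
  b <- BB - findInterval(cuts - 1e-12, bg_sorted)
  rate <- pmin(pmax(b / BB, 1 / (2 * BB)), 1 - 1 / (2 * BB))
  p_over <- stats::pbinom(f - 1, FF, rate, lower.tail = FALSE)
  p_under <- stats::pbinom(f, FF, rate)
  best_over <- min(p_over); best_under <- min(p_under)
  if (best_over <= best_under) {
    direction <- "over"
    i <- max(which(p_over == best_over))    # ties: highest cutoff
    p <- best_over
  } else {
    direction <- "under"
    i <- max(which(p_under == best_under))
    p <- best_under
  }
  list(motif_id = motif_id, cutoff = cuts[i], fg_hits = f[i], fg_total = FF,
       bg_hits = b[i], bg_total = BB, direction = direction,
       p_binomial = p, p_over = p_over[i], p_under = p_under[i],
       n_candidate_cutoffs = length(cuts))
}

#' Permutation calibration of the adaptive-cutoff p-value
#'
#' Permutes the foreground/background labels of the pooled best scores
#' `n_perm` times, recomputes the minimised binomial p-value for each
#' permutation, and reports `(1 + #{perm p <= observed p}) / (n_perm + 1)`.
#' This is the honest significance of the adaptive-cutoff statistic.
#'
#' @inheritParams optimal_cutoff_binomial
#' @param n_perm Number of label permutations (>= 100).
#' @param seed RNG seed.
#' @return Calibrated p-value.
#' @export
calibrate_by_label_permutation <- function(fg_best_scores, bg_best_scores,
                                           n_perm = 200, seed = NULL) {
  stopifnot(n_perm >= 100)
  obs <- optimal_cutoff_binomial(fg_best_scores, bg_best_scores)$p_binomial
  pool <- c(fg_best_scores, bg_best_scores)
  nf <- length(fg_best_scores)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), nf)
      p <- suppressWarnings(
        optimal_cutoff_binomial(pool[idx], pool[-idx])$p_binomial)
      if (p <= obs) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  })
}

#' Random regions matched in count and length to an input set
#'
#' Places one random region per input region (identical length multiset,
#' index by index) uniformly on the genome, rejecting placements that
#' intersect `exclude`.
#'
#' @param regions Interval frame to match.
#' @param genome Named chromosome lengths.
#' @param seed RNG seed.
#' @param exclude Optional interval frame the placements must avoid.
#' @param max_tries Rejection-sampling cap per region.
#' @return Interval frame of matched random regions.
#' @export
matched_random_regions <- function(regions, genome, seed = NULL,
                                   exclude = NULL, max_tries = 10000) {
  widths <- regions$end - regions$start
  with_seed(seed, {
    out_chrom <- character(length(widths))
    out_start <- numeric(length(widths))
    for (i in seq_along(widths)) {
      w <- widths[i]
      ok_chroms <- names(genome)[genome >= w]
      if (length(ok_chroms) == 0) stop("no chromosome can host a ", w, "-bp region")
      for (try in seq_len(max_tries)) {
        chrom <- if (length(ok_chroms) == 1) ok_chroms else
          sample(ok_chroms, 1, prob = genome[ok_chroms] - w + 1)
        s <- floor(stats::runif(1, 0, genome[[chrom]] - w + 1))
        cand <- data.frame(chrom = chrom, start = s, end = s + w)
        if (is.null(exclude) || nrow(exclude) == 0 ||
            !any(intervals_overlap_any(cand, exclude))) {
          out_chrom[i] <- chrom; out_start[i] <- s
          break
        }
        if (try == max_tries) {
          stop("could not place a ", w, "-bp region avoiding the exclude set")
        }
      }
    }
    genomic_intervals(out_chrom, out_start, out_start + widths,
                      name = sprintf("rand_%d", seq_along(widths)))
  })
}

#' Read / write sequences as FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as plain named
#' character vectors inside the package.
#'
#' @param path FASTA path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a JASPAR-style count matrix file
#'
#' Accepts the common 4-line `A [ ... ]` layout under a `>ID name`
#' header; multiple motifs per file are supported.
#'
#' @param path Path to the matrix file.
#' @return List of [pwm()] objects.
#' @export
read_jaspar_pwms <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no '>' motif headers in ", path)
  lapply(seq_along(starts), function(i) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    block <- lines[(starts[i] + 1):(starts[i] + 4)]
    rows <- lapply(block, function(l) {
      body <- sub("^[ACGTacgt]", "", l)
      as.numeric(regmatches(body, gregexpr("[0-9.]+", body))[[1]])
    })
    base_order <- toupper(substr(block, 1, 1))
    m <- do.call(rbind, rows)[match(c("A", "C", "G", "T"), base_order), , drop = FALSE]
    pwm(m, motif_id = id)
  })
}

#' Write a PWM in JASPAR count-matrix layout
#'
#' @param x A [pwm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pwm <- function(x, path) {
  lines <- c(paste0(">", x$motif_id),
             vapply(c("A", "C", "G", "T"), function(b) {
               paste0(b, "  [ ", paste(format(x$counts[b, ], trim = TRUE),
                                       collapse = " "), " ]")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
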