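#' Pool fold-changes across experiments and rank them
#'
#' All log fold-changes from one or more tables sharing the same gene
#' universe are pooled into a single increasing ordering, and each gene
#' receives the list of ordinal ranks its replicate values occupy. Ties
#' are broken deterministically by the (value, experiment index, gene
#' index) triple, so a re-run is identical.
#'
#' @param tables A fold-change matrix (genes x experiments) or a list of
#'   such matrices over the same genes.
#' @return List with `N` (total pooled values), `m` (experiments per
#'   gene), `gene_ids`, and `ranks`: per gene, the sorted integer ranks of
#'   its `m` values in the pooled increasing ordering.
#' @export
pool_and_rank <- function(tables) {
  if (is.matrix(tables)) tables <- list(tables)
  genes <- rownames(tables[[1]])
  for (t in tables) {
    if (!identical(sort(rownames(t)), sort(genes))) {
      diff <- union(setdiff(rownames(t), genes), setdiff(genes, rownames(t)))
      stop("tables do not share the gene universe; differing ids: ",
           paste(utils::head(diff, 5), collapse = ", "))
    }
  }
  mat <- do.call(cbind, lapply(tables, function(t) t[genes, , drop = FALSE]))
  G <- nrow(mat); m <- ncol(mat); N <- G * m
  v <- as.vector(mat)                     # column-major: gene fast, experiment slow
  gene_idx <- rep(seq_len(G), times = m)
  exp_idx <- rep(seq_len(m), each = G)
  ord <- order(v, exp_idx, gene_idx)
  rk <- integer(N)
  rk[ord] <- seq_len(N)
  ranks <- split(rk, gene_idx)
  ranks <- lapply(ranks, sort)
  names(ranks) <- genes
  list(N = N, m = m, gene_ids = genes, ranks = ranks)
}

#' Minimum hypergeometric p-value over a gene's pooled ranks
#'
#' Given the sorted ranks `r_1 < ... < r_m` of one gene's replicate
#' fold-changes in the pooled ordering of all `N` values, the statistic is
#' `min_j P(X >= j)` with `X ~ Hypergeometric(N, m, r_j)`: the chance that
#' a random placement of the gene's `m` values puts at least `j` of them
#' inside the top `r_j` positions. No correction is applied for taking
#' the minimum (the calibrated variant is [rsa_permutation_p()]).
#'
#' @param ranks Increasing integer ranks, length `m`.
#' @param N Total pooled values.
#' @param m Values per gene (defaults to `length(ranks)`).
#' @return p-value in `(0, 1]`.
#' @export
rsa_min_hypergeom <- function(ranks, N, m = length(ranks)) {
  stopifnot(m >= 1, all(ranks >= 1), all(ranks <= N), !is.unsorted(ranks))
  j <- seq_len(m)
  min(stats::phyper(j - 1, m, N - m, ranks, lower.tail = FALSE))
}

#' Permutation-calibrated RSA p-value
#'
#' Monte-Carlo calibration of the minimum-hypergeometric statistic:
#' random rank sets of size `m` are drawn from `1..N` and the fraction of
#' draws with a statistic at least as small as the observed one is
#' reported (with the +1 correction). Guards the selection bias of the
#' minimum; not the default reporting route.
#'
#' @inheritParams rsa_min_hypergeom
#' @param n_perm Number of random draws.
#' @return Calibrated p-value.
#' @export
rsa_permutation_p <- function(ranks, N, m = length(ranks), n_perm = 1000) {
  obs <- rsa_min_hypergeom(ranks, N, m)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    rr <- sort(sample.int(N, m))
    if (rsa_min_hypergeom(rr, N, m) <= obs) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0 = #{p > lambda} / ((1 - lambda) n)`
#' (capped at 1) and multiplies the Benjamini-Hochberg step-up values by
#' it. With a vector `lambda`, `pi0` is taken from a cubic smoothing
#' spline of the per-lambda estimates evaluated at `max(lambda)`. With
#' `pi0 = 1` the result is exactly Benjamini-Hochberg.
#'
#' @param pvalues Vector of p-values in `(0, 1]`.
#' @param lambda Tuning value(s) in `[0, 1)` for the `pi0` estimate.
#' @param pi0 Optional override of the estimated `pi0`.
#' @return List with `qvalues` (same order as input) and `pi0`.
#' @export
storey_qvalues <- function(pvalues, lambda = 0.5, pi0 = NULL) {
  if (length(pvalues) == 0) stop("no p-values supplied")
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  if (is.null(pi0)) {
    est <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l), 0)
    if (length(lambda) > 1) {
      fit <- stats::smooth.spline(lambda, est, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
    } else {
      pi0 <- est
    }
    pi0 <- min(max(pi0, 0), 1)
  }
  q <- pmin(pi0 * stats::p.adjust(pvalues, method = "BH"), 1)
  list(qvalues = q, pi0 = pi0)
}

#' RSA scoring of one knockdown's fold-change tables
#'
#' Runs the full pooled-rank analysis for one knockdown: pools the
#' replicate fold-changes, computes each gene's minimum hypergeometric
#' p-value in the down direction (increasing ordering: most negative
#' fold-changes rank first) and the up direction (decreasing ordering,
#' equivalent to ranking the negated values), and converts both p-value
#' vectors to q-values.
#'
#' @param tables Fold-change matrix or list of matrices (see
#'   [pool_and_rank()]).
#' @param lambda Passed to [storey_qvalues()].
#' @return `data.frame` with one row per gene: `gene_id`, `p_down`,
#'   `p_up`, `q_down`, `q_up`, plus list-columns `ranks_down`,
#'   `ranks_up`; attributes `N`, `m`, `pi0_down`, `pi0_up`.
#' @export
rsa_rank <- function(tables, lambda = 0.5) {
  if (is.matrix(tables)) tables <- list(tables)
  pooled_down <- pool_and_rank(tables)
  pooled_up <- pool_and_rank(lapply(tables, function(t) -t))
  p_down <- vapply(pooled_down$ranks,
                   rsa_min_hypergeom, 0, N = pooled_down$N, m = pooled_down$m)
  p_up <- vapply(pooled_up$ranks,
                 rsa_min_hypergeom, 0, N = pooled_up$N, m = pooled_up$m)
  qd <- storey_qvalues(p_down, lambda = lambda)
  qu <- storey_qvalues(p_up, lambda = lambda)
  out <- data.frame(gene_id = pooled_down$gene_ids,
                    p_down = unname(p_down), p_up = unname(p_up),
                    q_down = unname(qd$qvalues), q_up = unname(qu$qvalues),
                    stringsAsFactors = FALSE)
  out$ranks_down <- unname(pooled_down$ranks)
  out$ranks_up <- unname(pooled_up$ranks)
  attr(out, "N") <- pooled_down$N
  attr(out, "m") <- pooled_down$m
  attr(out, "pi0_down") <- qd$pi0
  attr(out, "pi0_up") <- qu$pi0
  out
}

#' Genes significant at a q-value cutoff
#'
#' @param records Output of [rsa_rank()].
#' @param q_cutoff q-value threshold (the headline analyses use `0.01`).
#' @param direction `"down"` (reduced expression after knockdown) or
#'   `"up"`.
#' @return Character vector of gene ids with `q <= q_cutoff` in the
#'   requested direction.
#' @export
significant_genes <- function(records, q_cutoff = 0.01,
                              direction = c("down", "up")) {
  direction <- match.arg(direction)
  q <- if (direction == "down") records$q_down else records$q_up
  records$gene_id[q <= q_cutoff]
}

#' Write RSA records as TSV
#'
#' Rank lists are serialised comma-separated.
#'
#' @param records Output of [rsa_rank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rsa_records <- function(records, path) {
  flat <- records[, c("gene_id", "p_down", "p_up", "q_down", "q_up")]
  flat$ranks_down <- vapply(records$ranks_down, paste, "", collapse = ",")
  flat$ranks_up <- vapply(records$ranks_up, paste, "", collapse = ",")
  data.table::fwrite(flat, path, sep = "\t", quote = FALSE)
  invisible(path)
}
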