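#' Fraction of one peak set overlapping another
#'
#' An interval of A counts once if it shares at least `min_overlap_bp`
#' with any interval of B; the fraction is over all of A. This is the
#' statistic behind cross-factor binding-site comparisons (e.g. the
#' fraction of each ENCODE factor's sites overlapping a reference
#' factor's sites).
#'
#' @param a,b Interval frames; `a` must be non-empty.
#' @param min_overlap_bp Minimum shared bases to count an overlap.
#' @return List: `n_a`, `n_b`, `n_a_overlapping`, `fraction`.
#' @export
overlap_fraction <- function(a, b, min_overlap_bp = 1) {
  if (nrow(a) == 0) stop("overlap fraction undefined for an empty A set")
  hit <- logical(nrow(a))
  for (chrom in unique(a$chrom)) {
    ai <- which(a$chrom == chrom)
    bi <- which(b$chrom == chrom)
    if (length(bi) == 0) next
    hit[ai] <- IRanges::countOverlaps(as_iranges(a[ai, , drop = FALSE]),
                                      as_iranges(b[bi, , drop = FALSE]),
                                      minoverlap = min_overlap_bp) > 0
  }
  list(n_a = nrow(a), n_b = nrow(b), n_a_overlapping = sum(hit),
       fraction = sum(hit) / nrow(a), overlapping = hit)
}

#' Cell-line-specific sites
#'
#' Retains the target sites whose summit lies more than `distance` bp
#' from every other-set summit on the same chromosome. "Within
#' `distance`" is boundary-inclusive: a summit exactly `distance` bp
#' from another-set summit is removed. The summit is the annotated
#' `summit` column when present, the interval midpoint otherwise.
#'
#' @param target_set Interval frame of candidate sites.
#' @param other_sets Interval frame, or list of frames, of sites from the
#'   other conditions/cell lines.
#' @param distance Exclusion radius in bp (default 5000, the 5-kb rule).
#' @return Subset of `target_set` (rows preserved in order).
#' @export
specific_sites <- function(target_set, other_sets, distance = 5000) {
  stopifnot(distance >= 0)
  if (is.data.frame(other_sets)) other_sets <- list(other_sets)
  other <- do.call(rbind, lapply(other_sets, function(s) {
    data.frame(chrom = s$chrom, summit = get_summits(s))
  }))
  if (is.null(other) || nrow(other) == 0) return(target_set)
  tsum <- get_summits(target_set)
  keep <- vapply(seq_len(nrow(target_set)), function(i) {
    os <- other$summit[other$chrom == target_set$chrom[i]]
    length(os) == 0 || min(abs(os - tsum[i])) > distance
  }, TRUE)
  target_set[keep, , drop = FALSE]
}

get_summits <- function(x) {
  if ("summit" %in% names(x) && !all(is.na(x$summit))) {
    ifelse(is.na(x$summit), interval_summits(x), x$summit)
  } else {
    interval_summits(x)
  }
}

#' Nearest peak to a gene's TSS
#'
#' Minimises |summit - TSS| over all peaks on the gene's chromosome and
#' reports the signed distance in gene orientation: positive downstream
#' of the TSS, negative upstream (the sign flips on `-`-strand genes).
#' Ties break toward the smaller absolute summit coordinate.
#'
#' @param peaks Non-empty interval frame (a `summit` column is used when
#'   present).
#' @param gene One row of a [gene_models()] frame.
#' @return List: `peak` (the winning row), `signed_distance`.
#' @export
nearest_peak_to_tss <- function(peaks, gene) {
  stopifnot(nrow(peaks) > 0)
  on_chrom <- peaks[peaks$chrom == gene$chrom, , drop = FALSE]
  if (nrow(on_chrom) == 0) stop("no peaks on chromosome ", gene$chrom)
  summits <- get_summits(on_chrom)
  dist <- abs(summits - gene$tss)
  best <- which(dist == min(dist))
  if (length(best) > 1) best <- best[which.min(summits[best])]
  signed <- (summits[best] - gene$tss) * if (gene$strand == "-") -1 else 1
  list(peak = on_chrom[best, , drop = FALSE], signed_distance = unname(signed))
}

#' Assign peaks to genes by the TSS-window / intron rule
#'
#' A peak is assigned to a gene when its summit lies within `tss_window`
#' bp of the TSS (boundary inclusive; relation `tss_window`), or inside
#' the gene according to the body rule: `mode = "intron"` accepts only
#' intronic summits (relation `intron`), `mode = "gene_body"` accepts any
#' summit in the gene span (relation `exon` or `intron`). A peak may be
#' assigned to several genes; all qualifying assignments are emitted.
#' The gene-body mode is always a superset of the intron mode on the
#' same inputs.
#'
#' @param peaks Interval frame (a `summit` column is used when present).
#' @param genes A [gene_models()] frame.
#' @param tss_window Window around the TSS in bp (default 5000).
#' @param mode `"intron"` (default) or `"gene_body"`.
#' @return `data.frame` with `peak_name`, `gene_id`, `relation`,
#'   `signed_distance_to_tss`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, tss_window = 5000,
                                  mode = c("intron", "gene_body")) {
  mode <- match.arg(mode)
  if (nrow(peaks) == 0) {
    return(data.frame(peak_name = character(0), gene_id = character(0),
                      relation = character(0),
                      signed_distance_to_tss = numeric(0)))
  }
  summits <- get_summits(peaks)
  pname <- if ("name" %in% names(peaks) && !all(is.na(peaks$name))) {
    peaks$name
  } else sprintf("peak_%d", seq_len(nrow(peaks)))
  rows <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, , drop = FALSE]
    on_chrom <- which(peaks$chrom == g$chrom)
    if (length(on_chrom) == 0) next
    s <- summits[on_chrom]
    signed <- (s - g$tss) * if (g$strand == "-") -1 else 1
    in_tss <- abs(s - g$tss) <= tss_window
    in_span <- s >= g$gene_start & s < g$gene_end
    ex <- g$exons[[1]]
    in_exon <- vapply(s, function(p) any(ex[, 1] <= p & p < ex[, 2]), TRUE)
    in_intron <- in_span & !in_exon
    relation <- rep(NA_character_, length(s))
    relation[in_intron] <- "intron"
    relation[in_exon] <- "exon"
    relation[in_tss] <- "tss_window"
    qualifies <- in_tss | (mode == "intron" & in_intron) |
      (mode == "gene_body" & in_span)
    if (!any(qualifies)) next
    rows[[length(rows) + 1]] <- data.frame(
      peak_name = pname[on_chrom][qualifies],
      gene_id = g$gene_id,
      relation = relation[qualifies],
      signed_distance_to_tss = signed[qualifies],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(peak_name = character(0), gene_id = character(0),
               relation = character(0), signed_distance_to_tss = numeric(0))
  }
  rownames(out) <- NULL
  out
}
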