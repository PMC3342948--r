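#' Construct gene models
#'
#' A gene model carries what the TSS-window / intron assignment rules need:
#' the gene span, strand, derived TSS, and an ordered set of exons. Introns
#' are always derived as the gaps between consecutive exons, never read
#' from a file.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param chrom Chromosome per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param gene_start,gene_end Gene span (0-based half-open).
#' @param exons List (one element per gene) of two-column matrices /
#'   data.frames with exon `start`, `end`, sorted, non-overlapping, inside
#'   the span. Defaults to single-exon genes spanning the whole gene.
#' @return A `data.frame` with one row per gene: `gene_id`, `chrom`,
#'   `strand`, `gene_start`, `gene_end`, `tss`, and a list-column `exons`.
#'   `tss` is `gene_start` on `+` genes and `gene_end - 1` on `-` genes.
#' @export
gene_models <- function(gene_id, chrom, strand, gene_start, gene_end,
                        exons = NULL) {
  n <- length(gene_id)
  stopifnot(!anyDuplicated(gene_id), all(strand %in% c("+", "-")),
            all(gene_start >= 0), all(gene_start < gene_end))
  if (is.null(exons)) {
    exons <- Map(function(s, e) cbind(start = s, end = e), gene_start, gene_end)
  }
  stopifnot(length(exons) == n)
  for (i in seq_len(n)) {
    ex <- as.matrix(as.data.frame(exons[[i]]))
    if (nrow(ex) == 0) stop("gene ", gene_id[i], ": no exons")
    if (is.unsorted(ex[, 1])) stop("gene ", gene_id[i], ": exons not sorted")
    if (any(ex[, 1] >= ex[, 2])) stop("gene ", gene_id[i], ": empty exon")
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
      stop("gene ", gene_id[i], ": overlapping exons")
    }
    if (ex[1, 1] < gene_start[i] || ex[nrow(ex), 2] > gene_end[i]) {
      stop("gene ", gene_id[i], ": exons outside gene span")
    }
    exons[[i]] <- ex
  }
  tss <- ifelse(strand == "+", gene_start, gene_end - 1)
  out <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                    strand = as.character(strand),
                    gene_start = as.numeric(gene_start),
                    gene_end = as.numeric(gene_end), tss = as.numeric(tss),
                    stringsAsFactors = FALSE)
  out$exons <- exons
  out
}

#' Introns of one gene model row
#'
#' @param gene One row of a [gene_models()] frame.
#' @return Matrix of intron `start`, `end` (0-based half-open); zero rows
#'   for single-exon genes.
#' @export
gene_introns <- function(gene) {
  ex <- gene$exons[[1]]
  if (nrow(ex) < 2) {
    return(cbind(start = numeric(0), end = numeric(0)))
  }
  out <- cbind(start = unname(ex[-nrow(ex), 2]), end = unname(ex[-1, 1]))
  rownames(out) <- NULL
  out
}

#' Read gene models from BED12
#'
#' Only the fields the assignment rules use are interpreted: chrom, span,
#' name, strand, and the block structure (exons). `thickStart`/`thickEnd`
#' and colors are ignored.
#'
#' @param path Path to a 12-column BED file.
#' @return A [gene_models()] frame.
#' @export
read_bed12_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(dt) < 12) stop("BED12 requires 12 columns, got ", ncol(dt))
  parse_csv_ints <- function(s) as.numeric(strsplit(sub(",$", "", s), ",")[[1]])
  exons <- lapply(seq_len(nrow(dt)), function(i) {
    sizes <- parse_csv_ints(dt[i, 11])
    offs <- parse_csv_ints(dt[i, 12])
    if (length(sizes) != dt[i, 10] || length(offs) != dt[i, 10]) {
      stop("BED12 line ", i, ": blockCount disagrees with block lists")
    }
    cbind(start = dt[i, 2] + offs, end = dt[i, 2] + offs + sizes)
  })
  gene_models(gene_id = dt[[4]], chrom = dt[[1]], strand = dt[[6]],
              gene_start = dt[[2]], gene_end = dt[[3]], exons = exons)
}

#' Write gene models as BED12
#'
#' @param genes A [gene_models()] frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12_genes <- function(genes, path) {
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    paste(genes$chrom[i], format_coord(genes$gene_start[i]),
          format_coord(genes$gene_end[i]), genes$gene_id[i], 0, genes$strand[i],
          format_coord(genes$gene_start[i]), format_coord(genes$gene_start[i]),
          "0", nrow(ex),
          paste0(paste(format_coord(ex[, 2] - ex[, 1]), collapse = ","), ","),
          paste0(paste(format_coord(ex[, 1] - genes$gene_start[i]), collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}
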