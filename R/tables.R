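#' Read a fold-change table
#'
#' A fold-change table is a genes x experiments matrix of log fold-changes
#' relative to matched controls (e.g. columns `M1,M2,U1,U2,G1,G2` for two
#' replicate knockdown experiments in each of three expression datasets).
#' On disk it is a TSV with a header row of experiment ids and the gene id
#' in the first column.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, `rownames` = gene ids, `colnames` = experiment
#'   ids in file order. No missing values.
#' @export
read_foldchange_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 2) stop("fold-change table needs a gene column plus >= 1 experiment")
  genes <- dt[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    stop("duplicate gene id(s): ", paste(unique(dup)[seq_len(min(5, length(unique(dup))))],
                                         collapse = ", "))
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    # locate the first offending cell for the error message
    for (j in seq_len(ncol(dt) - 1)) {
      v <- suppressWarnings(as.numeric(dt[[j + 1]]))
      bad <- which(is.na(v) & !is.na(dt[[j + 1]]))
      if (length(bad) > 0) {
        stop("non-numeric cell at gene '", genes[bad[1]], "', experiment '",
             colnames(dt)[j + 1], "': '", dt[[j + 1]][bad[1]], "'")
      }
    }
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("missing/non-finite value at gene '", genes[idx[1]], "', experiment '",
         colnames(m)[idx[2]], "'")
  }
  rownames(m) <- genes
  m
}

#' Write a fold-change table
#'
#' @param x Numeric matrix with gene-id rownames and experiment-id colnames.
#' @param path Output TSV path.
#' @param gene_col Header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_foldchange_table <- function(x, path, gene_col = "gene_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_col
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
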