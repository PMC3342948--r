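#' Construct a set of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Human-readable reports are the only place
#' 1-based coordinates appear (see [to_onebased()]).
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start,end Integer-valued vectors; `0 <= start < end`.
#' @param name Optional labels (`NA` when absent).
#' @param score Optional numeric scores (`NA` when absent).
#' @param strand Strand per interval, one of `"+"`, `"-"`, `"."`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, one row per interval, input order preserved.
#' @examples
#' genomic_intervals("chr1", 0, 100, name = "pk", score = 5, strand = "+")
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = ".") {
  n <- length(start)
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate interval invariants
#'
#' Checks `0 <= start < end`, non-empty chromosome names, and allowed
#' strand values. Returns the input invisibly; stops with a message
#' naming the first offending row otherwise.
#'
#' @param x Interval `data.frame` as built by [genomic_intervals()].
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    stop("interval frame lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(!nzchar(x$chrom) | is.na(x$chrom))) {
    stop("empty chromosome name at row ", which(!nzchar(x$chrom) | is.na(x$chrom))[1])
  }
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    stop("invalid interval at row ", bad[1], ": start=", x$start[bad[1]],
         " end=", x$end[bad[1]], " (need 0 <= start < end)")
  }
  if ("strand" %in% names(x)) {
    bad_strand <- which(!x$strand %in% c("+", "-", "."))
    if (length(bad_strand) > 0) {
      stop("invalid strand at row ", bad_strand[1], ": '", x$strand[bad_strand[1]], "'")
    }
  }
  invisible(x)
}

#' Convert between 0-based half-open and 1-based closed coordinates
#'
#' All internal coordinates are 0-based half-open; these two helpers are
#' the single place the package converts to and from the 1-based closed
#' convention used in human-readable reports. They are mutual inverses.
#'
#' @param x Interval frame.
#' @return Interval frame with shifted coordinates.
#' @export
to_onebased <- function(x) {
  x$start <- x$start + 1
  x
}

#' @rdname to_onebased
#' @export
from_onebased <- function(x) {
  x$start <- x$start - 1
  x
}

#' Read a BED file (3-6 columns)
#'
#' @param path Path to a tab-separated BED3/BED6 file without header.
#' @return Interval frame (see [genomic_intervals()]); `name`/`score`/
#'   `strand` are `NA`/`"."` when the file has fewer than 6 columns.
#'   Input order is preserved.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  badnum <- which(is.na(start) | is.na(end))
  if (length(badnum) > 0) {
    stop("malformed BED line ", badnum[1], ": non-numeric start/end")
  }
  name <- get(4)
  score <- suppressWarnings(as.numeric(get(5)))
  strand <- get(6)
  strand[is.na(strand)] <- "."
  df <- data.frame(chrom = get(1), start = start, end = end, name = name,
                   score = score, strand = strand, stringsAsFactors = FALSE)
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad) > 0) {
    stop("invalid interval at BED line ", bad[1], ": [", df$start[bad[1]],
         ", ", df$end[bad[1]], ")")
  }
  validate_intervals(df)
  df
}

#' Write intervals as BED
#'
#' Writes BED3 when no name/score/strand is populated anywhere, BED6
#' otherwise (missing names become `"."`, missing scores `0`). Round-trips
#' through [read_bed()] losslessly on the populated fields.
#'
#' @param x Interval frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  has_extra <- nrow(x) > 0 &&
    (any(!is.na(x$name)) || any(!is.na(x$score)) || any(x$strand != "."))
  if (has_extra) {
    out <- data.frame(
      chrom = x$chrom,
      start = format_coord(x$start),
      end = format_coord(x$end),
      name = ifelse(is.na(x$name), ".", x$name),
      score = ifelse(is.na(x$score), "0", format(x$score, trim = TRUE, scientific = FALSE, digits = 10)),
      strand = x$strand,
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(chrom = x$chrom, start = format_coord(x$start),
                      end = format_coord(x$end), stringsAsFactors = FALSE)
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

format_coord <- function(x) {
  format(x, trim = TRUE, scientific = FALSE)
}

#' Midpoint summit of intervals
#'
#' The summit of an interval without an explicit summit annotation is its
#' midpoint, `floor((start + end) / 2)`.
#'
#' @param x Interval frame.
#' @return Numeric vector of summit positions.
#' @export
interval_summits <- function(x) {
  floor((x$start + x$end) / 2)
}

# IRanges view of an interval frame (1-based closed internally to IRanges).
as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1, end = x$end)
}
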