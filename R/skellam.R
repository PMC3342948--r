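#' Skellam probability mass function
#'
#' Null distribution of the difference `D = X1 - X2` of two independent
#' Poisson counts, `X1 ~ Poisson(mu1)` (ChIP window count) and
#' `X2 ~ Poisson(mu2)` (control window count). Computed through the
#' modified-Bessel-function form
#' `P(D = k) = exp(-(mu1+mu2)) (mu1/mu2)^(k/2) I_|k|(2 sqrt(mu1 mu2))`,
#' evaluated in log space with the exponentially scaled Bessel function;
#' when the scaled Bessel underflows (far tails) the term is recovered by
#' a log-space Poisson convolution. `mu2 = 0` (or `mu1 = 0`) degenerates
#' to a pure (negated) Poisson.
#'
#' @param k Integer vector of differences.
#' @param mu1,mu2 Non-negative Poisson means (scalars).
#' @param log If `TRUE`, return log probabilities.
#' @return Vector of probabilities `P(D = k)`.
#' @export
dskellam <- function(k, mu1, mu2, log = FALSE) {
  if (!is.finite(mu1) || !is.finite(mu2) || mu1 < 0 || mu2 < 0) {
    stop("mu1 and mu2 must be finite and non-negative")
  }
  if (any(k != round(k))) stop("k must be integer-valued")
  if (mu2 == 0 && mu1 == 0) {
    lp <- ifelse(k == 0, 0, -Inf)
    return(if (log) lp else exp(lp))
  }
  if (mu2 == 0) {
    lp <- ifelse(k >= 0, stats::dpois(pmax(k, 0), mu1, log = TRUE), -Inf)
    return(if (log) lp else exp(lp))
  }
  if (mu1 == 0) {
    lp <- ifelse(k <= 0, stats::dpois(pmax(-k, 0), mu2, log = TRUE), -Inf)
    return(if (log) lp else exp(lp))
  }
  x <- 2 * sqrt(mu1 * mu2)
  lp <- vapply(k, function(ki) {
    -(mu1 + mu2) + (ki / 2) * (base::log(mu1) - base::log(mu2)) +
      log_besselI(x, abs(ki))
  }, 0)
  if (log) lp else exp(lp)
}

# log I_nu(x) for integer nu >= 0. base::besselI where it is reliable;
# in the deep tail (large order), where the scaled Bessel function
# underflows and loses precision, the ascending power series
# I_nu(x) = sum_m (x/2)^(2m+nu) / (m! (m+nu)!) is summed in log space.
log_besselI <- function(x, nu) {
  if (nu <= x + 20) {
    bi <- suppressWarnings(besselI(x, nu, expon.scaled = TRUE))
    if (is.finite(bi) && bi > 0) return(base::log(bi) + x)
  }
  m <- 0:ceiling(x + 60)
  logsumexp((2 * m + nu) * base::log(x / 2) - lgamma(m + 1) - lgamma(m + nu + 1))
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + base::log(sum(exp(lx - m)))
}

#' Skellam upper-tail probability (peak-calling p-value)
#'
#' `P(D >= d)` for the Skellam null, accumulated in log space so the far
#' tail stays accurate; never returns exact 0 (floored at the smallest
#' positive double).
#'
#' @param d Integer difference (vectorised).
#' @param mu1,mu2 Poisson means as in [dskellam()]; recycled against `d`.
#' @param log.p If `TRUE`, return log of the upper-tail probability.
#' @return Vector of upper-tail probabilities in `(0, 1]`.
#' @export
skellam_sf <- function(d, mu1, mu2, log.p = FALSE) {
  n <- max(length(d), length(mu1), length(mu2))
  d <- rep_len(d, n); mu1 <- rep_len(mu1, n); mu2 <- rep_len(mu2, n)
  lp <- vapply(seq_len(n), function(i) skellam_sf_one(d[i], mu1[i], mu2[i]), 0)
  if (log.p) lp else pmax(exp(lp), .Machine$double.xmin)
}

skellam_sf_one <- function(d, mu1, mu2) {
  if (!is.finite(mu1) || !is.finite(mu2) || mu1 < 0 || mu2 < 0) {
    stop("mu1 and mu2 must be finite and non-negative")
  }
  if (mu1 == 0 && mu2 == 0) return(if (d <= 0) 0 else -Inf)
  if (mu2 == 0) return(stats::ppois(ceiling(d) - 1, mu1, lower.tail = FALSE, log.p = TRUE))
  # d below the entire (numerically relevant) support: p = 1
  if (d <= (mu1 - mu2) - (12 * sqrt(mu1 + mu2) + 60) - 1) return(0)
  kmax <- ceiling(max(d, mu1 - mu2) + 12 * sqrt(mu1 + mu2) + 60)
  ks <- seq.int(from = ceiling(d), to = kmax)
  lo <- logsumexp(dskellam(ks, mu1, mu2, log = TRUE))
  min(lo, 0)
}

#' Skellam lower-tail probability
#'
#' `P(D <= q)`. Implemented through the exact sign-flip identity
#' `P(D <= q | mu1, mu2) = P(-D >= -q) = sf(-q | mu2, mu1)`, which keeps
#' both tails accurate without catastrophic cancellation.
#'
#' @inheritParams skellam_sf
#' @param q Integer quantile (vectorised).
#' @return Vector of lower-tail probabilities.
#' @export
skellam_cdf <- function(q, mu1, mu2, log.p = FALSE) {
  skellam_sf(-q, mu2, mu1, log.p = log.p)
}

#' Build a read-start track
#'
#' A track is the minimal ChIP-seq representation the caller needs:
#' per-chromosome sorted read 5'-start positions plus the genome the
#' reads live on.
#'
#' @param positions Named list (by chromosome) of integer-valued read
#'   start positions (0-based).
#' @param genome Named numeric vector of chromosome lengths in bp.
#' @return A `read_track` object: list with `positions` (sorted),
#'   `genome`, `total_depth`.
#' @export
read_track <- function(positions, genome) {
  stopifnot(!is.null(names(genome)), all(genome > 0))
  positions <- positions[intersect(names(positions), names(genome))]
  for (chrom in names(positions)) {
    p <- sort(as.numeric(positions[[chrom]]))
    if (length(p) > 0 && (p[1] < 0 || p[length(p)] >= genome[[chrom]])) {
      stop("read position outside ", chrom, " bounds")
    }
    positions[[chrom]] <- p
  }
  structure(list(positions = positions, genome = genome,
                 total_depth = sum(lengths(positions))),
            class = "read_track")
}

#' Read a track from a BED file of read starts
#'
#' Each BED record contributes its `start` as one read 5'-start.
#'
#' @param path BED path.
#' @param genome Named chromosome lengths.
#' @return A [read_track()].
#' @export
read_track_from_bed <- function(path, genome) {
  bed <- read_bed(path)
  read_track(split(bed$start, bed$chrom), genome)
}

#' Write a track as a BED file of 1-bp read-start intervals
#'
#' @param track A [read_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  chrom <- rep(names(track$positions), lengths(track$positions))
  start <- unlist(track$positions, use.names = FALSE)
  if (length(start) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  write_bed(genomic_intervals(chrom, start, start + 1), path)
}

# Tiling window starts/ends for one chromosome.
tile_windows <- function(len, window_size, step) {
  starts <- seq.int(0L, max(0, len - 1), by = step)
  data.frame(start = starts, end = pmin(starts + window_size, len))
}

# Number of sorted positions in [a, b) for each (a, b) pair.
count_in <- function(sorted_pos, a, b) {
  findInterval(b - 0.5, sorted_pos) - findInterval(a - 0.5, sorted_pos)
}

#' Count read starts in tiling windows
#'
#' Windows of `window_size` bp are placed every `step` bp along each
#' chromosome (the final windows are clipped at the chromosome end). A
#' read with start position `p` is counted in window `[a, b)` iff
#' `a <= p < b`.
#'
#' @param track A [read_track()].
#' @param window_size Window width, bp.
#' @param step Window spacing, bp; `1 <= step <= window_size`.
#' @return `data.frame` with `chrom`, `start`, `end`, `count`.
#' @export
count_windows <- function(track, window_size, step = window_size) {
  stopifnot(window_size >= step, step >= 1)
  out <- lapply(names(track$genome), function(chrom) {
    w <- tile_windows(track$genome[[chrom]], window_size, step)
    pos <- track$positions[[chrom]]
    if (is.null(pos)) pos <- numeric(0)
    w$count <- count_in(pos, w$start, w$end)
    w$chrom <- chrom
    w[, c("chrom", "start", "end", "count")]
  })
  do.call(rbind, out)
}

#' Estimate the per-window Skellam null
#'
#' The control-derived local background rate is
#' `lambda = max(local means, lambda_bg)`, the maximum of the control
#' count averaged over nested spans around the window (the window itself,
#' then wider surroundings, all rescaled to window units) and a
#' genome-wide floor. The null for the ChIP-minus-control difference is
#' then `mu1 = r * lambda`, `mu2 = lambda`, where `r` is the
#' ChIP-to-control sequencing depth ratio: the expected ChIP count in a
#' background window is the control rate scaled up by the depth ratio.
#'
#' @param local_means Numeric matrix, windows x spans: control count per
#'   window-equivalent for each local span (e.g. 1x, 5x, 25x windows).
#' @param r Depth ratio `chip_depth / ctrl_depth`; must be positive.
#' @param lambda_bg Genome-wide expected control count per window.
#' @return List with vectors `mu1`, `mu2`.
#' @export
estimate_null <- function(local_means, r, lambda_bg) {
  stopifnot(r > 0, lambda_bg >= 0)
  local_means <- as.matrix(local_means)
  lambda <- pmax(apply(local_means, 1, max), lambda_bg)
  list(mu1 = r * lambda, mu2 = lambda)
}

#' Call peaks with a Skellam null
#'
#' Slides `window_size`-bp windows every `step` bp, computes the
#' ChIP-minus-control count difference per window, scores it against the
#' Skellam null from [estimate_null()] (one-sided, enrichment only),
#' keeps windows with `p <= p_cutoff`, merges kept windows within
#' `merge_gap` bp of each other into peaks, and drops peaks intersecting
#' any excluded interval. Deterministic.
#'
#' @param chip,ctrl ChIP and control [read_track()]s on the same genome.
#' @param window_size,step Window geometry in bp (defaults 200/50).
#' @param p_cutoff Per-window p-value cutoff (default `1e-6`).
#' @param merge_gap Maximum gap between significant windows merged into
#'   one peak; defaults to `window_size`.
#' @param excluded Optional interval frame of regions whose peaks are
#'   discarded (blacklist: satellites, rRNA, ...).
#' @param local_spans Multipliers of `window_size` over which the local
#'   control background is averaged (max rule).
#' @return `data.frame` of peaks sorted by position: `chrom`, `start`,
#'   `end`, `name`, `score` (`-log10 p`, capped at 500), `strand`,
#'   `summit` (midpoint of the most significant window), `best_pvalue`,
#'   `n_windows`.
#' @export
call_peaks <- function(chip, ctrl, window_size = 200, step = 50,
                       p_cutoff = 1e-6, merge_gap = window_size,
                       excluded = NULL, local_spans = c(1, 5, 25)) {
  stopifnot(identical(names(chip$genome), names(ctrl$genome)))
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      name = character(0), score = numeric(0), strand = character(0),
                      summit = numeric(0), best_pvalue = numeric(0),
                      n_windows = integer(0), stringsAsFactors = FALSE)
  if (chip$total_depth == 0 || ctrl$total_depth == 0) {
    warning("empty track(s): no peaks called")
    return(empty)
  }
  r <- chip$total_depth / ctrl$total_depth
  genome_total <- sum(chip$genome)
  lambda_bg <- ctrl$total_depth * window_size / genome_total

  peak_list <- lapply(names(chip$genome), function(chrom) {
    len <- chip$genome[[chrom]]
    w <- tile_windows(len, window_size, step)
    cpos <- chip$positions[[chrom]]; if (is.null(cpos)) cpos <- numeric(0)
    kpos <- ctrl$positions[[chrom]]; if (is.null(kpos)) kpos <- numeric(0)
    c_chip <- count_in(cpos, w$start, w$end)
    c_ctrl <- count_in(kpos, w$start, w$end)
    centers <- (w$start + w$end) / 2
    local_means <- vapply(local_spans, function(mult) {
      half <- mult * window_size / 2
      a <- pmax(centers - half, 0)
      b <- pmin(centers + half, len)
      count_in(kpos, a, b) * window_size / (b - a)
    }, numeric(nrow(w)))
    null <- estimate_null(local_means, r, lambda_bg)
    d <- c_chip - c_ctrl

    # cheap lower bounds on the p-value rule out most windows before the
    # exact tail sum: sf(d) >= P(X1 >= d + k0) P(X2 <= k0) for any k0 >= 0
    k0 <- ceiling(null$mu2)
    lb <- pmax(
      stats::ppois(d - 1, null$mu1, lower.tail = FALSE) * exp(-null$mu2),
      stats::ppois(d + k0 - 1, null$mu1, lower.tail = FALSE) *
        stats::ppois(k0, null$mu2)
    )
    cand <- which(lb <= p_cutoff)
    if (length(cand) == 0) return(NULL)
    pv <- skellam_sf(d[cand], null$mu1[cand], null$mu2[cand])
    sig <- cand[pv <= p_cutoff]
    if (length(sig) == 0) return(NULL)
    pv <- pv[pv <= p_cutoff]

    ord <- order(w$start[sig])
    sig <- sig[ord]; pv <- pv[ord]
    gap_break <- c(FALSE, w$start[sig][-1] - w$end[sig][-length(sig)] > merge_gap)
    grp <- cumsum(gap_break)
    do.call(rbind, lapply(split(seq_along(sig), grp), function(ii) {
      win_i <- sig[ii]
      best <- ii[which.min(pv[ii])]
      data.frame(chrom = chrom,
                 start = min(w$start[win_i]), end = max(w$end[win_i]),
                 name = NA_character_,
                 score = min(500, -log10(pv[best])),
                 strand = ".",
                 summit = floor((w$start[sig[best]] + w$end[sig[best]]) / 2),
                 best_pvalue = pv[best], n_windows = length(ii),
                 stringsAsFactors = FALSE)
    }))
  })
  peaks <- do.call(rbind, peak_list)
  if (is.null(peaks) || nrow(peaks) == 0) return(empty)
  rownames(peaks) <- NULL
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  if (!is.null(excluded) && nrow(excluded) > 0) {
    keep <- !intervals_overlap_any(peaks, excluded)
    peaks <- peaks[keep, , drop = FALSE]
  }
  rownames(peaks) <- NULL
  peaks
}

# TRUE per row of a whenever it shares >= 1 bp with some interval of b.
intervals_overlap_any <- function(a, b) {
  out <- logical(nrow(a))
  for (chrom in unique(a$chrom)) {
    ai <- which(a$chrom == chrom)
    bi <- which(b$chrom == chrom)
    if (length(bi) == 0) next
    hits <- IRanges::countOverlaps(as_iranges(a[ai, , drop = FALSE]),
                                   as_iranges(b[bi, , drop = FALSE]),
                                   minoverlap = 1)
    out[ai] <- hits > 0
  }
  out
}
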