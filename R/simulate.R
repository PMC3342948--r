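#' Evaluate an expression with a temporarily seeded RNG
#'
#' All generators in the package are pure functions of (spec, seed): the
#' global RNG state is saved, the seed applied, and the state restored
#' afterwards, so simulation calls do not perturb user code.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Place n non-overlapping width-bp intervals uniformly on a genome,
# avoiding `avoid` (interval frame) and keeping >= gap bp between placed
# intervals. Errors when the genome cannot host them.
place_disjoint <- function(n, genome, width, avoid = NULL, gap = 0,
                           max_tries = 1000) {
  if (n == 0) return(genomic_intervals(character(0), numeric(0), numeric(0)))
  if (n * (width + gap) > sum(genome)) {
    stop("genome too small to place ", n, " disjoint ", width, "-bp intervals")
  }
  chroms <- names(genome)
  placed <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  tries <- 0
  while (nrow(placed) < n) {
    tries <- tries + 1
    if (tries > max_tries * n) {
      stop("could not place ", n, " disjoint ", width,
           "-bp intervals (genome too crowded)")
    }
    chrom <- sample(chroms, 1, prob = pmax(genome - width, 0))
    if (genome[[chrom]] < width) next
    s <- floor(stats::runif(1, 0, genome[[chrom]] - width + 1))
    cand <- data.frame(chrom = chrom, start = max(0, s - gap),
                       end = s + width + gap)
    clash <- any(intervals_overlap_any(cand, placed)) ||
      (!is.null(avoid) && nrow(avoid) > 0 && any(intervals_overlap_any(cand, avoid)))
    if (!clash) {
      placed <- rbind(placed, data.frame(chrom = chrom, start = s, end = s + width))
    }
  }
  genomic_intervals(placed$chrom, placed$start, placed$end)
}

#' Simulation spec for a ChIP-seq experiment
#'
#' @param genome Named chromosome lengths (bp).
#' @param n_peaks Number of planted binding sites.
#' @param peak_width Width of each planted site, bp.
#' @param enrichment ChIP read-rate multiplier inside planted sites
#'   (> 1).
#' @param chip_depth,ctrl_depth Total read counts. The study-scale ratio
#'   is ~15M ChIP vs ~9M control reads; the desk-scale default keeps a
#'   similar ratio at 400k/250k.
#' @param seed RNG seed.
#' @param excluded Optional interval frame the planted sites must avoid.
#' @return A `chip_sim_spec` list.
#' @export
chip_sim_spec <- function(genome = c(chr1 = 1e6, chr2 = 1e6), n_peaks = 50,
                          peak_width = 300, enrichment = 8,
                          chip_depth = 4e5, ctrl_depth = 2.5e5,
                          seed = 1, excluded = NULL) {
  stopifnot(enrichment > 1, chip_depth > 0, ctrl_depth > 0,
            peak_width >= 1, n_peaks >= 0, all(genome > 0),
            !is.null(names(genome)))
  structure(list(genome = genome, n_peaks = n_peaks, peak_width = peak_width,
                 enrichment = enrichment, chip_depth = chip_depth,
                 ctrl_depth = ctrl_depth, seed = seed, excluded = excluded),
            class = "chip_sim_spec")
}

#' Simulate ChIP and control read-start tracks with planted peaks
#'
#' Control read starts are uniform over the genome. ChIP read starts are
#' drawn from a piecewise-constant rate: background everywhere and
#' `background * enrichment` inside the planted peaks, normalised so that
#' exactly `chip_depth` reads are drawn. The same seed reproduces the
#' same tracks bit for bit.
#'
#' @param spec A [chip_sim_spec()].
#' @return List with `chip` and `ctrl` [read_track()]s and `truth_peaks`
#'   (interval frame of the planted sites, named `truth_1..n`).
#' @export
simulate_chipseq <- function(spec) {
  stopifnot(inherits(spec, "chip_sim_spec"))
  with_seed(spec$seed, {
    peaks <- place_disjoint(spec$n_peaks, spec$genome, spec$peak_width,
                            avoid = spec$excluded, gap = spec$peak_width)
    if (nrow(peaks) > 0) peaks$name <- sprintf("truth_%d", seq_len(nrow(peaks)))
    ctrl_pos <- sample_uniform_reads(spec$ctrl_depth, spec$genome)
    chip_pos <- sample_enriched_reads(spec$chip_depth, spec$genome, peaks,
                                      spec$enrichment)
    list(chip = read_track(chip_pos, spec$genome),
         ctrl = read_track(ctrl_pos, spec$genome),
         truth_peaks = peaks)
  })
}

sample_uniform_reads <- function(depth, genome) {
  n_per <- stats::rmultinom(1, depth, prob = genome)[, 1]
  pos <- lapply(seq_along(genome), function(i) {
    floor(stats::runif(n_per[i], 0, genome[[i]]))
  })
  names(pos) <- names(genome)
  pos
}

# Draw reads from rate 1 outside peaks / `enrichment` inside, via the
# exact piecewise-constant segment decomposition of each chromosome.
sample_enriched_reads <- function(depth, genome, peaks, enrichment) {
  segs <- do.call(rbind, lapply(names(genome), function(chrom) {
    len <- genome[[chrom]]
    pk <- peaks[peaks$chrom == chrom, , drop = FALSE]
    pk <- pk[order(pk$start), , drop = FALSE]
    bounds <- sort(unique(c(0, len, pk$start, pk$end)))
    s <- bounds[-length(bounds)]
    e <- bounds[-1]
    inpk <- vapply(s, function(x) any(pk$start <= x & x < pk$end), TRUE)
    data.frame(chrom = chrom, start = s, end = e,
               rate = ifelse(inpk, enrichment, 1), stringsAsFactors = FALSE)
  }))
  w <- (segs$end - segs$start) * segs$rate
  n_per <- stats::rmultinom(1, depth, prob = w)[, 1]
  pos_all <- floor(stats::runif(depth,
                                rep(segs$start, n_per),
                                rep(segs$end, n_per)))
  chrom_all <- rep(segs$chrom, n_per)
  split(pos_all, factor(chrom_all, levels = names(genome)))
}

#' Simulation spec for paired knockdown fold-change tables
#'
#' Gene classes mirror the structure expected of two cooperating
#' transcription factors: genes down in both knockdowns (co-activated
#' targets), up in both (co-repressed), responsive to a single factor,
#' antagonistic (opposite signs), and null.
#'
#' @param n_genes Total genes.
#' @param class_sizes Named counts over `co_activated`, `co_repressed`,
#'   `mitf_only`, `yy1_only`, `antagonistic`; the remainder is null.
#' @param effect Mean |log fold-change| of affected classes.
#' @param noise_sd Replicate noise sd on the log scale.
#' @param layout_a Experiment ids of the first (MITF-side) table; the
#'   default mirrors two MALME-3M, two UACC62 and two external replicate
#'   experiments.
#' @param layout_b Experiment ids of the second (YY1-side) table.
#' @param seed RNG seed.
#' @return An `expr_sim_spec` list.
#' @export
expr_sim_spec <- function(n_genes = 2000,
                          class_sizes = c(co_activated = 150, co_repressed = 150,
                                          mitf_only = 100, yy1_only = 100),
                          effect = 1.5, noise_sd = 0.3,
                          layout_a = c("M1", "M2", "U1", "U2", "G1", "G2"),
                          layout_b = c("M1", "M2", "U1", "U2"),
                          seed = 1) {
  known <- c("co_activated", "co_repressed", "mitf_only", "yy1_only", "antagonistic")
  stopifnot(all(names(class_sizes) %in% known), sum(class_sizes) <= n_genes,
            noise_sd > 0, effect >= 0)
  full <- stats::setNames(rep(0, length(known)), known)
  full[names(class_sizes)] <- class_sizes
  structure(list(n_genes = n_genes, class_sizes = full, effect = effect,
                 noise_sd = noise_sd, layout_a = layout_a, layout_b = layout_b,
                 seed = seed),
            class = "expr_sim_spec")
}

#' Simulate paired knockdown fold-change tables with planted gene classes
#'
#' Class means (first table, second table): co-activated `(-e, -e)`,
#' co-repressed `(+e, +e)`, antagonistic `(-e, +e)`, single-factor
#' classes `(-e, 0)` / `(0, -e)`, null `(0, 0)`. Each replicate value is
#' the class mean plus Normal(0, `noise_sd`) noise.
#'
#' @param spec An [expr_sim_spec()].
#' @return List with `mitf` and `yy1` fold-change matrices and `truth`
#'   (`data.frame` of `gene_id`, `class`).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expr_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    cs <- spec$class_sizes
    cls <- c(rep(names(cs), cs), rep("null", n - sum(cs)))
    gene_ids <- sprintf("g%05d", seq_len(n))
    e <- spec$effect
    mean_a <- c(co_activated = -e, co_repressed = e, mitf_only = -e,
                yy1_only = 0, antagonistic = -e, null = 0)[cls]
    mean_b <- c(co_activated = -e, co_repressed = e, mitf_only = 0,
                yy1_only = -e, antagonistic = e, null = 0)[cls]
    ma <- length(spec$layout_a); mb <- length(spec$layout_b)
    tab_a <- matrix(stats::rnorm(n * ma, mean = rep(mean_a, ma), sd = spec$noise_sd),
                    nrow = n, dimnames = list(gene_ids, spec$layout_a))
    tab_b <- matrix(stats::rnorm(n * mb, mean = rep(mean_b, mb), sd = spec$noise_sd),
                    nrow = n, dimnames = list(gene_ids, spec$layout_b))
    list(mitf = tab_a, yy1 = tab_b,
         truth = data.frame(gene_id = gene_ids, class = unname(cls),
                            stringsAsFactors = FALSE))
  })
}

#' Simulation spec for motif-planted sequence sets
#'
#' @param n_fg,n_bg Numbers of foreground / background regions. The
#'   study-scale analysis used 814 open-chromatin regions against 814
#'   matched random regions; the desk-scale default is 300 + 300.
#' @param region_length Region length, bp.
#' @param gc Background GC fraction.
#' @param pwm A [pwm()] motif.
#' @param plant_rate_fg,plant_rate_bg Fraction of regions receiving one
#'   planted motif instance.
#' @param seed RNG seed.
#' @return A `motif_sim_spec` list.
#' @export
motif_sim_spec <- function(n_fg = 300, n_bg = 300, region_length = 300,
                           gc = 0.41, pwm = ebox_pwm(),
                           plant_rate_fg = 0.4, plant_rate_bg = 0.05,
                           seed = 1) {
  stopifnot(plant_rate_fg >= 0, plant_rate_fg <= 1,
            plant_rate_bg >= 0, plant_rate_bg <= 1,
            gc > 0, gc < 1, region_length >= ncol(pwm$counts))
  structure(list(n_fg = n_fg, n_bg = n_bg, region_length = region_length,
                 gc = gc, pwm = pwm, plant_rate_fg = plant_rate_fg,
                 plant_rate_bg = plant_rate_bg, seed = seed),
            class = "motif_sim_spec")
}

#' Simulate foreground/background sequence sets with planted motifs
#'
#' Backgrounds are i.i.d. with base probabilities
#' `(A,C,G,T) = ((1-gc)/2, gc/2, gc/2, (1-gc)/2)`. A planted instance is
#' drawn column-wise from the motif's probability matrix, a strand is
#' chosen uniformly (reverse-complemented when `-`), and the instance
#' overwrites the region at a uniform offset.
#'
#' @param spec A [motif_sim_spec()].
#' @return List with `fg`, `bg` (named character vectors of sequences)
#'   and `truth` (`data.frame` of `set`, `region`, `offset`, `strand` for
#'   every planted instance).
#' @export
simulate_sequences <- function(spec) {
  stopifnot(inherits(spec, "motif_sim_spec"))
  with_seed(spec$seed, {
    probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
               G = spec$gc / 2, T = (1 - spec$gc) / 2)
    pmat <- pwm_probs(spec$pwm)
    L <- ncol(pmat)
    gen_set <- function(n, rate, set_name) {
      seqs <- character(n)
      truth <- list()
      for (i in seq_len(n)) {
        s <- sample(names(probs), spec$region_length, replace = TRUE, prob = probs)
        if (stats::runif(1) < rate) {
          inst <- vapply(seq_len(L), function(j) {
            sample(rownames(pmat), 1, prob = pmat[, j])
          }, "")
          strand <- sample(c("+", "-"), 1)
          if (strand == "-") inst <- rev(chartr_vec(inst))
          off <- sample.int(spec$region_length - L + 1, 1) - 1
          s[(off + 1):(off + L)] <- inst
          truth[[length(truth) + 1]] <- data.frame(
            set = set_name, region = sprintf("%s_%d", set_name, i),
            offset = off, strand = strand, stringsAsFactors = FALSE)
        }
        seqs[i] <- paste(s, collapse = "")
      }
      names(seqs) <- sprintf("%s_%d", set_name, seq_len(n))
      list(seqs = seqs, truth = truth)
    }
    fg <- gen_set(spec$n_fg, spec$plant_rate_fg, "fg")
    bg <- gen_set(spec$n_bg, spec$plant_rate_bg, "bg")
    truth <- do.call(rbind, c(fg$truth, bg$truth))
    if (is.null(truth)) {
      truth <- data.frame(set = character(0), region = character(0),
                          offset = numeric(0), strand = character(0))
    }
    list(fg = fg$seqs, bg = bg$seqs, truth = truth)
  })
}

# base-wise complement of a character vector of single bases
chartr_vec <- function(bases) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[bases]
}

#' Simulate two peak sets with a controlled overlap fraction
#'
#' Set B is placed first (disjoint intervals); then
#' `round(overlap_target * n_a)` intervals of A are placed to intersect a
#' distinct B interval by at least 1 bp, and the remaining A intervals
#' are placed disjoint from B, so the realised overlap fraction of A in B
#' equals the target exactly (up to rounding of the count).
#'
#' @param n_a,n_b Interval counts.
#' @param overlap_target Fraction of A intervals overlapping B, in
#'   `[0, 1]`.
#' @param genome Named chromosome lengths.
#' @param width Interval width, bp.
#' @param seed RNG seed.
#' @return List with interval frames `a` and `b`.
#' @export
simulate_peak_sets <- function(n_a, n_b, overlap_target,
                               genome = c(chr1 = 1e6), width = 200, seed = 1) {
  stopifnot(overlap_target >= 0, overlap_target <= 1)
  n_hit <- round(overlap_target * n_a)
  stopifnot(n_hit <= n_b)
  with_seed(seed, {
    b <- place_disjoint(n_b, genome, width, gap = 2 * width)
    hit_idx <- sample.int(n_b, n_hit)
    a_hit <- if (n_hit > 0) {
      shift <- sample.int(2 * width - 1, n_hit, replace = TRUE) - width
      starts <- pmax(b$start[hit_idx] + shift, 0)
      genomic_intervals(b$chrom[hit_idx], starts, starts + width)
    } else genomic_intervals(character(0), numeric(0), numeric(0))
    a_miss <- place_disjoint(n_a - n_hit, genome, width,
                             avoid = rbind(b[, c("chrom", "start", "end")],
                                           a_hit[, c("chrom", "start", "end")]))
    a <- rbind(a_hit, a_miss)
    a$name <- sprintf("a_%d", seq_len(nrow(a)))
    b$name <- sprintf("b_%d", seq_len(nrow(b)))
    list(a = a, b = b)
  })
}

#' Simulate gene models
#'
#' Places non-overlapping multi-exon genes with random strands; exon and
#' intron sizes are drawn uniformly from the supplied ranges. Used to
#' exercise TSS-window and intron assignment logic against known
#' structures.
#'
#' @param n_genes Number of genes.
#' @param genome Named chromosome lengths.
#' @param n_exons Range (min, max) of exons per gene.
#' @param exon_len,intron_len Ranges (min, max) of exon / intron lengths.
#' @param seed RNG seed.
#' @return A [gene_models()] frame.
#' @export
simulate_gene_models <- function(n_genes = 20, genome = c(chr1 = 1e6),
                                 n_exons = c(1, 5), exon_len = c(100, 400),
                                 intron_len = c(200, 2000), seed = 1) {
  with_seed(seed, {
    ex_counts <- sample(seq(n_exons[1], n_exons[2]), n_genes, replace = TRUE)
    spans <- vapply(ex_counts, function(k) {
      sum(sample(seq(exon_len[1], exon_len[2]), k, replace = TRUE)) +
        if (k > 1) sum(sample(seq(intron_len[1], intron_len[2]), k - 1, replace = TRUE)) else 0
    }, 0)
    max_span <- max(spans) * 2
    slots <- place_disjoint(n_genes, genome, max_span, gap = 1000)
    exons <- vector("list", n_genes)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_start <- numeric(n_genes); gene_end <- numeric(n_genes)
    for (i in seq_len(n_genes)) {
      k <- ex_counts[i]
      el <- sample(seq(exon_len[1], exon_len[2]), k, replace = TRUE)
      il <- if (k > 1) sample(seq(intron_len[1], intron_len[2]), k - 1, replace = TRUE) else numeric(0)
      starts <- slots$start[i] + cumsum(c(0, el[-k] + il))
      exons[[i]] <- cbind(start = starts, end = starts + el)
      gene_start[i] <- starts[1]
      gene_end[i] <- starts[k] + el[k]
    }
    gene_models(gene_id = sprintf("gene_%02d", seq_len(n_genes)),
                chrom = slots$chrom, strand = strand,
                gene_start = gene_start, gene_end = gene_end, exons = exons)
  })
}
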