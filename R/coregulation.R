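lowess_on_grid <- function(x, y, grid, span, iter = 2) {
  fit <- stats::lowess(x, y, f = span, iter = iter)
  stats::approx(fit$x, fit$y, xout = grid, rule = 2, ties = mean)$y
}

coreg_grid <- function(x, grid_size) {
  qs <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  if (qs[1] >= qs[2]) stop("degenerate x: no spread between the 1% and 99% quantiles")
  seq(qs[1], qs[2], length.out = grid_size)
}

#' Bagged lowess curve
#'
#' The reported trend between the two knockdowns' fold-changes is the
#' pointwise mean of `n_boot` lowess fits, each to a bootstrap resample
#' (with replacement, same n) of the (x, y) pairs, evaluated on a fixed
#' grid spanning the central 98% of x. Bagging stabilises the raw lowess
#' fit against resampling noise.
#'
#' @param x,y Paired observations (e.g. mean log fold-change after each
#'   knockdown); length >= 10.
#' @param n_boot Number of bootstrap fits (default 100).
#' @param span Lowess span (fraction of points per local fit).
#' @param grid_size Number of grid points.
#' @param seed RNG seed.
#' @param iter Robustifying iterations of the lowess fit.
#' @return List with `grid`, `bagged` (pointwise mean fit), `n_boot`,
#'   `span`, `seed`.
#' @export
bagged_lowess <- function(x, y, n_boot = 100, span = 0.3, grid_size = 100,
                          seed = NULL, iter = 2) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  grid <- coreg_grid(x, grid_size)
  n <- length(x)
  with_seed(seed, {
    acc <- numeric(length(grid))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      acc <- acc + lowess_on_grid(x[idx], y[idx], grid, span, iter)
    }
    list(grid = grid, bagged = acc / n_boot, n_boot = n_boot, span = span,
         seed = seed)
  })
}

#' Randomized-x null envelope for the lowess curve
#'
#' Each permutation shuffles the x-coordinates (over the whole data, or
#' over a masked subset, leaving the rest in place), fits a single
#' lowess, and evaluates it on the grid; the envelope is the pointwise
#' minimum and maximum over all `n_perm` fits. A trend that exits the
#' envelope is stronger than anything x-randomisation produces.
#'
#' @inheritParams bagged_lowess
#' @param n_perm Number of x permutations (default 1000).
#' @param grid Evaluation grid; defaults to the central-98% grid of x.
#' @param subset_mask Optional logical vector: permute x only within the
#'   masked positions.
#' @return List with `grid`, `env_lo`, `env_hi`, `n_perm`, `span`,
#'   `seed`.
#' @export
randomization_envelope <- function(x, y, n_perm = 1000, span = 0.3,
                                   grid = NULL, grid_size = 100, seed = NULL,
                                   subset_mask = NULL, iter = 2) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  if (is.null(grid)) grid <- coreg_grid(x, grid_size)
  if (!is.null(subset_mask)) stopifnot(length(subset_mask) == length(x))
  with_seed(seed, {
    lo <- rep(Inf, length(grid)); hi <- rep(-Inf, length(grid))
    for (p in seq_len(n_perm)) {
      xp <- x
      if (is.null(subset_mask)) {
        xp <- sample(x)
      } else {
        xp[subset_mask] <- sample(x[subset_mask])
      }
      fit <- lowess_on_grid(xp, y, grid, span, iter)
      lo <- pmin(lo, fit); hi <- pmax(hi, fit)
    }
    list(grid = grid, env_lo = lo, env_hi = hi, n_perm = n_perm, span = span,
         seed = seed)
  })
}

#' Bagged curve plus null envelope in one object
#'
#' Convenience wrapper running [bagged_lowess()] and
#' [randomization_envelope()] on a shared grid and flagging, per grid
#' point, whether the bagged curve exits the envelope (no multiplicity
#' correction; descriptive, as the curve is drawn).
#'
#' @inheritParams randomization_envelope
#' @param n_boot,n_perm Bootstrap / permutation counts.
#' @return `data.frame` with `grid`, `bagged`, `env_lo`, `env_hi`,
#'   `outside` (logical); parameters as attributes.
#' @export
coreg_curve <- function(x, y, n_boot = 100, n_perm = 1000, span = 0.3,
                        grid_size = 100, seed = NULL, subset_mask = NULL) {
  grid <- coreg_grid(x, grid_size)
  bag <- bagged_lowess(x, y, n_boot = n_boot, span = span,
                       grid_size = grid_size, seed = seed)
  env <- randomization_envelope(x, y, n_perm = n_perm, span = span,
                                grid = grid, seed = if (is.null(seed)) NULL else seed + 1,
                                subset_mask = subset_mask)
  out <- data.frame(grid = grid, bagged = bag$bagged, env_lo = env$env_lo,
                    env_hi = env$env_hi)
  out$outside <- out$bagged < out$env_lo | out$bagged > out$env_hi
  attr(out, "n_boot") <- n_boot
  attr(out, "n_perm") <- n_perm
  attr(out, "span") <- span
  attr(out, "seed") <- seed
  out
}

top_k_genes <- function(records, k, direction) {
  p <- if (direction == "down") records$p_down else records$p_up
  ord <- order(p, records$gene_id)
  records$gene_id[ord[seq_len(k)]]
}

overlap_mode_directions <- function(mode) {
  switch(mode,
         co_activated = c("down", "down"),
         co_repressed = c("up", "up"),
         antagonistic_1 = c("down", "up"),
         antagonistic_2 = c("up", "down"),
         stop("unknown mode: ", mode))
}

#' Fisher overlap of two top-k gene lists
#'
#' Takes the top-k genes of each knockdown in the directions the mode
#' dictates (co_activated: down/down, co_repressed: up/up,
#' antagonistic_1: down/up, antagonistic_2: up/down), counts the
#' intersection, and scores it with the upper-tail hypergeometric
#' probability of an overlap at least this large between two random
#' k-subsets of the universe (one-sided Fisher's exact test on the 2x2
#' table).
#'
#' @param records_mitf,records_yy1 [rsa_rank()] frames over the same gene
#'   universe.
#' @param k Top-list size, `<=` universe.
#' @param mode One of `"co_activated"`, `"co_repressed"`,
#'   `"antagonistic_1"`, `"antagonistic_2"`.
#' @return List with `k`, `mode`, `overlap`, `fisher_p`.
#' @export
quadrant_overlap_test <- function(records_mitf, records_yy1, k, mode) {
  if (!identical(sort(records_mitf$gene_id), sort(records_yy1$gene_id))) {
    stop("records do not share the gene universe")
  }
  universe <- nrow(records_mitf)
  if (k > universe) stop("k = ", k, " exceeds the universe (", universe, ")")
  dirs <- overlap_mode_directions(mode)
  top_a <- top_k_genes(records_mitf, k, dirs[1])
  top_b <- top_k_genes(records_yy1, k, dirs[2])
  ov <- length(intersect(top_a, top_b))
  p <- stats::phyper(ov - 1, k, universe - k, k, lower.tail = FALSE)
  list(k = k, mode = mode, overlap = ov, fisher_p = p)
}

#' Overlap significance across a grid of top-list sizes
#'
#' Runs [quadrant_overlap_test()] for every k in the grid and all four
#' modes, producing the curve that shows whether co-regulation
#' significance is robust to the choice of top-list size.
#'
#' @inheritParams quadrant_overlap_test
#' @param k_grid Increasing vector of top-list sizes.
#' @param modes Modes to evaluate (default all four).
#' @return `data.frame` with `k`, `mode`, `overlap`, `fisher_p`.
#' @export
overlap_significance_curve <- function(records_mitf, records_yy1,
                                       k_grid = c(100, 200, 300, 400, 500),
                                       modes = c("co_activated", "co_repressed",
                                                 "antagonistic_1", "antagonistic_2")) {
  stopifnot(!is.unsorted(k_grid))
  rows <- lapply(modes, function(mode) {
    do.call(rbind, lapply(k_grid, function(k) {
      as.data.frame(quadrant_overlap_test(records_mitf, records_yy1, k, mode),
                    stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
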