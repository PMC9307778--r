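# Replicate-free CRISPRi screen analysis.
#
# One well per targeted super-enhancer plus negative-control wells, no
# replicates: differential expression is the change between a gene's
# within-well expression rank and its global rank (the CMAP-style statistic),
# thresholded by an empirical FDR against the negative-control wells.
# Normalisation is median-of-ratios size factors followed by log2(x + 1) as
# the variance-stabilisation step, with optional removal of leading singular
# components in place of a surrogate-variable fit.

#' Normalise screen counts
#'
#' (1) Drops genes with zero counts in every well; (2) computes per-well
#' size factors as the median, over genes with all-positive counts, of
#' count / geometric-mean-across-wells (DESeq median-of-ratios); (3) returns
#' `log2(count / size_factor + 1)`; (4) optionally removes the
#' `n_surrogates` leading singular components of the gene-centred matrix,
#' standing in for a surrogate-variable batch correction.
#'
#' @param counts genes x wells nonnegative integer matrix.
#' @param n_surrogates number of leading components to remove (default 0).
#' @return Normalised genes x wells matrix (log2 scale); size factors in
#'   attribute `size_factors`.
#' @export
preprocess_counts <- function(counts, n_surrogates = 0) {
  if (any(counts < 0)) stop("negative counts")
  keep <- rowSums(counts) > 0
  log_filter("preprocess_counts: all-zero genes", nrow(counts), sum(keep))
  counts <- counts[keep, , drop = FALSE]
  allpos <- rowSums(counts == 0) == 0
  if (!any(allpos)) {
    stop("no gene has all-positive counts; size factors undefined ",
         "(consider a pseudo-reference fallback)")
  }
  ref <- exp(rowMeans(log(counts[allpos, , drop = FALSE])))
  sf <- apply(counts[allpos, , drop = FALSE] / ref, 2, stats::median)
  norm <- log2(sweep(counts, 2, sf, "/") + 1)
  if (n_surrogates > 0) {
    mu <- rowMeans(norm)
    cen <- norm - mu
    sv <- svd(cen, nu = n_surrogates, nv = n_surrogates)
    k <- seq_len(n_surrogates)
    norm <- cen - sv$u[, k, drop = FALSE] %*%
      (sv$d[k] * t(sv$v[, k, drop = FALSE])) + mu
  }
  attr(norm, "size_factors") <- sf
  norm
}

#' Rank-change table
#'
#' Within every well, genes are ranked in order of expression (rank 1 =
#' highest, n = lowest, ties averaged). The global rank is the same ranking
#' applied to the per-gene aggregate (median by default) across all wells.
#' The rank change is `RC = within-well rank - global rank`: positive RC
#' means the gene is downranked (lower relative expression) in that well.
#'
#' @param norm normalised genes x wells matrix.
#' @param aggregate `"median"` (default) or `"mean"` per-gene aggregation
#'   for the global rank.
#' @return A list with `rc` (genes x wells rank changes), `within` (the
#'   within-well ranks) and `global_rank`.
#' @export
rank_table <- function(norm, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (ncol(norm) < 2) stop("need at least 2 wells")
  within <- apply(norm, 2, function(v) rank(-v, ties.method = "average"))
  agg <- if (aggregate == "median") apply(norm, 1, stats::median) else
    rowMeans(norm)
  global_rank <- rank(-agg, ties.method = "average")
  rc <- within - global_rank
  dimnames(rc) <- dimnames(norm)
  list(rc = rc, within = within, global_rank = global_rank)
}

#' Empirical FDR at a rank-change threshold
#'
#' Counts genes beyond the threshold in the tested well (RC >= threshold for
#' direction `"down"`, RC <= -threshold for `"up"`), takes the median of the
#' same count across negative-control wells, and returns
#' `median control count / well count` (1 when the well count is 0; capped
#' at 1). A median of 4 control genes against 40 well genes gives 0.10.
#'
#' @param rc rank-change list from [rank_table()] (or the `rc` matrix).
#' @param well tested well id.
#' @param controls negative-control well ids.
#' @param threshold positive rank-change threshold.
#' @param direction `"down"` or `"up"`.
#' @return A list with `efdr`, `gene_count` (well exceedances) and
#'   `control_counts`.
#' @export
efdr_at_threshold <- function(rc, well, controls, threshold,
                              direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (is.list(rc)) rc <- rc$rc
  stopifnot(length(controls) >= 1, threshold > 0)
  exceed <- function(w) {
    v <- rc[, w]
    if (direction == "down") sum(v >= threshold) else sum(v <= -threshold)
  }
  gene_count <- exceed(well)
  control_counts <- vapply(controls, exceed, 0)
  med <- stats::median(control_counts)
  efdr <- if (gene_count == 0) 1 else min(med / gene_count, 1)
  list(efdr = efdr, gene_count = gene_count, control_counts = control_counts)
}

#' Select target genes per super-enhancer well
#'
#' Iterates over an ascending grid of rank-change thresholds and, per SE
#' well and direction, picks the smallest threshold whose empirical FDR
#' against the negative-control wells is at most `target_efdr`; the target
#' genes are those beyond that threshold. When no threshold qualifies the
#' call set is empty. The default grid is integer multiples of 1% of the
#' gene count, from 1% to 30%.
#'
#' @param rc rank-change list from [rank_table()].
#' @param wells well metadata (`well`, `role`, `se_id`; see [read_wells()]).
#' @param threshold_grid ascending numeric thresholds (default 1%..30% of
#'   gene count).
#' @param target_efdr empirical FDR target (default 0.1).
#' @return A `data.frame` with one row per (SE well, direction): `well`,
#'   `se_id`, `direction`, `threshold`, `efdr`, `n_genes`; called gene ids
#'   in list-column `genes`.
#' @export
select_targets <- function(rc, wells, threshold_grid = NULL,
                           target_efdr = 0.1) {
  rcm <- if (is.list(rc)) rc$rc else rc
  n_genes <- nrow(rcm)
  if (is.null(threshold_grid)) {
    threshold_grid <- round(n_genes * seq(0.01, 0.30, by = 0.01))
    threshold_grid <- unique(threshold_grid[threshold_grid >= 1])
  }
  if (!length(threshold_grid)) stop("empty threshold grid")
  if (is.unsorted(threshold_grid)) stop("threshold grid must be ascending")
  controls <- wells$well[wells$role == "neg_control"]
  if (length(controls) < 1) stop("no negative-control wells")
  se_wells <- wells[wells$role == "se", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(se_wells))) {
    w <- se_wells$well[i]
    for (dir in c("down", "up")) {
      chosen <- NA_real_; efdr <- NA_real_; genes <- character(0)
      for (th in threshold_grid) {
        e <- efdr_at_threshold(rcm, w, controls, th, direction = dir)
        if (e$gene_count > 0 && e$efdr <= target_efdr) {
          chosen <- th; efdr <- e$efdr
          v <- rcm[, w]
          genes <- rownames(rcm)[if (dir == "down") v >= th else v <= -th]
          break
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        well = w, se_id = se_wells$se_id[i], direction = dir,
        threshold = chosen, efdr = efdr, n_genes = length(genes),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$genes <- list(genes)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Control-relative log2 fold change
#'
#' Per-gene difference between a well's normalised value and the median of
#' the negative-control wells (normalised values are already on the log2
#' scale, so the difference is a log2 fold change).
#'
#' @param norm normalised genes x wells matrix.
#' @param well tested well id.
#' @param controls negative-control well ids.
#' @return Named numeric vector of per-gene LFCs.
#' @export
control_lfc <- function(norm, well, controls) {
  stopifnot(length(controls) >= 1)
  ctrl_med <- apply(norm[, controls, drop = FALSE], 1, stats::median)
  norm[, well] - ctrl_med
}

#' Rank-change vs fold-change correlation across super-enhancers
#'
#' Over the pooled set of genes called significant in any SE well, computes
#' the Pearson correlation between the (negated) rank change in well i and
#' the control-relative LFC in well j, for every well pair. RC is negated so
#' that downranked genes (positive RC) align with negative LFC and a well's
#' agreement with itself is a positive correlation.
#'
#' @param rc rank-change list or matrix.
#' @param lfc genes x SE-wells matrix of control-relative LFCs.
#' @param significant_genes pooled significant gene ids (>= 3).
#' @return SE x SE correlation matrix (rows: RC well, columns: LFC well).
#'   Pairs with a zero-variance vector are `NA`.
#' @export
rc_lfc_correlation <- function(rc, lfc, significant_genes) {
  rcm <- if (is.list(rc)) rc$rc else rc
  genes <- intersect(significant_genes, rownames(rcm))
  if (length(genes) < 3) stop("pooled significant set has fewer than 3 genes")
  wells <- colnames(lfc)
  R <- -rcm[genes, wells, drop = FALSE]
  L <- lfc[genes, wells, drop = FALSE]
  suppressWarnings(stats::cor(R, L))
}

#' Cluster summary of the significant rank-change profiles
#'
#' K-means clustering of the significant genes' RC profiles across SE wells
#' for each k in `k_range` (10 restarts, fixed seed), reporting the
#' within-cluster sum of squares per k for an elbow table; the gene clusters
#' at `chosen_k` (default 3); and an average-linkage hierarchical clustering
#' of the SE wells on Euclidean distance of their RC profiles.
#'
#' @param rc rank-change list or matrix.
#' @param significant_genes gene ids to cluster (>= max(k_range)).
#' @param k_range candidate cluster counts (default 1:6).
#' @param chosen_k cluster count used for the reported assignment
#'   (default 3).
#' @param se_wells well ids to use as dimensions (default: all columns).
#' @param seed integer seed for the k-means restarts.
#' @return A list with `elbow` (data.frame k, wss), `clusters` (named
#'   integer vector at `chosen_k`), and `se_hclust` (an `hclust` object).
#' @export
cluster_summary <- function(rc, significant_genes, k_range = 1:6,
                            chosen_k = 3, se_wells = NULL, seed = 1) {
  rcm <- if (is.list(rc)) rc$rc else rc
  if (is.null(se_wells)) se_wells <- colnames(rcm)
  genes <- intersect(significant_genes, rownames(rcm))
  if (length(genes) < max(k_range)) {
    stop("fewer significant genes than the largest k")
  }
  X <- rcm[genes, se_wells, drop = FALSE]
  if (all(apply(X, 2, stats::var) == 0)) stop("degenerate (constant) profiles")
  fits <- withr::with_seed(seed, {
    lapply(k_range, function(k) stats::kmeans(X, centers = k, nstart = 10,
                                              iter.max = 50))
  })
  elbow <- data.frame(k = k_range,
                      wss = vapply(fits, function(f) f$tot.withinss, 0))
  clusters <- fits[[match(chosen_k, k_range)]]$cluster
  names(clusters) <- genes
  se_hclust <- stats::hclust(stats::dist(t(X)), method = "average")
  list(elbow = elbow, clusters = clusters, se_hclust = se_hclust)
}
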