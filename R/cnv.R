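# Copy-number windowing and the super-enhancer amplification tests.
#
# The genome grid comes from tile_genome(); per-patient seg-mean values are
# assigned to windows by overlap-length-weighted mean; amplification of the
# SE-overlapping windows is assessed against 10,000 random draws of
# equally-sized window sets (Welch one-sided t + one-sided Mann-Whitney U)
# and by one direct comparison against all windows.

#' Assign per-patient copy number to windows
#'
#' A window receives signal from a patient whenever a segment overlaps it by
#' at least one base pair. When several segments overlap one window, the
#' window value is the overlap-length-weighted mean of the segment values
#' (mass-conserving); windows with no overlapping segment are missing (`NA`).
#'
#' @param grid window interval set from [tile_genome()].
#' @param segments a segment table (see [read_segments()]).
#' @return A windows x patients numeric matrix with `NA` for no coverage.
#' @export
assign_copy_number <- function(grid, segments) {
  validate_segments(segments)
  patients <- sort(unique(segments$patient))
  g <- .as_granges(grid)
  s <- GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start + 1, end = segments$end))
  hits <- GenomicRanges::findOverlaps(g, s, minoverlap = 1L)
  q <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  ow <- IRanges::width(IRanges::pintersect(IRanges::ranges(g)[q],
                                           IRanges::ranges(s)[j]))
  wf <- factor(q, levels = seq_len(nrow(grid)))
  pf <- factor(segments$patient[j], levels = patients)
  num <- tapply(ow * segments$value[j], list(wf, pf), sum)
  den <- tapply(ow, list(wf, pf), sum)
  cn <- unclass(num / den)
  dimnames(cn) <- list(grid$id, patients)
  cn
}

#' Windows overlapping super-enhancers
#'
#' Ids of grid windows with >= 1 bp intersection with any super-enhancer
#' (the bedtools-intersect step), deduplicated.
#'
#' @param grid window interval set.
#' @param ses interval set of super-enhancers.
#' @return Character vector of window ids.
#' @export
se_window_overlap <- function(grid, ses) {
  ids <- grid$id[.overlapping_idx(grid, ses)]
  sereg_log("se_window_overlap: ", length(ids), " of ", nrow(grid),
            " windows overlap ", nrow(ses), " SEs")
  ids
}

# Welch one-sided t-test (alternative: group 1 greater), vectorised over
# parallel summary statistics. Welch-Satterthwaite degrees of freedom.
.welch_p_greater <- function(m1, v1, n1, m2, v2, n2) {
  a <- v1 / n1; b <- v2 / n2
  degenerate <- (v1 + v2) == 0
  se2 <- a + b
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  p <- stats::pt(t, df, lower.tail = FALSE)
  p[degenerate] <- 1
  list(p = p, t = t, df = df, degenerate = degenerate)
}

# One-sided Mann-Whitney U (alternative: x stochastically greater than y),
# normal approximation with tie correction, no continuity correction.
# Matches wilcox.test(x, y, alternative = "greater", exact = FALSE,
# correct = FALSE).
.mwu_p_greater <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sigma2 == 0) return(1)
  stats::pnorm((U - n1 * n2 / 2) / sqrt(sigma2), lower.tail = FALSE)
}

# Per-window summary across patients: mean with missing excluded (default),
# or the raw pooled patient x window values.
.window_values <- function(cn, ids, pooled = FALSE) {
  sub <- cn[ids, , drop = FALSE]
  if (pooled) as.vector(sub[!is.na(sub)]) else rowMeans(sub, na.rm = TRUE)
}

#' Random-draw amplification test
#'
#' Compares the copy-number distribution of the SE-overlapping windows
#' against `n_iter` random draws of equally many windows from the whole-grid
#' background (inclusive of the SE windows), once per iteration, with a
#' Welch one-sided t-test (alternative: SE mean greater) and a one-sided
#' Mann-Whitney U (normal approximation with tie correction). Windows are
#' summarised per window as the mean copy number across patients with
#' missing values excluded (set `pooled = TRUE` to compare raw
#' patient-by-window values instead).
#'
#' @param cn windows x patients copy-number matrix.
#' @param se_windows character vector of SE-overlapping window ids (>= 2).
#' @param n_iter number of random draws (default 10000).
#' @param seed integer seed.
#' @param pooled compare pooled patient x window values instead of
#'   per-window means.
#' @return A list with `welch_p` and `mwu_p` (length `n_iter`), `n_iter`,
#'   `degenerate` flags, and a `summary` (median Welch p, fraction of
#'   iterations with Welch p < 0.05).
#' @export
random_draw_test <- function(cn, se_windows, n_iter = 10000, seed = 1,
                             pooled = FALSE) {
  stopifnot(length(se_windows) >= 2, all(se_windows %in% rownames(cn)))
  se_vals <- .window_values(cn, se_windows, pooled = pooled)
  all_ids <- rownames(cn)
  n_draw <- length(se_windows)
  m1 <- mean(se_vals); v1 <- stats::var(se_vals); n1 <- length(se_vals)
  withr::with_seed(seed, {
    draws <- vapply(seq_len(n_iter),
                    function(i) sample.int(length(all_ids), n_draw),
                    integer(n_draw))
  })
  if (pooled) {
    res <- vapply(seq_len(n_iter), function(i) {
      bg <- .window_values(cn, all_ids[draws[, i]], pooled = TRUE)
      w <- .welch_p_greater(m1, v1, n1, mean(bg), stats::var(bg), length(bg))
      c(w$p, .mwu_p_greater(se_vals, bg), as.numeric(w$degenerate))
    }, numeric(3))
    welch_p <- res[1, ]; mwu_p <- res[2, ]; degenerate <- res[3, ] > 0
  } else {
    means <- rowMeans(cn, na.rm = TRUE)
    V <- matrix(means[draws], nrow = n_draw)
    m2 <- colMeans(V)
    v2 <- (colSums(V^2) - n_draw * m2^2) / (n_draw - 1)
    w <- .welch_p_greater(m1, v1, n1, m2, v2, n_draw)
    welch_p <- w$p; degenerate <- w$degenerate
    mwu_p <- vapply(seq_len(n_iter),
                    function(i) .mwu_p_greater(se_vals, V[, i]), 0)
    mwu_p[degenerate] <- 1
  }
  list(welch_p = welch_p, mwu_p = mwu_p, n_iter = n_iter,
       degenerate = degenerate,
       summary = list(median_welch_p = stats::median(welch_p),
                      frac_welch_sig = mean(welch_p < 0.05),
                      median_mwu_p = stats::median(mwu_p),
                      frac_mwu_sig = mean(mwu_p < 0.05)))
}

#' Direct SE-vs-genome amplification comparison
#'
#' One Welch one-sided t-test and one one-sided Mann-Whitney U of the
#' SE-overlapping window values against the values of all grid windows.
#' p-values below 2.2e-16 are reported at that floor.
#'
#' @inheritParams random_draw_test
#' @return A list with `welch_p`, `mwu_p` and a `degenerate` flag.
#' @export
direct_comparison <- function(cn, se_windows, pooled = FALSE) {
  stopifnot(length(se_windows) >= 2, all(se_windows %in% rownames(cn)))
  se_vals <- .window_values(cn, se_windows, pooled = pooled)
  all_vals <- .window_values(cn, rownames(cn), pooled = pooled)
  w <- .welch_p_greater(mean(se_vals), stats::var(se_vals), length(se_vals),
                        mean(all_vals), stats::var(all_vals), length(all_vals))
  mwu <- if (w$degenerate) 1 else .mwu_p_greater(se_vals, all_vals)
  list(welch_p = max(w$p, 2.2e-16), mwu_p = max(mwu, 2.2e-16),
       degenerate = w$degenerate)
}
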