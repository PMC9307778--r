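# Hi-C contact normalisation and super-enhancer target classification.
#
# A per-chromosome symmetric count matrix is balanced with the Knight-Ruiz
# algorithm (all unmasked row sums driven to 1), contacts are expressed as
# observed over the distance-stratum expectation, SE-gene pairs are compared
# against 100 permutations of distance-matched control genes, and pairs
# above the 75th percentile of the control distribution are direct targets.
# A modified Activity-by-Contact score multiplies standardised
# log2-transformed enhancer activity and 50-kb contact.

#' Construct a per-chromosome contact matrix
#'
#' @param chrom chromosome name.
#' @param binsize bin width in bp.
#' @param counts symmetric nonnegative square count matrix.
#' @param bins optional bin table (`chrom`, `start`, `end`, `bin`); default
#'   bins tile from 0 at `binsize`.
#' @return An object of class `contact_matrix`: list with `chrom`,
#'   `binsize`, `counts`, `bins`, `masked` (all-zero bins), `balanced`,
#'   `balancing`, `balanced_counts`.
#' @export
contact_matrix <- function(chrom, binsize, counts, bins = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) stop("count matrix must be square")
  if (any(counts < 0)) stop("negative contact counts")
  if (!isTRUE(all.equal(counts, t(counts)))) stop("count matrix not symmetric")
  counts <- (counts + t(counts)) / 2  # enforce exact symmetry
  if (is.null(bins)) {
    bins <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * binsize,
                       end = seq_len(n) * binsize,
                       bin = paste0(chrom, "_b", seq_len(n)),
                       stringsAsFactors = FALSE)
  }
  if (nrow(bins) != n) stop("bin table does not match matrix dimension")
  structure(list(chrom = chrom, binsize = binsize, counts = counts,
                 bins = bins, masked = rowSums(counts) == 0,
                 balanced = FALSE, balancing = NULL, balanced_counts = NULL),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "-", nrow(x$counts), "bins @", x$binsize,
      "bp;", sum(x$masked), "masked;",
      if (x$balanced) "KR-balanced" else "raw", "\n")
  invisible(x)
}

# Knight-Ruiz balancing of a symmetric nonnegative matrix with full support:
# finds x > 0 with x * (A %*% x) = 1. Inner-outer Newton iteration with
# conjugate-gradient inner solves. Returns NULL when the iteration stalls.
.kr_vector <- function(A, tol = 1e-6, max_iter = 3000) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  it <- 0
  while (rout > rt) {
    it <- it + 1
    if (it > max_iter) return(NULL)
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- w <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k > max_iter) return(NULL)
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    eta <- g * rat
    if (g * eta^2 > 0.1) eta <- max(eta, g * eta^2)
    eta <- max(min(eta, etamax), stop_tol / sqrt(rout))
    if (!is.finite(rout)) return(NULL)
  }
  x
}

# Symmetric alternate-scaling (Sinkhorn-Knopp style) fallback:
# x <- sqrt(x / (A x)) until row sums of diag(x) A diag(x) are within tol.
.sinkhorn_vector <- function(A, tol = 1e-6, max_iter = 50000) {
  x <- rep(1, nrow(A))
  for (i in seq_len(max_iter)) {
    r <- as.vector(A %*% x) * x
    if (max(abs(r - 1)) < tol) return(x)
    x <- x * sqrt(1 / r)
  }
  NULL
}

#' Knight-Ruiz balancing
#'
#' Finds a positive vector x such that `diag(x) %*% M %*% diag(x)` has all
#' unmasked row sums equal to 1 within `tol`. All-zero bins are masked
#' first and excluded. If the Knight-Ruiz iteration stalls, a symmetric
#' Sinkhorn-Knopp iteration is used as a logged fallback; failure of both is
#' an error carrying the last residual.
#'
#' @param cm a [contact_matrix()].
#' @param tol convergence tolerance on row sums (default 1e-6).
#' @param max_iter maximum iterations (default 3000).
#' @return `cm` with `balanced = TRUE`, `balancing` (the vector, `NA` at
#'   masked bins) and `balanced_counts` filled in.
#' @export
kr_balance <- function(cm, tol = 1e-6, max_iter = 3000) {
  keep <- !cm$masked
  if (!any(keep)) stop("fully zero contact matrix; cannot balance")
  A <- cm$counts[keep, keep, drop = FALSE]
  x <- .kr_vector(A, tol = tol, max_iter = max_iter)
  if (is.null(x)) {
    sereg_log("kr_balance: KR stalled; falling back to Sinkhorn-Knopp")
    x <- .sinkhorn_vector(A, tol = tol)
  }
  if (is.null(x) || any(!is.finite(x)) || any(x <= 0)) {
    last <- if (is.null(x)) NA_real_ else
      max(abs(as.vector(A %*% x) * x - 1))
    stop("matrix balancing did not converge (last residual ", last, ")")
  }
  B <- A * tcrossprod(x)
  resid <- max(abs(rowSums(B) - 1))
  if (resid >= tol) stop("balancing residual ", resid, " exceeds tol ", tol)
  full <- matrix(0, nrow(cm$counts), ncol(cm$counts))
  full[keep, keep] <- B
  bal <- rep(NA_real_, nrow(cm$counts))
  bal[keep] <- x
  cm$balanced <- TRUE
  cm$balancing <- bal
  cm$balanced_counts <- full
  cm
}

#' Expected contact by bin distance
#'
#' For each bin distance d, the mean balanced contact over all pairs of
#' unmasked bins at that distance (zero entries included). Distances with no
#' unmasked pair are `NA`.
#'
#' @param cm a balanced [contact_matrix()].
#' @return Numeric vector `expected` where `expected[d + 1]` is the mean at
#'   bin distance d.
#' @export
expected_by_distance <- function(cm) {
  if (!cm$balanced) stop("matrix must be balanced first")
  B <- cm$balanced_counts
  keep <- !cm$masked
  n <- nrow(B)
  vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    ok <- keep[i] & keep[i + d]
    if (!any(ok)) return(NA_real_)
    mean(B[cbind(i[ok], i[ok] + d)])
  }, 0)
}

# Internal: bin index (1-based row of the bin table) containing position pos.
.bin_index <- function(cm, pos) {
  idx <- findInterval(pos, cm$bins$start)
  if (idx < 1 || pos >= cm$bins$end[nrow(cm$bins)]) {
    stop("position ", pos, " outside binned region of ", cm$chrom)
  }
  idx
}

#' Observed/expected contact between a super-enhancer and a TSS
#'
#' Observed is the balanced count between the bin containing the SE midpoint
#' and the bin containing the TSS; the result is observed divided by the
#' expected value at their bin distance. `NA` (flagged) when either bin is
#' masked; a same-bin pair uses the d = 0 stratum and is flagged `self_bin`.
#'
#' @param cm balanced [contact_matrix()].
#' @param expected vector from [expected_by_distance()].
#' @param se one-row interval set (or list with `start`, `end`).
#' @param tss TSS position in bp.
#' @return A list with `oe`, `observed`, `expected`, `distance_bins`,
#'   `self_bin`, `masked`.
#' @export
se_gene_oe <- function(cm, expected, se, tss) {
  mid <- floor((se$start + se$end) / 2)
  bi <- .bin_index(cm, mid)
  bj <- .bin_index(cm, tss)
  d <- abs(bi - bj)
  if (cm$masked[bi] || cm$masked[bj]) {
    return(list(oe = NA_real_, observed = NA_real_, expected = NA_real_,
                distance_bins = d, self_bin = d == 0, masked = TRUE))
  }
  obs <- cm$balanced_counts[bi, bj]
  exp_d <- expected[d + 1]
  list(oe = obs / exp_d, observed = obs, expected = exp_d,
       distance_bins = d, self_bin = d == 0, masked = FALSE)
}

#' Distance-matched permutation control distribution
#'
#' For each permutation and each target gene at SE-to-TSS distance d, draws
#' one control gene uniformly from the `k_near` pool genes whose distance to
#' the SE is closest to d, without replacement within a permutation, and
#' records its observed/expected contact. All permutations are pooled into
#' one control distribution. Only intra-chromosomal (same chromosome as the
#' matrix) genes are meaningful here.
#'
#' @param cm balanced [contact_matrix()].
#' @param expected vector from [expected_by_distance()].
#' @param se one-row SE interval.
#' @param target_tss named vector of target-gene TSS positions.
#' @param pool_tss named vector of candidate control-gene TSS positions
#'   (expressed, not significantly changed, same chromosome); must be at
#'   least as many as targets.
#' @param n_perm number of permutations (default 100).
#' @param k_near control candidates per target (default 10).
#' @param seed integer seed.
#' @return A list with `control_oe` (pooled values), `picks` (matrix of
#'   chosen gene ids, targets x permutations), `n_perm`.
#' @export
distance_matched_null <- function(cm, expected, se, target_tss, pool_tss,
                                  n_perm = 100, k_near = 10, seed = 1) {
  if (length(pool_tss) < length(target_tss)) {
    stop("control pool smaller than target set")
  }
  mid <- floor((se$start + se$end) / 2)
  td <- abs(target_tss - mid)
  pd <- abs(pool_tss - mid)
  pool_ids <- names(pool_tss)
  picks <- matrix(NA_character_, length(target_tss), n_perm,
                  dimnames = list(names(target_tss), NULL))
  withr::with_seed(seed, {
    for (p in seq_len(n_perm)) {
      avail <- rep(TRUE, length(pool_tss))
      for (t in seq_along(td)) {
        cand <- which(avail)
        o <- order(abs(pd[cand] - td[t]))
        cand <- cand[o[seq_len(min(k_near, length(cand)))]]
        pick <- cand[sample.int(length(cand), 1)]
        avail[pick] <- FALSE
        picks[t, p] <- pool_ids[pick]
      }
    }
  })
  control_oe <- apply(picks, 2, function(col) {
    vapply(col, function(g) {
      se_gene_oe(cm, expected, se, pool_tss[[g]])$oe
    }, 0)
  })
  list(control_oe = as.vector(control_oe), picks = picks, n_perm = n_perm)
}

#' Classify targets as direct or indirect
#'
#' The threshold is the linear-interpolation `percentile` of the control
#' distribution (R quantile type 7); target pairs with observed/expected
#' strictly greater than the threshold are direct, the rest indirect.
#'
#' @param target_oe named vector of target observed/expected values.
#' @param control control distribution (nonempty numeric).
#' @param percentile percentile in (0, 100) (default 75).
#' @return A `data.frame` with `gene`, `oe`, `classification`; the threshold
#'   in attribute `threshold`.
#' @export
classify_targets <- function(target_oe, control, percentile = 75) {
  control <- control[!is.na(control)]
  if (!length(control)) stop("empty control distribution")
  thr <- unname(stats::quantile(control, percentile / 100, type = 7))
  out <- data.frame(
    gene = names(target_oe), oe = unname(target_oe),
    classification = ifelse(target_oe > thr, "direct", "indirect"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Full direct-target analysis for one super-enhancer
#'
#' Target genes are the cis (same-chromosome) genes significant in the DE
#' table at `padj < padj_threshold` (optionally also `log2fc <
#' lfc_threshold`, the down-regulated subset); the control pool is the cis
#' expressed genes (`base_mean > min_base_mean`) that fail significance.
#' The pipeline is observed/expected lookup, distance-matched permutation
#' null, percentile classification. The matrix is balanced on the fly if
#' needed.
#'
#' @param cm a [contact_matrix()].
#' @param se one-row SE interval set (with an `id`).
#' @param de DE table (`gene`, `log2fc`, `padj`, `base_mean`).
#' @param genes gene annotation data.frame (`gene`, `chrom`, `tss`).
#' @param padj_threshold significance cutoff (default 0.0005).
#' @param lfc_threshold optional LFC cutoff; e.g. -0.5 restricts targets to
#'   significantly down-regulated genes (default `NULL`, no LFC filter).
#' @param min_base_mean expressed-gene cutoff for the control pool
#'   (default 100).
#' @param percentile,n_perm,k_near,seed see [distance_matched_null()] and
#'   [classify_targets()].
#' @return A `data.frame` of target calls: `se_id`, `gene`, `distance` (bp),
#'   `oe`, `classification`; attributes `threshold` and `control_oe`. Empty
#'   (with a log line) when there are no cis targets.
#' @export
run_target_analysis <- function(cm, se, de, genes, padj_threshold = 0.0005,
                                lfc_threshold = NULL, min_base_mean = 100,
                                percentile = 75, n_perm = 100, k_near = 10,
                                seed = 1) {
  ann <- merge(de, genes, by = "gene")
  cis <- ann[ann$chrom == cm$chrom, , drop = FALSE]
  if (!nrow(cis)) {
    sereg_log("run_target_analysis: no cis genes (intra-chromosomal only)")
    warning("no cis genes on ", cm$chrom)
    return(.empty_target_calls())
  }
  sig <- cis$padj < padj_threshold
  if (!is.null(lfc_threshold)) sig <- sig & cis$log2fc < lfc_threshold
  targets <- cis[sig, , drop = FALSE]
  pool <- cis[!sig & cis$base_mean > min_base_mean, , drop = FALSE]
  if (!nrow(targets)) {
    sereg_log("run_target_analysis: no cis target genes pass thresholds")
    return(.empty_target_calls())
  }
  if (!cm$balanced) cm <- kr_balance(cm)
  expected <- expected_by_distance(cm)
  target_tss <- stats::setNames(targets$tss, targets$gene)
  pool_tss <- stats::setNames(pool$tss, pool$gene)
  target_oe <- vapply(seq_along(target_tss), function(i) {
    se_gene_oe(cm, expected, se, target_tss[i])$oe
  }, 0)
  names(target_oe) <- names(target_tss)
  null <- distance_matched_null(cm, expected, se, target_tss, pool_tss,
                                n_perm = n_perm, k_near = k_near, seed = seed)
  calls <- classify_targets(target_oe, null$control_oe,
                            percentile = percentile)
  mid <- floor((se$start + se$end) / 2)
  out <- data.frame(se_id = se$id, gene = calls$gene,
                    distance = abs(target_tss[calls$gene] - mid),
                    oe = calls$oe, classification = calls$classification,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- attr(calls, "threshold")
  attr(out, "control_oe") <- null$control_oe
  out
}

.empty_target_calls <- function() {
  data.frame(se_id = character(0), gene = character(0),
             distance = numeric(0), oe = numeric(0),
             classification = character(0), stringsAsFactors = FALSE)
}

#' Modified Activity-by-Contact scores
#'
#' For each SE and each cis expressed gene (`base_mean > min_base_mean`),
#' activity is the SE's aggregate BRD4 signal and contact is the balanced
#' Hi-C count between the SE-midpoint bin and the TSS bin (50-kb resolution
#' by default). Both vectors are log2(x + 1)-transformed and standardised
#' (z-scores over all scored pairs; min-max scaling behind `scaling =
#' "minmax"`), then multiplied. Pairs are ranked per SE by descending score.
#'
#' @param ses SE interval set with `id` and `signal` columns.
#' @param genes gene annotation with `gene`, `chrom`, `tss`, `base_mean`.
#' @param cm balanced [contact_matrix()] at the ABC resolution.
#' @param min_base_mean expressed-gene cutoff (default 100).
#' @param scaling `"z"` (default) or `"minmax"`.
#' @return A `data.frame` with `se_id`, `gene`, `activity`, `contact`,
#'   `score`, `rank` (per SE, 1 = best).
#' @export
abc_scores <- function(ses, genes, cm, min_base_mean = 100,
                       scaling = c("z", "minmax")) {
  scaling <- match.arg(scaling)
  if (!cm$balanced) cm <- kr_balance(cm)
  expressed <- genes[genes$base_mean > min_base_mean &
                       genes$chrom == cm$chrom, , drop = FALSE]
  ses <- ses[ses$chrom == cm$chrom, , drop = FALSE]
  pairs <- expand.grid(se = seq_len(nrow(ses)), g = seq_len(nrow(expressed)))
  if (nrow(pairs) < 2) stop("fewer than 2 SE-gene pairs; cannot standardise")
  activity <- ses$signal[pairs$se]
  contact <- vapply(seq_len(nrow(pairs)), function(k) {
    se <- ses[pairs$se[k], ]
    bi <- .bin_index(cm, floor((se$start + se$end) / 2))
    bj <- .bin_index(cm, expressed$tss[pairs$g[k]])
    cm$balanced_counts[bi, bj]
  }, 0)
  zscale <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  mmscale <- function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  }
  a <- log2(activity + 1); cc <- log2(contact + 1)
  if (scaling == "z") {
    a <- zscale(a); cc <- zscale(cc)
  } else {
    a <- mmscale(a); cc <- mmscale(cc)
  }
  out <- data.frame(se_id = ses$id[pairs$se], gene = expressed$gene[pairs$g],
                    activity = activity, contact = contact, score = a * cc,
                    stringsAsFactors = FALSE)
  out <- out[order(out$se_id, -out$score), , drop = FALSE]
  out$rank <- stats::ave(-out$score, out$se_id, FUN = rank)
  rownames(out) <- NULL
  out
}
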