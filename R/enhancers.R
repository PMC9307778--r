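# Enhancer filter chain and ROSE-style super-enhancer calling.
#
# The pipeline keeps BRD4 peaks co-occupied by H3K27ac (>= 1 bp overlap,
# BRD4 coordinates retained), removes peaks touching annotated genes or
# promoters, stitches surviving enhancers within 12.5 kb (the ROSE default),
# and cuts the signal-vs-rank curve at the point where its scaled slope
# first exceeds 1.

#' Keep BRD4 peaks co-occupied by H3K27ac
#'
#' Returns the subset of BRD4 intervals that overlap at least one H3K27ac
#' interval by >= 1 bp. Output coordinates are the BRD4 coordinates; a BRD4
#' peak overlapped by several H3K27ac peaks appears once.
#'
#' @param brd4,k27ac interval sets on the same genome.
#' @return The co-occupied subset of `brd4`.
#' @export
co_occupied_peaks <- function(brd4, k27ac) {
  idx <- .overlapping_idx(brd4, k27ac)
  out <- brd4[idx, , drop = FALSE]
  log_filter("co_occupied_peaks", nrow(brd4), nrow(out))
  rownames(out) <- NULL
  out
}

#' Remove peaks overlapping genes or promoters
#'
#' Drops any peak with >= 1 bp overlap to an annotated gene body or promoter,
#' leaving the distal (intergenic) enhancer set the super-enhancer calling
#' runs on.
#'
#' @param peaks interval set of peaks.
#' @param genes,promoters annotation interval sets.
#' @return The surviving subset of `peaks`.
#' @export
exclude_genic <- function(peaks, genes, promoters) {
  annot <- rbind(genes[c("chrom", "start", "end", "id")],
                 promoters[c("chrom", "start", "end", "id")])
  drop <- .overlapping_idx(peaks, annot)
  out <- if (length(drop)) peaks[-drop, , drop = FALSE] else peaks
  log_filter("exclude_genic", nrow(peaks), nrow(out))
  rownames(out) <- NULL
  out
}

#' Stitch nearby enhancers into candidate super-enhancer regions
#'
#' Transitively merges same-chromosome peaks whose inter-peak gap
#' (`next$start - prev$end`) is at most `gap` bp (12.5 kb, the ROSE default).
#' Each stitched region spans min(start) to max(end), carries the sum of its
#' constituents' signal, and records the constituent peak ids.
#'
#' @param peaks interval set with a `signal` column.
#' @param gap maximum stitching gap in bp (default 12500).
#' @return An interval set of stitched regions with columns `signal`,
#'   `n_constituents` and a `constituents` list-column of peak ids.
#' @export
stitch <- function(peaks, gap = 12500) {
  if (nrow(peaks) == 0) {
    out <- peaks
    out$n_constituents <- integer(0)
    out$constituents <- list()
    return(out)
  }
  if (is.null(peaks$signal)) peaks$signal <- 0
  o <- order(peaks$chrom, peaks$start, peaks$end)
  p <- peaks[o, , drop = FALSE]
  new_chrom <- c(TRUE, p$chrom[-1] != p$chrom[-nrow(p)])
  # running maximum of end within chromosome handles contained intervals
  run_end <- p$end
  grp <- integer(nrow(p)); grp[1] <- 1L
  if (nrow(p) > 1) {
    for (i in 2:nrow(p)) {
      if (!new_chrom[i] && p$start[i] - run_end[i - 1] <= gap) {
        grp[i] <- grp[i - 1]
        run_end[i] <- max(run_end[i - 1], p$end[i])
      } else {
        grp[i] <- grp[i - 1] + 1L
      }
    }
  }
  pieces <- split(p, grp)
  out <- data.frame(
    chrom = vapply(pieces, function(x) x$chrom[1], ""),
    start = vapply(pieces, function(x) min(x$start), 0),
    end = vapply(pieces, function(x) max(x$end), 0),
    id = paste0("region", seq_along(pieces)),
    signal = vapply(pieces, function(x) sum(x$signal), 0),
    n_constituents = vapply(pieces, nrow, 0L),
    stringsAsFactors = FALSE)
  out$constituents <- lapply(pieces, function(x) x$id)
  sereg_log("stitch: ", nrow(peaks), " peaks -> ", nrow(out), " regions")
  rownames(out) <- NULL
  out
}

#' ROSE-style super-enhancer rank cutoff
#'
#' Sorts stitched regions by ascending signal, rescales the rank axis and the
#' signal axis each to [0, 1], estimates the slope of the resulting curve by
#' central finite differences (one-sided at the endpoints), and sets the
#' cutoff at the signal of the lowest-rank point whose scaled slope strictly
#' exceeds 1 — the point where the curve leaves the unit tangent, the
#' geometric criterion ROSE implements. Regions with signal strictly above
#' the cutoff are super-enhancers, ranked 1 = highest signal.
#'
#' @param regions stitched interval set with a `signal` column (>= 3 regions
#'   with non-identical signals).
#' @return A list with `ses` (the super-enhancer subset, extra columns
#'   `rank`), `cutoff_signal`, and `curve` (a data.frame of rank, signal and
#'   scaled slope for plotting).
#' @export
rank_cutoff <- function(regions) {
  n <- nrow(regions)
  sig <- sort(regions$signal)
  if (n < 3) stop("need at least 3 regions")
  rng <- sig[n] - sig[1]
  x <- (seq_len(n) - 1) / (n - 1)
  curve <- data.frame(rank = seq_len(n), signal = sig)
  if (rng == 0) {
    warning("all signals identical; no super-enhancers called")
    curve$slope <- NA_real_
    return(list(ses = cbind(regions[0, , drop = FALSE], rank = integer(0)),
                cutoff_signal = NA_real_, curve = curve))
  }
  y <- (sig - sig[1]) / rng
  slope <- numeric(n)
  slope[1] <- (y[2] - y[1]) / (x[2] - x[1])
  slope[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    slope[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  curve$slope <- slope
  hit <- which(slope > 1)
  if (!length(hit)) {
    warning("scaled slope never exceeds 1; no super-enhancers called")
    return(list(ses = cbind(regions[0, , drop = FALSE], rank = integer(0)),
                cutoff_signal = NA_real_, curve = curve))
  }
  cutoff <- sig[hit[1]]
  ses <- regions[regions$signal > cutoff, , drop = FALSE]
  ses <- ses[order(-ses$signal), , drop = FALSE]
  if (nrow(ses)) {
    ses$rank <- seq_len(nrow(ses))
    ses$id <- paste0("SE", ses$rank)
  } else {
    ses$rank <- integer(0)
  }
  sereg_log("rank_cutoff: ", nrow(ses), " super-enhancers above signal ",
            signif(cutoff, 6))
  rownames(ses) <- NULL
  list(ses = ses, cutoff_signal = cutoff, curve = curve)
}

#' Full super-enhancer call from raw peak inputs
#'
#' Convenience wrapper: co-occupancy filter, genic/promoter exclusion,
#' stitching, rank cutoff.
#'
#' @param brd4,k27ac,genes,promoters interval sets.
#' @param gap stitching gap in bp.
#' @return The [rank_cutoff()] result, plus the intermediate `enhancers`.
#' @export
call_super_enhancers <- function(brd4, k27ac, genes, promoters, gap = 12500) {
  kept <- co_occupied_peaks(brd4, k27ac)
  distal <- exclude_genic(kept, genes, promoters)
  regions <- stitch(distal, gap = gap)
  out <- rank_cutoff(regions)
  out$enhancers <- distal
  out$regions <- regions
  out
}
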