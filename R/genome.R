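# Genome tables, interval sets and the shared overlap convention.
#
# All coordinates package-wide are 0-based half-open [start, end), the native
# BED convention. Two intervals overlap iff max(starts) < min(ends), i.e. they
# share at least one base; that single predicate (via GenomicRanges with a
# 0-based shift at the boundary) backs every overlap step in the pipeline.

#' Construct a genome table
#'
#' A genome table holds the chromosome names and lengths that every interval
#' set is validated against.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length positive integer chromosome lengths in bp.
#' @return A `data.frame` with columns `chrom`, `length`.
#' @seealso [hg19_autosomes()]
#' @export
genome_table <- function(chrom, length) {
  stopifnot(is.character(chrom), length(chrom) == base::length(length))
  if (anyDuplicated(chrom)) stop("duplicate chromosome names")
  length <- as.numeric(length)
  if (any(!is.finite(length) | length <= 0)) stop("chromosome lengths must be > 0")
  data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
}

#' The hg19 autosomal genome
#'
#' Chromosome lengths for the 22 human autosomes in genome build hg19/GRCh37,
#' embedded as constants. This is the coordinate system the copy-number
#' windowing runs on; the 22 lengths sum to 2,881,033,286 bp.
#'
#' @return A genome table (see [genome_table()]) with 22 rows, chr1..chr22.
#' @examples
#' g <- hg19_autosomes()
#' sum(g$length)  # 2881033286
#' @export
hg19_autosomes <- function() {
  genome_table(
    chrom = paste0("chr", 1:22),
    length = c(
      249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
      159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
      115169878, 107349540, 102531392,  90354753,  81195210,  78077248,
       59128983,  63025520,  48129895,  51304566)
  )
}

#' Construct and validate an interval set
#'
#' The backbone container for peaks, enhancers, super-enhancers and windows:
#' a data.frame of 0-based half-open intervals with an id and an optional
#' nonnegative signal column.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param id interval identifiers (defaults to `iv1..ivN`).
#' @param signal optional nonnegative per-interval signal.
#' @param genome optional genome table; when given, every chromosome must be
#'   present and `end` must not exceed its length.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `id` and,
#'   when supplied, `signal`.
#' @export
intervals <- function(chrom, start, end, id = NULL, signal = NULL,
                      genome = NULL) {
  n <- length(start)
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(end) == n)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop("interval start >= end at record ", bad,
         " (", chrom[bad], ":", start[bad], "-", end[bad], ")")
  }
  if (any(start < 0)) stop("negative start coordinate")
  if (is.null(id)) id <- if (n) paste0("iv", seq_len(n)) else character(0)
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    id = as.character(id), stringsAsFactors = FALSE)
  if (!is.null(signal)) {
    signal <- as.numeric(signal)
    stopifnot(length(signal) == n)
    if (any(signal < 0, na.rm = TRUE)) stop("signal must be nonnegative")
    out$signal <- signal
  }
  if (!is.null(genome)) {
    miss <- setdiff(out$chrom, genome$chrom)
    if (length(miss)) stop("chromosomes absent from genome: ",
                           paste(miss, collapse = ", "))
    lens <- genome$length[match(out$chrom, genome$chrom)]
    if (any(out$end > lens)) stop("interval end exceeds chromosome length")
  }
  out
}

#' Do two intervals overlap?
#'
#' The single overlap predicate used throughout: half-open intervals share at
#' least one base iff `max(start1, start2) < min(end1, end2)`. Vectorised.
#'
#' @param start1,end1,start2,end2 coordinates of the two intervals.
#' @return Logical vector.
#' @examples
#' intervals_overlap(100, 200, 199, 300)  # TRUE, 1-bp overlap
#' intervals_overlap(100, 200, 200, 300)  # FALSE, half-open abut
#' @export
intervals_overlap <- function(start1, end1, start2, end2) {
  pmax(start1, start2) < pmin(end1, end2)
}

# Internal: interval set -> GRanges. Converts 0-based half-open to the 1-based
# closed convention GRanges uses, so findOverlaps reproduces the >= 1 bp rule.
.as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

# Internal: indices of `query` intervals overlapping any `subject` interval
# by >= 1 bp.
.overlapping_idx <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) return(integer(0))
  hits <- GenomicRanges::findOverlaps(.as_granges(query), .as_granges(subject),
                                      minoverlap = 1L)
  sort(unique(S4Vectors::queryHits(hits)))
}

#' Tile a genome into fixed-width windows
#'
#' Divides each chromosome into consecutive, non-overlapping windows of
#' `width` bp starting at 0; the final window on each chromosome is truncated
#' at the chromosome end. The default 15-kb width over the hg19 autosomes
#' produces ~192,000 windows, the grid the copy-number analyses run on.
#'
#' @param genome a genome table.
#' @param width window width in bp (default 15000).
#' @return An interval set of windows with stable ids `<chrom>_w<k>` ordered
#'   by (chromosome, start).
#' @examples
#' tile_genome(genome_table("chrA", 46000), 15000)  # 4 windows, last 1 kb
#' @export
tile_genome <- function(genome, width = 15000) {
  stopifnot(width > 0)
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0, len - 1, by = width)
    ends <- pmin(starts + width, len)
    data.frame(chrom = genome$chrom[i], start = starts, end = ends,
               id = paste0(genome$chrom[i], "_w", seq_along(starts)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "window_width") <- width
  out
}
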