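# Readers and writers for the plain-text formats the pipeline touches:
# BED3/BED4 interval files, SEG-like copy-number segment tables, gene x sample
# matrices (TSV), DE tables, and binned contact triplets with a bin table.
# All readers validate on the way in; all read/write pairs round-trip.

#' Read intervals from a BED-dialect file
#'
#' Accepts whitespace- or tab-delimited BED3 (chrom, start, end), BED4
#' (+ name) or bedGraph-style (chrom, start, end, signal) text. Coordinates
#' are taken as 0-based half-open unless `one_based = TRUE`, in which case
#' starts are shifted down by one at the boundary. Records on chromosomes
#' absent from `genome` are dropped with a logged count.
#'
#' @param path file path.
#' @param genome genome table used to validate/drop chromosomes.
#' @param one_based set TRUE for 1-based inclusive input dialects.
#' @return An interval set (see [intervals()]); a numeric 4th column is parsed
#'   as `signal`, a non-numeric one as `id`.
#' @export
read_intervals <- function(path, genome, one_based = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(intervals(character(0), numeric(0), numeric(0)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinate")
  }
  if (one_based) start <- start - 1
  id <- NULL; signal <- NULL
  if (any(nf >= 5)) {
    id <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
    col5 <- vapply(fields, function(f) if (length(f) >= 5) f[5] else NA_character_, "")
    signal <- suppressWarnings(as.numeric(col5))
    if (anyNA(signal) && !anyNA(col5)) stop("non-numeric signal column")
  } else if (any(nf >= 4)) {
    col4 <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
    num4 <- suppressWarnings(as.numeric(col4))
    if (all(is.na(num4) == is.na(col4))) signal <- num4 else id <- col4
  }
  keep <- chrom %in% genome$chrom
  if (any(!keep)) {
    log_filter("read_intervals: off-genome chromosomes", length(keep), sum(keep))
    warning(sum(!keep), " record(s) on chromosomes absent from genome dropped")
  }
  bad <- which(keep & start >= end)
  if (length(bad)) {
    stop("interval with start >= end at line ", bad[1])
  }
  intervals(chrom[keep], start[keep], end[keep],
            id = if (is.null(id)) NULL else id[keep],
            signal = if (is.null(signal)) NULL else signal[keep],
            genome = genome)
}

#' Write intervals to a BED-dialect file
#'
#' Emits tab-separated BED4 (`chrom start end id`) or, when a signal column is
#' present, 5 columns with the signal formatted to 6 significant digits.
#' `read_intervals(write_intervals(x))` recovers `x`.
#'
#' @param set interval set.
#' @param path output file path.
#' @export
write_intervals <- function(set, path) {
  cols <- c(set["chrom"], list(format(set$start, scientific = FALSE, trim = TRUE),
                               format(set$end, scientific = FALSE, trim = TRUE)),
            set["id"])
  if (!is.null(set$signal)) {
    cols <- c(cols, list(signif(set$signal, 6)))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SEG-like copy-number segment table
#'
#' Expects delimited text with a header and columns patient, chrom, start,
#' end, value (seg-mean-style continuous copy number). Validates that one
#' patient's segments on one chromosome never overlap.
#'
#' @param path file path.
#' @return A `data.frame` with columns `patient`, `chrom`, `start`, `end`,
#'   `value`.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("patient", "chrom", "start", "end", "value")
  if (!all(need %in% names(df))) {
    stop("segment file must have header columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$patient <- as.character(df$patient); df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df$value <- as.numeric(df$value)
  if (any(df$start >= df$end)) stop("segment with start >= end")
  validate_segments(df)
  df
}

#' @rdname read_segments
#' @param segments a segment table to validate (overlap check only).
#' @export
validate_segments <- function(segments) {
  by <- split(segments, paste(segments$patient, segments$chrom, sep = "\r"))
  for (grp in by) {
    o <- order(grp$start)
    s <- grp$start[o]; e <- grp$end[o]
    if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
      stop("overlapping segments for patient ", grp$patient[1],
           " on ", grp$chrom[1])
    }
  }
  invisible(segments)
}

#' @rdname read_segments
#' @param path output file path for [write_segments()].
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a labelled matrix (genes or windows x samples) as TSV
#'
#' First column holds row ids, header row holds column ids. Missing entries
#' are the literal `NA`.
#'
#' @param path file path.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate row ids in matrix file")
  m <- as.matrix(df[-1])
  if (anyDuplicated(colnames(m))) stop("duplicate column ids in matrix file")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_matrix
#' @param m numeric matrix with dimnames.
#' @param id_name header name for the row-id column.
#' @export
write_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a differential-expression table
#'
#' Delimited text with header columns `gene`, `log2fc`, `padj`, `base_mean`
#' (DESeq2-style results consumed by the Hi-C target analysis). Adjusted
#' p-values must lie in [0, 1].
#'
#' @param path file path.
#' @return A `data.frame` with the four columns above.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "padj", "base_mean")
  if (!all(need %in% names(df))) {
    stop("DE table must have header columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE)) {
    stop("adjusted p-values outside [0, 1]")
  }
  if (any(df$base_mean < 0, na.rm = TRUE)) stop("negative base mean")
  df
}

#' @rdname read_de_table
#' @param de DE table to write.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binned contact matrix from a bin table and a triplet file
#'
#' `bins_path` is TSV with header `chrom, start, end, bin` giving a uniform
#' tiling of each chromosome; `triplets_path` is TSV with header
#' `bin_i, bin_j, count`. One chromosome's bins are materialised as a dense
#' symmetric matrix (each triplet stored once and mirrored). Triplets joining
#' two different chromosomes are retained in an `inter` attribute and
#' excluded from the matrix: all downstream contact analysis is restricted to
#' intra-chromosomal pairs.
#'
#' @param bins_path,triplets_path file paths.
#' @param chrom chromosome to materialise (default: the first in the bin
#'   table).
#' @return A [contact_matrix()] object.
#' @export
read_contacts <- function(bins_path, triplets_path, chrom = NULL) {
  bins <- utils::read.delim(bins_path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "bin")
  if (!all(need %in% names(bins))) {
    stop("bin table must have header columns: ", paste(need, collapse = ", "))
  }
  trip <- utils::read.delim(triplets_path, header = TRUE,
                            stringsAsFactors = FALSE)
  if (!all(c("bin_i", "bin_j", "count") %in% names(trip))) {
    stop("triplet file must have header columns: bin_i, bin_j, count")
  }
  if (!all(trip$bin_i %in% bins$bin) || !all(trip$bin_j %in% bins$bin)) {
    stop("triplet references unknown bin id")
  }
  if (is.null(chrom)) chrom <- bins$chrom[1]
  cb <- bins[bins$chrom == chrom, , drop = FALSE]
  cb <- cb[order(cb$start), , drop = FALSE]
  widths <- cb$end - cb$start
  if (nrow(cb) > 1) {
    if (length(unique(widths[-nrow(cb)])) != 1 ||
        any(cb$start[-1] != cb$end[-nrow(cb)])) {
      stop("bins do not tile ", chrom, " at a uniform width")
    }
  }
  binsize <- widths[1]
  n <- nrow(cb)
  m <- matrix(0, n, n)
  tchrom_i <- bins$chrom[match(trip$bin_i, bins$bin)]
  tchrom_j <- bins$chrom[match(trip$bin_j, bins$bin)]
  inter <- trip[tchrom_i != tchrom_j, , drop = FALSE]
  intra <- trip[tchrom_i == chrom & tchrom_j == chrom, , drop = FALSE]
  ii <- match(intra$bin_i, cb$bin); jj <- match(intra$bin_j, cb$bin)
  for (k in seq_len(nrow(intra))) {
    m[ii[k], jj[k]] <- m[ii[k], jj[k]] + intra$count[k]
    if (ii[k] != jj[k]) m[jj[k], ii[k]] <- m[jj[k], ii[k]] + intra$count[k]
  }
  cm <- contact_matrix(chrom = chrom, binsize = binsize, counts = m,
                       bins = cb)
  attr(cm, "inter") <- inter
  cm
}

#' @rdname read_contacts
#' @param cm a [contact_matrix()].
#' @export
write_contacts <- function(cm, bins_path, triplets_path) {
  utils::write.table(cm$bins, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ut <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
              arr.ind = TRUE)
  trip <- data.frame(bin_i = cm$bins$bin[ut[, 1]],
                     bin_j = cm$bins$bin[ut[, 2]],
                     count = cm$counts[ut])
  trip <- trip[order(match(trip$bin_i, cm$bins$bin),
                     match(trip$bin_j, cm$bins$bin)), ]
  utils::write.table(trip, triplets_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(triplets_path)
}

#' Read / write screen well metadata
#'
#' TSV with header `well, role, se_id`; `role` is one of `se`, `neg_control`,
#' `pos_control`.
#'
#' @param path file path.
#' @return A `data.frame` with the three columns.
#' @export
read_wells <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("well", "role") %in% names(df))) {
    stop("well metadata must have header columns: well, role")
  }
  if (is.null(df$se_id)) df$se_id <- NA_character_
  bad <- setdiff(unique(df$role), c("se", "neg_control", "pos_control"))
  if (length(bad)) stop("unknown well role: ", paste(bad, collapse = ", "))
  df[c("well", "role", "se_id")]
}

#' @rdname read_wells
#' @param wells well metadata to write.
#' @export
write_wells <- function(wells, path) {
  utils::write.table(wells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
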