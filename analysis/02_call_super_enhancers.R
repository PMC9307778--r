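#!/usr/bin/env Rscript
# Stage 2 — super-enhancer calling from the simulated peak tracks.
#
# Keeps BRD4 peaks co-occupied by H3K27ac (>= 1 bp, BRD4 coordinates),
# removes peaks touching genes or promoters, stitches within 12.5 kb, and
# cuts the signal-vs-rank curve where its scaled slope first exceeds 1.
# Writes the SE BED (signal + rank columns) and the rank-curve table, and
# reports recovery of the planted clusters.
#
# Usage: Rscript analysis/02_call_super_enhancers.R [--in-dir d] [--out-dir d]

suppressPackageStartupMessages(library(sereg))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
ind <- get_arg("--in-dir", "results/simdata")
out <- get_arg("--out-dir", "results/se_calls")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- with(utils::read.delim(file.path(ind, "genome.tsv")),
               genome_table(chrom, length))
brd4 <- read_intervals(file.path(ind, "brd4_peaks.bed"), genome)
k27 <- read_intervals(file.path(ind, "k27ac_peaks.bed"), genome)
genes <- read_intervals(file.path(ind, "genes.bed"), genome)
proms <- read_intervals(file.path(ind, "promoters.bed"), genome)

res <- call_super_enhancers(brd4, k27, genes, proms)
message(nrow(brd4), " BRD4 peaks -> ", nrow(res$enhancers),
        " co-occupied distal enhancers -> ", nrow(res$regions),
        " stitched regions -> ", nrow(res$ses),
        " super-enhancers (cutoff signal ",
        signif(res$cutoff_signal, 4), ")")

write_intervals(res$ses[c("chrom", "start", "end", "id", "signal")],
                file.path(out, "super_enhancers.bed"))
utils::write.table(res$curve, file.path(out, "rank_curve.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

truth <- read_intervals(file.path(ind, "truth_se_regions.bed"), genome)
hit <- vapply(seq_len(nrow(truth)), function(i) {
  any(res$ses$chrom == truth$chrom[i] &
        pmax(res$ses$start, truth$start[i]) <
          pmin(res$ses$end, truth$end[i]))
}, TRUE)
message("planted-cluster recall: ", mean(hit), " (", sum(hit), "/",
        length(hit), ")")
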