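#!/usr/bin/env Rscript
# Stage 5 — replicate-free CRISPRi screen: rank-change analysis.
#
# Normalises the counts (median-of-ratios size factors, log2), builds the
# within-well vs global rank-change table, chooses per-well thresholds at
# empirical FDR <= 0.1 against the negative-control wells, computes
# control-relative LFCs and the pooled RC-vs-LFC correlation matrix, and
# summarises the significant genes by k-means (k = 3) plus an SE dendrogram.
#
# Usage: Rscript analysis/05_screen.R [--seed s]

suppressPackageStartupMessages(library(sereg))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
ind <- get_arg("--in-dir", "results/simdata")
out <- get_arg("--out-dir", "results/screen")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

counts <- read_matrix(file.path(ind, "screen_counts.tsv"))
wells <- read_wells(file.path(ind, "screen_wells.tsv"))
storage.mode(counts) <- "integer"

norm <- preprocess_counts(counts)
rt <- rank_table(norm)
targets <- select_targets(rt, wells)
down <- targets[targets$direction == "down", ]
message("down-regulated calls: ", sum(down$n_genes), " genes across ",
        sum(down$n_genes > 0), " of ", nrow(down), " SE wells (median ",
        stats::median(down$n_genes), " per well)")

ctrl <- wells$well[wells$role == "neg_control"]
se_wells <- wells$well[wells$role == "se"]
lfc <- vapply(se_wells, function(w) control_lfc(norm, w, ctrl),
              numeric(nrow(norm)))
pooled <- unique(unlist(down$genes))
message("pooled significant genes: ", length(pooled))
cc <- rc_lfc_correlation(rt, lfc, pooled)
self_best <- mean(vapply(seq_len(nrow(cc)),
                         function(i) which.max(cc[i, ]) == i, TRUE),
                  na.rm = TRUE)
message("RC-LFC correlation: self-comparison is the row maximum for ",
        round(100 * self_best), "% of wells")

cs <- cluster_summary(rt, pooled, k_range = 1:6, chosen_k = 3,
                      se_wells = se_wells, seed = seed)

write_matrix(rt$rc, file.path(out, "rank_changes.tsv"), id_name = "gene")
write_matrix(lfc, file.path(out, "control_lfc.tsv"), id_name = "gene")
flat <- targets[c("well", "se_id", "direction", "threshold", "efdr",
                  "n_genes")]
flat$genes <- vapply(targets$genes, paste, "", collapse = ",")
utils::write.table(flat, file.path(out, "target_calls.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_matrix(cc, file.path(out, "rc_lfc_correlation.tsv"), id_name = "well")
utils::write.table(cs$elbow, file.path(out, "kmeans_elbow.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(gene = names(cs$clusters),
                              cluster = cs$clusters),
                   file.path(out, "gene_clusters.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote ", out)
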