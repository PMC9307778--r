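#!/usr/bin/env Rscript
# Stage 1 — generate every input the pipeline consumes, with planted truth.
#
# Writes, under results/simdata/: BRD4/H3K27ac/gene/promoter BED files, a
# SEG-like copy-number segment table plus the expression matrix for a
# 300-patient cohort, screen count and well-metadata tables, a binned Hi-C
# contact matrix as bins + triplets, a DE table for the Hi-C stage, and a
# truth manifest (YAML) holding everything the recovery checks may use.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>] [--out-dir <dir>]

suppressPackageStartupMessages(library(sereg))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out-dir", "results/simdata")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
p <- function(...) file.path(out, paste0(...))

## peak landscape on a two-chromosome toy genome
genome <- genome_table(c("cA", "cB"), c(6e7, 5e7))
pk <- simulate_peaks(genome, seed = seed)
write_intervals(pk$brd4, p("brd4_peaks.bed"))
write_intervals(pk$k27ac, p("k27ac_peaks.bed"))
write_intervals(pk$genes, p("genes.bed"))
write_intervals(pk$promoters, p("promoters.bed"))
write_intervals(pk$truth$se_regions, p("truth_se_regions.bed"))
utils::write.table(genome, p("genome.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("peaks: ", nrow(pk$brd4), " BRD4, ", nrow(pk$k27ac), " K27ac, ",
        nrow(pk$truth$se_regions), " planted SE clusters")

## copy-number + expression cohort on a 500-window chromosome
cohort_genome <- genome_table("cS", 500 * 15000)
grid <- tile_genome(cohort_genome, 15000)
co <- simulate_cohort(grid, n_patients = 300, n_genes = 400,
                      linked_pairs = 20, slope = 0.5, noise_sd = 0.5,
                      seed = seed + 1)
write_segments(co$segments, p("cohort_segments.seg"))
write_matrix(co$expression, p("cohort_expression.tsv"), id_name = "gene")
writeLines(co$truth$amp_windows, p("truth_amp_windows.txt"))
utils::write.table(co$truth$linked, p("truth_linked_pairs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cohort_genome, p("cohort_genome.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("cohort: ", length(unique(co$segments$patient)), " patients, ",
        nrow(co$expression), " genes, ", nrow(co$truth$linked),
        " planted linkages")

## CRISPRi screen counts
scr <- simulate_screen(seed = seed + 2)
write_matrix(scr$counts, p("screen_counts.tsv"), id_name = "gene")
write_wells(scr$wells, p("screen_wells.tsv"))
message("screen: ", nrow(scr$counts), " genes x ", ncol(scr$counts),
        " wells; planted targets in ",
        sum(lengths(scr$truth$targets) > 0), " wells")

## Hi-C contacts with planted loops + DE table
set.seed(seed + 3)
n_bins <- 300; binsize <- 50000
gene_bins <- sample(setdiff(1:n_bins, 145:155), 120)
hic_genes <- data.frame(gene = sprintf("g%03d", seq_along(gene_bins)),
                        chrom = "chrS",
                        tss = (gene_bins - 1) * binsize + 25000)
loops <- data.frame(bin_i = 150, bin_j = gene_bins[1:5], enrichment = 5)
sc <- simulate_contacts(n_bins = n_bins, binsize = binsize, scale = 200,
                        loops = loops, seed = seed + 3)
write_contacts(sc$contacts, p("hic_bins.tsv"), p("hic_triplets.tsv"))
de <- simulate_de_table(hic_genes$gene,
                        stats::setNames(rep(-1.5, 20), hic_genes$gene[1:20]),
                        seed = seed + 3)
write_de_table(de, p("hic_de_table.tsv"))
utils::write.table(hic_genes, p("hic_genes.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("hic: ", n_bins, " bins @ ", binsize, " bp, ", nrow(loops),
        " planted loops, ", sum(de$padj < 0.0005), " DE genes")

## truth manifest
yaml::write_yaml(list(
  seed = seed,
  planted_se_regions = nrow(pk$truth$se_regions),
  amp_windows = co$truth$amp_windows,
  linked_pairs = co$truth$linked,
  screen_targets = scr$truth$targets,
  hic_loops = loops,
  hic_loop_genes = hic_genes$gene[1:5],
  hic_se = list(chrom = "chrS", start = 149 * binsize, end = 150 * binsize)
), p("truth_manifest.yaml"))
message("wrote ", out)
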