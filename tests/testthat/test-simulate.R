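# Synthetic-data generators: determinism, validation, round-trips through
# the real readers, and the statistical structure the downstream stages rely
# on.

test_that("generators are deterministic under a fixed seed", {
  g <- toy_genome()
  expect_identical(simulate_peaks(g, seed = 3), simulate_peaks(g, seed = 3))
  grid <- tile_genome(genome_table("cS", 100 * 15000), 15000)
  expect_identical(
    simulate_cohort(grid, n_patients = 10, n_genes = 20, linked_pairs = 3,
                    seed = 5),
    simulate_cohort(grid, n_patients = 10, n_genes = 20, linked_pairs = 3,
                    seed = 5))
  expect_identical(simulate_screen(n_genes = 50, n_se_wells = 3, seed = 9),
                   simulate_screen(n_genes = 50, n_se_wells = 3, seed = 9))
  expect_identical(simulate_contacts(n_bins = 30, seed = 2),
                   simulate_contacts(n_bins = 30, seed = 2))
  # and different seeds change the draw
  expect_false(identical(simulate_contacts(n_bins = 30, seed = 2),
                         simulate_contacts(n_bins = 30, seed = 3)))
})

test_that("generator preconditions are enforced", {
  g <- toy_genome()
  grid <- tile_genome(genome_table("cS", 100 * 15000), 15000)
  expect_error(simulate_peaks(g, cluster_span = 1000, peaks_per_cluster = 8),
               "infeasible packing")
  expect_error(simulate_cohort(grid, n_patients = 2), "at least 3 patients")
  expect_error(simulate_cohort(grid, n_patients = 5, n_genes = 3,
                               linked_pairs = 10), "exceeds")
  expect_error(simulate_screen(n_control_wells = 1), "control wells")
  expect_error(simulate_screen(dispersion = 0), "dispersion")
  expect_error(simulate_contacts(decay_exponent = 0), "decay_exponent")
  expect_error(
    simulate_contacts(loops = data.frame(bin_i = 2, bin_j = 5,
                                         enrichment = 0.5)),
    "enrichment")
  expect_error(
    simulate_contacts(loops = data.frame(bin_i = 3, bin_j = 3,
                                         enrichment = 2)),
    "distinct bins")
})

test_that("emitted files re-read cleanly through the package readers", {
  g <- toy_genome()
  sim <- simulate_peaks(g, n_background_peaks = 50, n_se_clusters = 2,
                        n_genes = 30, seed = 11)
  f <- withr::local_tempfile()
  write_intervals(sim$brd4, f)
  back <- read_intervals(f, g)
  expect_equal(back$start, sim$brd4$start)
  expect_equal(back$signal, signif(sim$brd4$signal, 6))

  grid <- tile_genome(genome_table("cS", 50 * 15000), 15000)
  co <- simulate_cohort(grid, n_patients = 5, n_genes = 10, linked_pairs = 2,
                        seed = 2)
  write_segments(co$segments, f)
  expect_equal(read_segments(f), co$segments)
  write_matrix(co$expression, f, id_name = "gene")
  expect_equal(read_matrix(f), co$expression)

  sc <- simulate_contacts(n_bins = 12, binsize = 1000, scale = 30, seed = 4)
  b <- withr::local_tempfile(); t <- withr::local_tempfile()
  write_contacts(sc$contacts, b, t)
  back <- read_contacts(b, t)
  expect_equal(back$counts, sc$contacts$counts)
  expect_equal(back$binsize, 1000)
})

test_that("full co-occupancy keeps every BRD4 peak", {
  g <- toy_genome()
  sim <- simulate_peaks(g, n_background_peaks = 60, n_se_clusters = 2,
                        co_occupancy_prob = 1, seed = 8)
  kept <- co_occupied_peaks(sim$brd4, sim$k27ac)
  expect_equal(nrow(kept), nrow(sim$brd4))
})

test_that("cohort amplification and linkage structure are as planted", {
  grid <- tile_genome(genome_table("cS", 200 * 15000), 15000)
  co <- simulate_cohort(grid, n_patients = 40, n_genes = 50,
                        linked_pairs = 5, slope = 1, noise_sd = 0,
                        missing_rate = 0, seed = 6)
  # noiseless linkage: expression of a planted gene is exactly
  # mu + slope * CN of its window
  for (k in seq_len(5)) {
    w <- co$truth$linked$window[k]; gene <- co$truth$linked$gene[k]
    resid <- co$expression[gene, ] - co$cn[w, ]
    expect_lt(diff(range(resid)), 1e-9)
  }
  # amplified (window, patient) cells sit amp_effect above their baseline
  amp <- co$truth$amplified
  w1 <- rownames(amp)[1]
  on <- co$cn[w1, amp[w1, ]]; off <- co$cn[w1, !amp[w1, ]]
  expect_gt(mean(on) - mean(off), 0.8)
})

test_that("screen counts plant down-regulated genes only in SE wells", {
  sim <- simulate_screen(n_genes = 400, n_se_wells = 6, n_control_wells = 4,
                         target_lfc = -3, seed = 10)
  expect_true(all(sim$counts >= 0))
  expect_equal(dim(sim$counts), c(400, 10))
  planted <- unlist(sim$truth$targets)
  # planted genes depressed in their own well relative to control mean
  for (w in names(sim$truth$targets)) {
    for (gene in sim$truth$targets[[w]]) {
      ctrl <- mean(sim$counts[gene, sim$wells$well[sim$wells$role ==
                                                     "neg_control"]])
      expect_lt(sim$counts[gene, w], ctrl)
    }
  }
})

test_that("null contact matrices have O/E near 1 and planted loops stand out", {
  sc <- simulate_contacts(n_bins = 150, scale = 200, seed = 21)
  cm <- kr_balance(sc$contacts)
  e <- expected_by_distance(cm)
  # O/E over all unmasked pairs averages 1 by construction; spot-check a few
  # distance strata individually for stability
  B <- cm$balanced_counts
  for (d in c(1, 5, 20)) {
    i <- seq_len(150 - d)
    oe <- B[cbind(i, i + d)] / e[d + 1]
    expect_equal(mean(oe), 1, tolerance = 1e-9)
  }

  loops <- data.frame(bin_i = 40, bin_j = 90, enrichment = 5)
  oe_loop <- vapply(1:20, function(s) {
    scl <- simulate_contacts(n_bins = 150, scale = 200, loops = loops,
                             seed = 100 + s)
    cml <- kr_balance(scl$contacts)
    el <- expected_by_distance(cml)
    cml$balanced_counts[40, 90] / el[51]
  }, 0)
  expect_equal(mean(oe_loop), 5, tolerance = 0.25)
})

test_that("DE-table stand-in respects planted classes and fractions", {
  genes <- sprintf("g%03d", 1:200)
  de0 <- simulate_de_table(genes, planted = numeric(0), seed = 3)
  expect_equal(sum(de0$padj < 0.0005), 0)

  planted <- stats::setNames(rep(-1, 10), genes[1:10])
  de <- simulate_de_table(genes, planted, lfc_noise_sd = 0, seed = 3)
  expect_equal(de$log2fc[de$gene %in% names(planted)], rep(-1, 10))
  expect_true(all(de$padj[de$gene %in% names(planted)] < 0.0005))
  expect_true(all(de$padj[!de$gene %in% names(planted)] > 0.1))
  # requested low-expression fraction among non-targets
  expect_equal(sum(de$base_mean < 100), floor(0.2 * 190))
  expect_true(all(de$base_mean[de$gene %in% names(planted)] > 100))
})
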