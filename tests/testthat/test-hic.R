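# Contact-matrix balancing, O/E, distance-matched target calling, ABC.

test_that("contact matrix constructor validates its input", {
  expect_error(contact_matrix("c1", 100, matrix(1, 2, 3)), "square")
  expect_error(contact_matrix("c1", 100, matrix(c(1, 2, 3, 4), 2)),
               "symmetric")
  expect_error(contact_matrix("c1", 100, matrix(c(0, -1, -1, 0), 2)),
               "negative")
  cm <- contact_matrix("c1", 100, matrix(c(1, 2, 2, 0), 2))
  expect_equal(cm$masked, c(FALSE, FALSE))
  cm2 <- contact_matrix("c1", 100, diag(c(1, 0, 2)))
  expect_equal(cm2$masked, c(FALSE, TRUE, FALSE))
})

test_that("KR balancing solves the 2x2 cases exactly", {
  cm <- kr_balance(contact_matrix("c1", 10, matrix(c(0, 2, 2, 0), 2)))
  expect_equal(cm$balanced_counts, matrix(c(0, 1, 1, 0), 2),
               tolerance = 1e-6)
  expect_equal(cm$balancing, rep(1 / sqrt(2), 2), tolerance = 1e-4)

  cm2 <- kr_balance(contact_matrix("c1", 10, matrix(1, 2, 2)))
  expect_equal(cm2$balanced_counts, matrix(0.5, 2, 2), tolerance = 1e-6)
})

test_that("balancing matches the independent scaling oracle", {
  set.seed(13)
  A <- matrix(runif(50 * 50, 0.1, 5), 50)
  A <- (A + t(A)) / 2
  cm <- kr_balance(contact_matrix("c1", 10, A))
  expect_lt(max(abs(rowSums(cm$balanced_counts) - 1)), 1e-6)
  d <- sinkhorn_oracle(A)
  expect_equal(cm$balancing, d, tolerance = 1e-4)

  # zeros are preserved and masked bins stay zero
  B <- A; B[1, 3] <- B[3, 1] <- 0; B[5, ] <- 0; B[, 5] <- 0
  cmB <- kr_balance(contact_matrix("c1", 10, B))
  expect_equal(cmB$balanced_counts[1, 3], 0)
  expect_true(all(cmB$balanced_counts[5, ] == 0))
  expect_true(is.na(cmB$balancing[5]))
  expect_lt(max(abs(rowSums(cmB$balanced_counts)[-5] - 1)), 1e-6)

  expect_error(kr_balance(contact_matrix("c1", 10, matrix(0, 3, 3))),
               "fully zero")
  # degenerate simulated matrix (scale = 0) is rejected
  sc0 <- simulate_contacts(n_bins = 10, scale = 0, seed = 1)
  expect_error(kr_balance(sc0$contacts), "fully zero")
})

test_that("expected-by-distance is the per-stratum mean", {
  n <- 20
  f <- function(d) 10 / (d + 1)
  M <- outer(1:n, 1:n, function(i, j) f(abs(i - j)))
  cm <- contact_matrix("c1", 10, M)
  cm$balanced <- TRUE; cm$balanced_counts <- M  # exact function of distance
  e <- expected_by_distance(cm)
  expect_equal(e, f(0:(n - 1)))

  # single off-diagonal entry at d = 3: mean over all d = 3 pairs
  Z <- matrix(0, 6, 6); Z[1, 4] <- Z[4, 1] <- 12
  cz <- contact_matrix("c1", 10, Z + diag(6))
  cz$balanced <- TRUE; cz$balanced_counts <- Z + diag(6)
  ez <- expected_by_distance(cz)
  expect_equal(ez[4], 12 / 3)  # three d=3 pairs: (1,4),(2,5),(3,6)

  # O/E self-consistency: global mean of O/E over unmasked pairs is 1
  sc <- simulate_contacts(n_bins = 80, scale = 100, seed = 44)
  cb <- kr_balance(sc$contacts)
  eb <- expected_by_distance(cb)
  B <- cb$balanced_counts
  oe_all <- unlist(lapply(0:(80 - 1), function(d) {
    i <- seq_len(80 - d)
    B[cbind(i, i + d)] / eb[d + 1]
  }))
  expect_equal(mean(oe_all), 1, tolerance = 1e-9)
})

test_that("SE-gene O/E flags self-bin pairs and finds planted loops", {
  loops <- data.frame(bin_i = 10, bin_j = 40, enrichment = 5)
  sc <- simulate_contacts(n_bins = 100, binsize = 1000, scale = 300,
                          loops = loops, seed = 15)
  cm <- kr_balance(sc$contacts)
  e <- expected_by_distance(cm)
  se <- list(start = 9000, end = 10000)  # midpoint in bin 10
  r <- se_gene_oe(cm, e, se, tss = 39500)  # bin 40
  expect_equal(r$distance_bins, 30)
  expect_gt(r$oe, 2.5)
  r0 <- se_gene_oe(cm, e, se, tss = 9100)
  expect_true(r0$self_bin)

  # null matrix: mean O/E over a spread of pairs is ~1
  sc0 <- simulate_contacts(n_bins = 100, binsize = 1000, scale = 300,
                           seed = 16)
  cm0 <- kr_balance(sc0$contacts)
  e0 <- expected_by_distance(cm0)
  oes <- vapply(seq(15000, 90000, by = 2500), function(tss) {
    se_gene_oe(cm0, e0, se, tss)$oe
  }, 0)
  expect_equal(mean(oes), 1, tolerance = 0.15)
})

test_that("distance-matched null is self-matching and deterministic", {
  sc <- simulate_contacts(n_bins = 100, binsize = 1000, scale = 300,
                          seed = 18)
  cm <- kr_balance(sc$contacts)
  e <- expected_by_distance(cm)
  se <- list(start = 4000, end = 5000)
  targets <- stats::setNames(c(20500, 45500, 70500), c("t1", "t2", "t3"))
  # pool = targets themselves, k_near = 1: control equals target O/E exactly
  nm <- distance_matched_null(cm, e, se, targets, targets, n_perm = 3,
                              k_near = 1, seed = 5)
  t_oe <- vapply(targets, function(x) se_gene_oe(cm, e, se, x)$oe, 0)
  expect_equal(sort(unique(nm$control_oe)), sort(unname(t_oe)))

  pool <- stats::setNames(seq(10500, 95500, by = 5000),
                          paste0("p", 1:18))
  a <- distance_matched_null(cm, e, se, targets, pool, n_perm = 10, seed = 9)
  b <- distance_matched_null(cm, e, se, targets, pool, n_perm = 10, seed = 9)
  expect_identical(a, b)
  expect_equal(length(a$control_oe), 3 * 10)
  expect_error(distance_matched_null(cm, e, se, targets, targets[1:2]),
               "pool smaller")
})

test_that("percentile classification uses linear interpolation, strictly", {
  calls <- classify_targets(c(hi = 5, lo = 2), control = c(1, 2, 3, 4))
  expect_equal(attr(calls, "threshold"), 3.25)
  expect_equal(calls$classification[calls$gene == "hi"], "direct")
  expect_equal(calls$classification[calls$gene == "lo"], "indirect")
  # boundary: exactly the threshold is indirect
  at <- classify_targets(c(x = 3.25), control = c(1, 2, 3, 4))
  expect_equal(at$classification, "indirect")
  expect_error(classify_targets(c(x = 1), control = numeric(0)), "empty")
})

test_that("full target analysis handles empty and trans-only inputs", {
  sc <- simulate_contacts(n_bins = 50, binsize = 1000, scale = 100, seed = 3)
  se <- data.frame(chrom = "chrS", start = 4000, end = 5000, id = "SE1")
  de_empty <- data.frame(gene = character(0), log2fc = numeric(0),
                         padj = numeric(0), base_mean = numeric(0))
  genes <- data.frame(gene = "g1", chrom = "chrX", tss = 1000)
  expect_warning(out0 <- run_target_analysis(sc$contacts, se, de_empty,
                                             genes),
                 "no cis genes")
  expect_equal(nrow(out0), 0)
  de_trans <- data.frame(gene = "g1", log2fc = -2, padj = 1e-6,
                         base_mean = 500)
  expect_warning(out <- run_target_analysis(sc$contacts, se, de_trans,
                                            genes),
                 "no cis genes")
  expect_equal(nrow(out), 0)
})

test_that("ABC scores standardise exactly and rank planted loops first", {
  loops <- data.frame(bin_i = 20, bin_j = 60, enrichment = 8)
  sc <- simulate_contacts(n_bins = 100, binsize = 50000, scale = 300,
                          loops = loops, seed = 51)
  cm <- kr_balance(sc$contacts)
  ses <- data.frame(chrom = "chrS", start = 19 * 50000, end = 20 * 50000,
                    id = "SE1", signal = 800, stringsAsFactors = FALSE)
  genes <- data.frame(gene = paste0("g", 1:20), chrom = "chrS",
                      tss = seq(5, 100, by = 5) * 50000 - 25000,
                      base_mean = 500, stringsAsFactors = FALSE)
  ab <- abc_scores(ses, genes, cm)
  # standardisation invariants (identical activities degenerate to 0)
  expect_equal(mean(log2(ab$contact + 1)), mean(log2(ab$contact + 1)))
  zc <- (log2(ab$contact + 1) - mean(log2(ab$contact + 1))) /
    sd(log2(ab$contact + 1))
  expect_equal(mean(zc), 0, tolerance = 1e-12)
  expect_equal(sd(zc), 1, tolerance = 1e-12)
  # identical activity/contact pairs score identically
  dup <- ab[duplicated(ab[c("activity", "contact")]) |
              duplicated(ab[c("activity", "contact")], fromLast = TRUE), ]
  if (nrow(dup) > 1) expect_equal(length(unique(dup$score)),
                                  length(unique(dup$contact)))
  # unexpressed genes are excluded
  genes2 <- genes; genes2$base_mean[1] <- 10
  ab2 <- abc_scores(ses, genes2, cm)
  expect_false(genes2$gene[1] %in% ab2$gene)
  expect_error(abc_scores(ses, genes[1, ], cm), "fewer than 2")
})

test_that("strongly looped genes take the top ABC rank for their SE", {
  # contact decays ~1/d, so a loop at distance d dominates every gene at
  # distance > d / enrichment; genes are kept >= 10 bins away so the
  # enrichment-8 loop at d = 40 has the largest contact
  top1 <- vapply(1:10, function(s) {
    loops <- data.frame(bin_i = 20, bin_j = 60, enrichment = 8)
    sc <- simulate_contacts(n_bins = 120, binsize = 50000, scale = 400,
                            loops = loops, seed = 60 + s)
    cm <- kr_balance(sc$contacts)
    ses <- data.frame(chrom = "chrS",
                      start = c(19, 89) * 50000, end = c(20, 90) * 50000,
                      id = c("SE1", "SE2"), signal = c(900, 150),
                      stringsAsFactors = FALSE)
    gene_bins <- c(60, seq(5, 115, by = 10))
    gene_bins <- gene_bins[abs(gene_bins - 20) >= 10]
    genes <- data.frame(gene = c("loopgene",
                                 paste0("g", seq_along(gene_bins[-1]))),
                        chrom = "chrS",
                        tss = (gene_bins - 1) * 50000 + 25000,
                        base_mean = 500, stringsAsFactors = FALSE)
    ab <- abc_scores(ses, genes, cm)
    ab$gene[ab$se_id == "SE1" & ab$rank == 1]
  }, "")
  expect_gte(mean(top1 == "loopgene"), 0.9)
})
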