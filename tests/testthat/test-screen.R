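# Replicate-free screen: normalisation, rank change, eFDR thresholding,
# control-relative LFC, correlation and clustering summaries.

test_that("median-of-ratios size factors match the brute-force oracle", {
  counts <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
                   dimnames = list(paste0("g", 1:3), c("A", "B")))
  norm <- preprocess_counts(counts)
  expect_equal(unname(attr(norm, "size_factors")), c(1, 1))

  counts2 <- counts; counts2[, "B"] <- 2 * counts2[, "A"]
  sf <- attr(preprocess_counts(counts2), "size_factors")
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)

  # brute-force oracle on a random table
  set.seed(6)
  cr <- matrix(rpois(50 * 4, 40) + 1, 50, 4,
               dimnames = list(paste0("g", 1:50), paste0("w", 1:4)))
  sf2 <- attr(preprocess_counts(cr), "size_factors")
  geo <- apply(cr, 1, function(v) exp(mean(log(v))))
  oracle <- apply(cr / geo, 2, median)
  expect_equal(unname(sf2), unname(oracle))

  # all-zero gene dropped; all-zero-containing table errors
  cr2 <- rbind(cr, gz = 0)
  expect_false("gz" %in% rownames(preprocess_counts(cr2)))
  cz <- matrix(c(0, 1, 1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("w1", "w2")))
  expect_error(preprocess_counts(cz), "size factors undefined")
})

test_that("surrogate-component removal strips a planted well-level batch", {
  set.seed(31)
  base <- rlnorm(200, log(500), 1)
  counts <- vapply(1:6, function(j) rpois(200, base), numeric(200))
  dimnames(counts) <- list(paste0("g", 1:200), paste0("w", 1:6))
  batch <- counts
  batch[, 4:6] <- round(batch[, 4:6] * rlnorm(200, 0.5, 0.05))
  n0 <- preprocess_counts(batch)
  n1 <- preprocess_counts(batch, n_surrogates = 1)
  gap0 <- mean(abs(rowMeans(n0[, 4:6]) - rowMeans(n0[, 1:3])))
  gap1 <- mean(abs(rowMeans(n1[, 4:6]) - rowMeans(n1[, 1:3])))
  expect_lt(gap1, gap0)
})

test_that("rank table implements the CMAP-style rank-change statistic", {
  m <- matrix(c(10, 5, 7,
                9, 6, 8), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("w1", "w2")))
  rt <- rank_table(m)
  expect_equal(unname(rt$within[, "w1"]), c(1, 3, 2))

  tied <- matrix(c(5, 5, 1, 4, 3, 2), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("w1", "w2")))
  expect_equal(unname(rank_table(tied)$within[, "w1"]), c(1.5, 1.5, 3))

  # sign convention: within rank 10, global rank 3 -> RC = +7 (downranked)
  set.seed(41)
  m2 <- matrix(rnorm(12 * 4), 12, 4,
               dimnames = list(paste0("g", 1:12), paste0("w", 1:4)))
  rt2 <- rank_table(m2)
  expect_equal(rt2$rc, rt2$within - rt2$global_rank, ignore_attr = TRUE)
  # no ties: RC sums to zero exactly within every well
  expect_equal(unname(colSums(rt2$rc)), rep(0, 4))
  expect_error(rank_table(m2[, 1, drop = FALSE]), "at least 2 wells")
})

test_that("eFDR at a threshold reproduces the 4-vs-40 worked arithmetic", {
  # one well with 40 genes beyond threshold, controls with median 4
  n <- 300
  rc <- matrix(0, n, 6,
               dimnames = list(paste0("g", 1:n),
                               c("se1", paste0("ctl", 1:5))))
  rc[1:40, "se1"] <- 50
  rc[1:3, "ctl1"] <- 50; rc[1:4, "ctl2"] <- 50; rc[1:4, "ctl3"] <- 50
  rc[1:5, "ctl4"] <- 50; rc[1:6, "ctl5"] <- 50
  e <- efdr_at_threshold(rc, "se1", paste0("ctl", 1:5), threshold = 50)
  expect_equal(e$gene_count, 40)
  expect_equal(median(e$control_counts), 4)
  expect_equal(e$efdr, 0.10)

  # empty well and silent controls
  e0 <- efdr_at_threshold(rc, "se1", paste0("ctl", 1:5), threshold = 100)
  expect_equal(e0$efdr, 1)
  expect_equal(e0$gene_count, 0)
  rc2 <- rc; rc2[, paste0("ctl", 1:5)] <- 0
  e1 <- efdr_at_threshold(rc2, "se1", paste0("ctl", 1:5), threshold = 50)
  expect_equal(e1$efdr, 0)

  # up direction mirrors the convention
  rc3 <- rc; rc3[1:10, "se1"] <- -50
  eu <- efdr_at_threshold(rc3, "se1", paste0("ctl", 1:5), threshold = 50,
                          direction = "up")
  expect_equal(eu$gene_count, 10)
})

test_that("eFDR is monotone non-increasing in the well count", {
  ctrl_counts <- c(3, 4, 5)
  efdrs <- vapply(1:60, function(wc) {
    rc <- matrix(0, 100, 4,
                 dimnames = list(paste0("g", 1:100),
                                 c("w", paste0("c", 1:3))))
    rc[seq_len(wc), "w"] <- 10
    for (j in 1:3) rc[seq_len(ctrl_counts[j]), paste0("c", j)] <- 10
    efdr_at_threshold(rc, "w", paste0("c", 1:3), 10)$efdr
  }, 0)
  expect_true(all(diff(efdrs) <= 1e-12))
})

test_that("target selection honours the eFDR gate and its edge cases", {
  set.seed(19)
  sim <- simulate_screen(n_genes = 500, n_se_wells = 4, n_control_wells = 4,
                         target_lfc = -3, seed = 19)
  norm <- preprocess_counts(sim$counts)
  rt <- rank_table(norm)
  wells <- sim$wells
  expect_error(select_targets(rt, wells, threshold_grid = numeric(0)),
               "empty threshold grid")

  # target_efdr = 1 accepts the smallest threshold with any exceedance
  tg1 <- select_targets(rt, wells, target_efdr = 1.0)
  down1 <- tg1[tg1$direction == "down", ]
  grid <- round(500 * seq(0.01, 0.3, 0.01))
  for (i in seq_len(nrow(down1))) {
    if (is.na(down1$threshold[i])) next
    expect_equal(down1$threshold[i], grid[1])
    expect_equal(down1$n_genes[i], sum(rt$rc[, down1$well[i]] >= grid[1]))
  }

  # a "perturbation" well identical to a control well gets no calls
  norm2 <- norm
  norm2[, wells$well[wells$role == "se"][1]] <-
    norm2[, wells$well[wells$role == "neg_control"][1]]
  rt2 <- rank_table(norm2)
  tg2 <- select_targets(rt2, wells)
  w1 <- wells$well[wells$role == "se"][1]
  expect_equal(tg2$n_genes[tg2$well == w1 & tg2$direction == "down"], 0)
})

test_that("planted screen targets are recovered per well", {
  sim <- simulate_screen(n_genes = 1000, n_se_wells = 12,
                         n_control_wells = 6, seed = 23)
  norm <- preprocess_counts(sim$counts)
  rt <- rank_table(norm)
  tg <- select_targets(rt, sim$wells)
  down <- tg[tg$direction == "down", ]
  j <- vapply(seq_len(nrow(down)), function(i) {
    jaccard(down$genes[[i]],
            intersect(sim$truth$targets[[down$well[i]]], rownames(norm)))
  }, 0)
  expect_gte(median(j), 0.75)
})

test_that("control-relative LFC is the difference to the control median", {
  norm <- matrix(c(1, 2, 3,
                   1, 2, 3,
                   2, 2, 4,
                   3, 2, 5), 3, 4,
                 dimnames = list(paste0("g", 1:3),
                                 c("c1", "c2", "c3", "se")))
  lfc <- control_lfc(norm, "se", c("c1", "c2", "c3"))
  expect_equal(unname(lfc), c(3, 2, 5) - c(1, 2, 3))
  expect_equal(unname(control_lfc(norm, "c2", c("c1", "c2", "c3"))),
               c(0, 0, 0))
})

test_that("RC-LFC correlation is positive on self-comparison", {
  sim <- simulate_screen(n_genes = 800, n_se_wells = 10,
                         n_control_wells = 5, mean_targets_per_well = 6,
                         seed = 29)
  norm <- preprocess_counts(sim$counts)
  rt <- rank_table(norm)
  tg <- select_targets(rt, sim$wells)
  pooled <- unique(unlist(tg$genes[tg$direction == "down"]))
  se_wells <- sim$wells$well[sim$wells$role == "se"]
  ctrl <- sim$wells$well[sim$wells$role == "neg_control"]
  lfc <- vapply(se_wells, function(w) control_lfc(norm, w, ctrl),
                numeric(nrow(norm)))
  cc <- rc_lfc_correlation(rt, lfc, pooled)
  # self-agreement positive, and the diagonal is the row maximum for most
  # wells (each SE matches itself best)
  expect_true(all(diag(cc) > 0))
  frac_max <- mean(vapply(seq_len(nrow(cc)),
                          function(i) which.max(cc[i, ]) == i, TRUE))
  expect_gte(frac_max, 0.9)

  expect_error(rc_lfc_correlation(rt, lfc, pooled[1:2]), "fewer than 3")
  # two identical wells: off-diagonal equals the diagonal
  lfc2 <- lfc; lfc2[, 2] <- lfc2[, 1]
  rt3 <- rt; rt3$rc[, se_wells[2]] <- rt3$rc[, se_wells[1]]
  cc2 <- rc_lfc_correlation(rt3, lfc2, pooled)
  expect_equal(cc2[1, 2], cc2[1, 1])
  expect_equal(cc2[2, 1], cc2[2, 2])
})

test_that("cluster summary recovers planted gene groups and edge cases", {
  # three well-separated RC profile groups over 8 wells
  set.seed(37)
  centers <- matrix(c(rep(c(500, 0, -500), each = 8)), 8, 3)
  X <- do.call(rbind, lapply(1:90, function(i) {
    g <- (i - 1) %% 3 + 1
    centers[, g] + rnorm(8, 0, 20)
  }))
  dimnames(X) <- list(paste0("g", 1:90), paste0("w", 1:8))
  cs <- cluster_summary(X, rownames(X), k_range = 1:5, chosen_k = 3,
                        seed = 2)
  truth_lab <- rep(1:3, 30)
  expect_gte(adjusted_rand(cs$clusters, truth_lab), 0.9)
  # elbow: WSS drops hugely up to k=3, little after
  drop23 <- cs$elbow$wss[2] - cs$elbow$wss[3]
  drop34 <- cs$elbow$wss[3] - cs$elbow$wss[4]
  expect_gt(drop23, 10 * max(drop34, 1))

  cs1 <- cluster_summary(X, rownames(X), k_range = 1, chosen_k = 1, seed = 2)
  expect_equal(unname(unique(cs1$clusters)), 1)

  # identical wells merge at zero height
  X2 <- X; X2[, 2] <- X2[, 1]
  cs2 <- cluster_summary(X2, rownames(X2), k_range = 1:3, chosen_k = 3,
                         seed = 2)
  expect_equal(min(cs2$se_hclust$height), 0)
})
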