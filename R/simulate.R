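# Synthetic-data generators with planted ground truth.
#
# Every input the pipeline consumes can be generated here: clustered
# BRD4/H3K27ac peak tracks with a heavy-tailed signal distribution,
# piecewise-constant copy-number cohorts whose amplified windows linearly
# drive linked genes, negative-binomial screen counts with a minority of
# planted down-regulated genes per well, power-law distance-decay contact
# matrices with planted enhancer-gene loops, and DE-table stand-ins.
# Identical seeds give byte-identical outputs; recovery tests may only look
# at the returned `truth`, never at generator internals.

#' Simulate BRD4/H3K27ac peak landscapes with planted super-enhancers
#'
#' Background peaks are scattered uniformly over the genome with log-normal
#' signal; each planted super-enhancer cluster packs `peaks_per_cluster`
#' peaks into `cluster_span` bp with signal inflated well above the
#' background median (at least 5x; drawn from `se_signal_mult`). Each BRD4
#' peak is overlapped by an H3K27ac peak with probability
#' `co_occupancy_prob`; genes and promoters are placed away from the planted
#' clusters so the genic-exclusion filter never removes them.
#'
#' @param genome genome table.
#' @param n_background_peaks background BRD4 peaks (default 200).
#' @param n_se_clusters planted clusters (default 8).
#' @param peaks_per_cluster peaks per planted cluster (default 8).
#' @param cluster_span cluster width in bp (default 20000, near the 21-kb
#'   median super-enhancer size).
#' @param signal_meanlog,signal_sdlog log-normal background signal
#'   parameters (default 0, 0.5).
#' @param se_signal_mult range of the per-peak signal multiplier over the
#'   background median for cluster peaks (default c(20, 32)).
#' @param co_occupancy_prob probability a BRD4 peak is K27ac-co-occupied
#'   (default 0.9).
#' @param n_genes annotated genes to place (default 150).
#' @param peak_width range of peak widths in bp (default c(400, 1200)).
#' @param seed integer seed.
#' @return A list with interval sets `brd4`, `k27ac`, `genes`, `promoters`
#'   and `truth$se_regions` (the planted cluster spans).
#' @export
simulate_peaks <- function(genome, n_background_peaks = 200,
                           n_se_clusters = 8, peaks_per_cluster = 8,
                           cluster_span = 20000, signal_meanlog = 0,
                           signal_sdlog = 0.5, se_signal_mult = c(20, 32),
                           co_occupancy_prob = 0.9, n_genes = 150,
                           peak_width = c(400, 1200), seed = 1) {
  if (cluster_span < peaks_per_cluster * peak_width[1]) {
    stop("infeasible packing: cluster_span too small for ",
         peaks_per_cluster, " peaks of >= ", peak_width[1], " bp")
  }
  withr::with_seed(seed, {
    tot <- sum(genome$length)
    rand_pos <- function(n) {
      g <- sample.int(nrow(genome), n, replace = TRUE,
                      prob = genome$length / tot)
      data.frame(chrom = genome$chrom[g],
                 pos = floor(stats::runif(n) * (genome$length[g] - 2e5)),
                 stringsAsFactors = FALSE)
    }
    # planted clusters: rejection-sample locations >= 100 kb apart
    clusters <- rand_pos(n_se_clusters * 50)
    keep <- rep(TRUE, nrow(clusters))
    for (i in seq_len(nrow(clusters))) {
      if (!keep[i]) next
      later <- which(keep & seq_len(nrow(clusters)) > i &
                       clusters$chrom == clusters$chrom[i] &
                       abs(clusters$pos - clusters$pos[i]) < 1e5)
      keep[later] <- FALSE
    }
    clusters <- clusters[keep, , drop = FALSE][seq_len(n_se_clusters), ]
    if (anyNA(clusters$pos)) stop("infeasible packing: cannot place clusters")

    bg_med <- exp(signal_meanlog)  # median of the log-normal background
    mk_peaks <- function(chrom, pos, prefix) {
      w <- floor(stats::runif(length(pos), peak_width[1], peak_width[2]))
      intervals(chrom, pos, pos + w,
                id = paste0(prefix, seq_along(pos)),
                signal = stats::rlnorm(length(pos), signal_meanlog,
                                       signal_sdlog))
    }
    bg <- rand_pos(n_background_peaks)
    brd4 <- mk_peaks(bg$chrom, bg$pos, "bgpk")
    cl_list <- lapply(seq_len(n_se_clusters), function(k) {
      slots <- seq(0, cluster_span - peak_width[2],
                   length.out = peaks_per_cluster)
      starts <- clusters$pos[k] + floor(slots)
      w <- floor(stats::runif(peaks_per_cluster, peak_width[1],
                              peak_width[2]))
      intervals(clusters$chrom[k], starts, starts + w,
                id = paste0("sepk", k, "_", seq_len(peaks_per_cluster)),
                signal = bg_med * stats::runif(peaks_per_cluster,
                                               se_signal_mult[1],
                                               se_signal_mult[2]))
    })
    brd4 <- rbind(brd4, do.call(rbind, cl_list))
    # K27ac: co-occupying peak per BRD4 peak w.p. co_occupancy_prob,
    # plus independent background
    co <- stats::runif(nrow(brd4)) < co_occupancy_prob
    k27_co <- brd4[co, , drop = FALSE]
    if (nrow(k27_co)) {
      shift <- floor(stats::runif(nrow(k27_co), -200, 200))
      wid <- k27_co$end - k27_co$start
      k27_co$start <- pmax(k27_co$start + shift, 0)
      k27_co$end <- k27_co$start + wid
    }
    k27_bg <- rand_pos(ceiling(n_background_peaks / 2))
    k27ac <- rbind(
      intervals(k27_co$chrom, k27_co$start, k27_co$end,
                id = paste0("k27co", seq_len(nrow(k27_co))),
                signal = k27_co$signal),
      mk_peaks(k27_bg$chrom, k27_bg$pos, "k27bg"))
    # genes + promoters away from planted clusters
    margin <- cluster_span + 25000
    gpos <- rand_pos(n_genes * 5)
    near <- vapply(seq_len(nrow(gpos)), function(i) {
      any(clusters$chrom == gpos$chrom[i] &
            abs(clusters$pos - gpos$pos[i]) < margin)
    }, TRUE)
    gpos <- gpos[!near, , drop = FALSE][seq_len(n_genes), ]
    gw <- floor(stats::runif(n_genes, 2000, 20000))
    genes <- intervals(gpos$chrom, gpos$pos + 2000, gpos$pos + 2000 + gw,
                       id = paste0("gene", seq_len(n_genes)))
    promoters <- intervals(gpos$chrom, gpos$pos, gpos$pos + 2000,
                           id = paste0("prom", seq_len(n_genes)))
    truth_se <- intervals(clusters$chrom, clusters$pos,
                          clusters$pos + cluster_span,
                          id = paste0("plantedSE", seq_len(n_se_clusters)))
    list(brd4 = brd4, k27ac = k27ac, genes = genes, promoters = promoters,
         truth = list(se_regions = truth_se,
                      co_occupancy_prob = co_occupancy_prob))
  })
}

#' Simulate a copy-number + expression patient cohort
#'
#' Per-patient copy number is piecewise constant: segment breakpoints follow
#' an exponential spacing (mean `mean_segment_windows` windows) not aligned
#' to window boundaries, with seg-mean baseline values Normal(0, 0.1).
#' Each amplified window is shifted by `amp_effect` in a random
#' Bernoulli(`amp_frac`) subset of patients — amplification must vary across
#' patients for a copy-number eQTL to be estimable. For each planted
#' (window w, gene g) pair, `expr[g, p] = mu_g + slope * CN[w, p] + noise`;
#' unlinked genes are baseline plus noise. Expression entries are masked
#' missing at `missing_rate`.
#'
#' @param grid window interval set from [tile_genome()].
#' @param n_patients cohort size (default 300; >= 3 required).
#' @param amp_windows window ids to amplify (default: 50 random windows).
#' @param amp_effect seg-mean shift for amplified windows (default 1).
#' @param n_genes expression genes (default 500).
#' @param linked_pairs planted (window, gene) linkages (default 20;
#'   must be <= n_genes).
#' @param slope linear effect of copy number on expression (default 1).
#' @param noise_sd expression noise sd (default 0.5).
#' @param missing_rate expression missingness rate (default 0.05).
#' @param amp_frac fraction of patients carrying each amplification
#'   (default 0.5).
#' @param mean_segment_windows mean segment length in windows (default 20).
#' @param seed integer seed.
#' @return A list with `segments` (SEG-like data.frame), `expression`
#'   (genes x patients matrix with `NA` missing), `cn` (windows x patients
#'   matrix derived through [assign_copy_number()]), and `truth`
#'   (`amp_windows`, `amp_effect`, `linked` data.frame of window/gene/slope,
#'   `amplified` windows x patients logical matrix).
#' @export
simulate_cohort <- function(grid, n_patients = 300, amp_windows = NULL,
                            amp_effect = 1, n_genes = 500, linked_pairs = 20,
                            slope = 1, noise_sd = 0.5, missing_rate = 0.05,
                            amp_frac = 0.5, mean_segment_windows = 20,
                            seed = 1) {
  if (n_patients < 3) stop("need at least 3 patients (association undefined)")
  if (linked_pairs > n_genes) stop("linked_pairs exceeds n_genes")
  width <- attr(grid, "window_width")
  if (is.null(width)) width <- stats::median(grid$end - grid$start)
  withr::with_seed(seed, {
    if (is.null(amp_windows)) {
      amp_windows <- sample(grid$id, min(50, nrow(grid)))
    }
    chroms <- unique(grid$chrom)
    patients <- sprintf("pt%03d", seq_len(n_patients))
    amp_tab <- grid[match(amp_windows, grid$id), , drop = FALSE]
    amplified <- matrix(stats::runif(length(amp_windows) * n_patients) <
                          amp_frac,
                        length(amp_windows), n_patients,
                        dimnames = list(amp_windows, patients))
    seg_list <- vector("list", n_patients * length(chroms))
    si <- 0
    for (p in seq_len(n_patients)) {
      for (ch in chroms) {
        L <- max(grid$end[grid$chrom == ch])
        bp <- c(0)
        while (bp[length(bp)] < L) {
          bp <- c(bp, bp[length(bp)] +
                    stats::rexp(1, 1 / (mean_segment_windows * width)))
        }
        bp[length(bp)] <- L
        bp <- unique(floor(bp))
        amp_here <- amp_tab[amp_tab$chrom == ch, , drop = FALSE]
        cuts <- sort(unique(c(bp, amp_here$start, amp_here$end)))
        cuts <- cuts[cuts >= 0 & cuts <= L]
        s <- cuts[-length(cuts)]; e <- cuts[-1]
        run <- findInterval(s, bp, rightmost.closed = FALSE)
        vals <- stats::rnorm(length(bp), 0, 0.1)[run]
        if (nrow(amp_here)) {
          for (k in seq_len(nrow(amp_here))) {
            if (amplified[amp_here$id[k], p]) {
              inside <- s >= amp_here$start[k] & e <= amp_here$end[k]
              vals[inside] <- vals[inside] + amp_effect
            }
          }
        }
        si <- si + 1
        seg_list[[si]] <- data.frame(patient = patients[p], chrom = ch,
                                     start = s, end = e, value = vals,
                                     stringsAsFactors = FALSE)
      }
    }
    segments <- do.call(rbind, seg_list)
    rownames(segments) <- NULL
    cn <- assign_copy_number(grid, segments)
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    mu <- stats::rnorm(n_genes, 5, 1)
    expr <- matrix(mu, n_genes, n_patients) +
      matrix(stats::rnorm(n_genes * n_patients, 0, noise_sd), n_genes)
    dimnames(expr) <- list(gene_ids, patients)
    link_w <- sample(amp_windows, linked_pairs, replace =
                       linked_pairs > length(amp_windows))
    link_g <- sample(gene_ids, linked_pairs)
    for (k in seq_len(linked_pairs)) {
      expr[link_g[k], ] <- expr[link_g[k], ] + slope * cn[link_w[k], ]
    }
    if (missing_rate > 0) {
      expr[stats::runif(length(expr)) < missing_rate] <- NA
    }
    list(segments = segments, expression = expr, cn = cn,
         truth = list(amp_windows = amp_windows, amp_effect = amp_effect,
                      linked = data.frame(window = link_w, gene = link_g,
                                          slope = rep(slope, linked_pairs),
                                          stringsAsFactors = FALSE),
                      amplified = amplified))
  })
}

#' Simulate a replicate-free CRISPRi screen
#'
#' Gene baseline means are log-normal; counts are negative binomial with
#' variance `mean + dispersion * mean^2`. Each SE well carries
#' Poisson(`mean_targets_per_well`) planted target genes whose mean is
#' multiplied by `2^target_lfc`; control wells are unperturbed. Planted
#' targets are drawn from the upper half of the baseline distribution — a
#' silenced gene is only observable in a rank statistic if it was expressed
#' to begin with.
#'
#' @param n_genes genes (default 2000).
#' @param n_se_wells SE-targeting wells (default 86, the screen design).
#' @param n_control_wells negative-control wells (default 10; >= 2).
#' @param mean_targets_per_well Poisson mean of planted targets per well
#'   (default 4, the observed median scale).
#' @param target_lfc planted log2 fold change, negative (default -2).
#' @param dispersion negative-binomial dispersion (> 0, default 0.02).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters
#'   (default log(1000), 1).
#' @param seed integer seed.
#' @return A list with `counts` (genes x wells integer matrix), `wells`
#'   (metadata data.frame) and `truth$targets` (named list well -> planted
#'   gene ids).
#' @export
simulate_screen <- function(n_genes = 2000, n_se_wells = 86,
                            n_control_wells = 10, mean_targets_per_well = 4,
                            target_lfc = -2, dispersion = 0.02,
                            baseline_meanlog = log(1000), baseline_sdlog = 1,
                            seed = 1) {
  if (n_control_wells < 2) stop("need at least 2 control wells")
  if (dispersion <= 0) stop("dispersion must be > 0")
  withr::with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    base <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    names(base) <- gene_ids
    se_wells <- sprintf("se_w%02d", seq_len(n_se_wells))
    ctrl_wells <- sprintf("ctrl_w%02d", seq_len(n_control_wells))
    wells <- data.frame(
      well = c(se_wells, ctrl_wells),
      role = c(rep("se", n_se_wells), rep("neg_control", n_control_wells)),
      se_id = c(paste0("SE", seq_len(n_se_wells)),
                rep(NA_character_, n_control_wells)),
      stringsAsFactors = FALSE)
    expressed <- gene_ids[base >= stats::median(base)]
    targets <- lapply(se_wells, function(w) {
      n_t <- stats::rpois(1, mean_targets_per_well)
      sample(expressed, min(n_t, length(expressed)))
    })
    names(targets) <- se_wells
    counts <- matrix(0L, n_genes, nrow(wells),
                     dimnames = list(gene_ids, wells$well))
    for (j in seq_len(nrow(wells))) {
      mu <- base
      w <- wells$well[j]
      if (wells$role[j] == "se" && length(targets[[w]])) {
        mu[targets[[w]]] <- mu[targets[[w]]] * 2^target_lfc
      }
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
    list(counts = counts, wells = wells,
         truth = list(targets = targets, target_lfc = target_lfc))
  })
}

#' Simulate a distance-decay Hi-C contact matrix with planted loops
#'
#' `count[i, j] ~ Poisson(scale * |i - j|^(-decay_exponent) * enrichment)`
#' for off-diagonal pairs, symmetric; the diagonal uses a fixed self-contact
#' scale (`scale * self_scale`). Loops are (bin_i, bin_j, enrichment >= 1)
#' rows multiplying the Poisson mean at those pairs.
#'
#' @param n_bins bins (default 400).
#' @param binsize bin width in bp (default 50000).
#' @param decay_exponent power-law exponent (> 0, default 1).
#' @param scale contact scale at distance 1 (default 100).
#' @param loops data.frame with `bin_i`, `bin_j` (1-based indices,
#'   `|i - j| >= 1`) and `enrichment` (>= 1); default none.
#' @param self_scale diagonal mean multiplier (default 4).
#' @param chrom chromosome name (default "chrS").
#' @param seed integer seed.
#' @return A list with `contacts` (a [contact_matrix()]) and `truth$loops`.
#' @export
simulate_contacts <- function(n_bins = 400, binsize = 50000,
                              decay_exponent = 1, scale = 100, loops = NULL,
                              self_scale = 4, chrom = "chrS", seed = 1) {
  if (decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (!is.null(loops) && nrow(loops)) {
    if (any(loops$enrichment < 1)) stop("loop enrichment must be >= 1")
    if (any(abs(loops$bin_i - loops$bin_j) < 1)) {
      stop("loops must join distinct bins (|i - j| >= 1)")
    }
  }
  withr::with_seed(seed, {
    d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
    mu <- scale * ifelse(d == 0, self_scale, d^(-decay_exponent))
    if (!is.null(loops) && nrow(loops)) {
      for (k in seq_len(nrow(loops))) {
        mu[loops$bin_i[k], loops$bin_j[k]] <-
          mu[loops$bin_i[k], loops$bin_j[k]] * loops$enrichment[k]
        mu[loops$bin_j[k], loops$bin_i[k]] <-
          mu[loops$bin_j[k], loops$bin_i[k]] * loops$enrichment[k]
      }
    }
    m <- matrix(0, n_bins, n_bins)
    ut <- upper.tri(m, diag = TRUE)
    m[ut] <- stats::rpois(sum(ut), mu[ut])
    m <- m + t(m) - diag(diag(m))
    list(contacts = contact_matrix(chrom, binsize, m),
         truth = list(loops = loops))
  })
}

#' Simulate a DE table around a planted target set
#'
#' Planted targets receive `LFC = planted value + Normal(0, lfc_noise_sd)`
#' and adjusted p below 0.0005; non-targets receive LFC around 0 and
#' adjusted p uniform on (0.1, 1). Base means are log-normal with a
#' configurable fraction of non-targets forced below 100 (unexpressed).
#'
#' @param genes all gene ids.
#' @param planted named numeric vector: planted target gene -> planted LFC.
#' @param lfc_noise_sd noise on planted LFCs (default 0.1).
#' @param frac_low_base fraction of non-targets with base mean < 100
#'   (default 0.2).
#' @param seed integer seed.
#' @return A DE table data.frame (`gene`, `log2fc`, `padj`, `base_mean`).
#' @export
simulate_de_table <- function(genes, planted = numeric(0),
                              lfc_noise_sd = 0.1, frac_low_base = 0.2,
                              seed = 1) {
  withr::with_seed(seed, {
    n <- length(genes)
    is_t <- genes %in% names(planted)
    log2fc <- stats::rnorm(n, 0, lfc_noise_sd)
    log2fc[is_t] <- planted[genes[is_t]] +
      stats::rnorm(sum(is_t), 0, lfc_noise_sd)
    padj <- stats::runif(n, 0.1, 1)
    padj[is_t] <- stats::runif(sum(is_t), 0, 0.00049)
    base_mean <- stats::rlnorm(n, log(500), 1)
    base_mean <- pmax(base_mean, 101)
    low <- sample(which(!is_t), floor(frac_low_base * sum(!is_t)))
    base_mean[low] <- stats::runif(length(low), 1, 99)
    data.frame(gene = genes, log2fc = log2fc, padj = padj,
               base_mean = base_mean, stringsAsFactors = FALSE)
  })
}
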