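# Shared fixtures and independent oracles used across the suite.

toy_genome <- function() genome_table(c("cA", "cB"), c(6e7, 5e7))

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# Independent OLS oracle: R's lm fit, coefficient table.
ols_oracle <- function(x, y) {
  fit <- summary(stats::lm(y ~ x))
  co <- fit$coefficients
  list(beta1 = co["x", "Estimate"], t = co["x", "t value"],
       p = co["x", "Pr(>|t|)"])
}

# Independent symmetric-scaling oracle for matrix balancing: plain
# alternating row/column normalisation of a symmetric matrix, taking the
# geometric mean of the two scalings each sweep (coded independently of the
# package's Knight-Ruiz and fallback implementations).
sinkhorn_oracle <- function(A, sweeps = 20000, tol = 1e-10) {
  d <- rep(1, nrow(A))
  for (i in seq_len(sweeps)) {
    r <- rowSums(A * outer(d, d))
    if (max(abs(r - 1)) < tol) break
    d <- d / sqrt(r)
  }
  d
}

# Brute-force finite-difference oracle for the rank cutoff: recompute the
# scaled curve and its derivative directly from definitions.
cutoff_oracle <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  dv <- vapply(seq_len(n), function(i) {
    lo <- max(i - 1, 1); hi <- min(i + 1, n)
    (y[hi] - y[lo]) / (x[hi] - x[lo])
  }, 0)
  s[which(dv > 1)[1]]
}

# Adjusted Rand index between two labelings (closed form from the
# contingency table).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab)); sum_b <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Fraction of a planted-truth interval set recovered by (>= 1 bp overlapped
# with) a called set, and count of called regions hitting no truth region.
recovery_stats <- function(called, truth) {
  hit_truth <- vapply(seq_len(nrow(truth)), function(i) {
    any(called$chrom == truth$chrom[i] &
          pmax(called$start, truth$start[i]) < pmin(called$end, truth$end[i]))
  }, TRUE)
  false_calls <- sum(!vapply(seq_len(nrow(called)), function(i) {
    any(truth$chrom == called$chrom[i] &
          pmax(truth$start, called$start[i]) < pmin(truth$end, called$end[i]))
  }, TRUE))
  list(recall = mean(hit_truth), false_calls = false_calls)
}
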