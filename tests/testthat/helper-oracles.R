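# Independent brute-force oracles used to cross-check the implementation.

# complement of covered intervals by per-base boolean mask (0-based half-open)
oracle_absent_mask <- function(len, starts, ends, min_len = 1) {
  covered <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  r <- rle(covered)
  pos <- cumsum(c(0, r$lengths))
  out <- data.frame(start = pos[-length(pos)][!r$values],
                    end = pos[-1][!r$values])
  out[out$end - out$start >= min_len, , drop = FALSE]
}

# presence by direct per-base counting on a depth vector
oracle_presence <- function(depth_by_base, min_cov, lost_cutoff) {
  as.integer(mean(depth_by_base >= min_cov) >= lost_cutoff)
}

# two-sided Fisher p by exhaustive enumeration of 2x2 tables with fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(n1, k)
  probs <- choose(n1, xs) * choose(n2, k - xs) / choose(n1 + n2, k)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up adjusted p-values, written out from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# PCA scores by covariance eigendecomposition (samples x genes input)
oracle_pca_scores <- function(mat_genes_by_samples) {
  X <- t(mat_genes_by_samples)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  Xc %*% ev$vectors
}

# exhaustive saturation means by direct subset enumeration
oracle_saturation_means <- function(v, k) {
  subs <- utils::combn(ncol(v), k)
  pan <- apply(subs, 2, function(s) sum(rowSums(v[, s, drop = FALSE]) > 0))
  core <- apply(subs, 2, function(s) sum(rowSums(v[, s, drop = FALSE]) == k))
  c(pan = mean(pan), core = mean(core))
}
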