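# Independent brute-force reference implementations used as oracles.
# These deliberately use naive loops and textbook formulas, not the
# package's code paths.

oracle_rank_desc <- function(s) {
  vapply(seq_along(s), function(i) {
    1 + sum(s > s[i]) + sum(s == s[i] & seq_along(s) != i) / 2
  }, numeric(1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) 0 else num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_rank_desc(-x), oracle_rank_desc(-y))
}

oracle_dcor <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a[i, j] <- abs(x[i] - x[j]); b[i, j] <- abs(y[i] - y[j])
  }
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- mean(A * B)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx == 0 || dvy == 0 || dcov2 <= 0) 0 else
    sqrt(dcov2 / sqrt(dvx * dvy))
}

# two-bin equal-frequency discretization: at or below the median vs above
oracle_bin2 <- function(x) ifelse(x <= quantile(x, 0.5, names = FALSE), 1L, 2L)

oracle_mi_binned <- function(bx, by) {
  n <- length(bx)
  mi <- 0
  for (u in unique(bx)) for (v in unique(by)) {
    pj <- sum(bx == u & by == v) / n
    if (pj > 0) mi <- mi + pj * log(pj / ((sum(bx == u) / n) * (sum(by == v) / n)))
  }
  max(0, mi)
}

oracle_clr <- function(M) {
  p <- nrow(M)
  Z <- matrix(0, p, p)
  for (i in 1:p) {
    bg <- M[i, -i]
    mu <- mean(bg)
    sdev <- sqrt(sum((bg - mu)^2) / (length(bg) - 1))
    for (j in 1:p) {
      if (sdev > 0) Z[i, j] <- max(0, (M[i, j] - mu) / sdev)
    }
  }
  S <- matrix(0, p, p)
  for (i in 1:p) for (j in 1:p) if (i != j)
    S[i, j] <- sqrt(Z[i, j]^2 + Z[j, i]^2)
  S
}

# MRMR objective of predictor subset S for target t
oracle_mrmr_objective <- function(M, t, S) {
  tot <- 0
  for (j in S) {
    red <- 0
    others <- setdiff(S, j)
    if (length(others)) red <- mean(M[j, others])
    tot <- tot + M[j, t] - red
  }
  tot
}

# exhaustive search over all non-empty predictor subsets
oracle_mrnetb_optimum <- function(M, t) {
  P <- setdiff(seq_len(nrow(M)), t)
  best <- -Inf
  for (k in seq_along(P)) {
    sets <- combn(P, k, simplify = FALSE)
    for (S in sets) {
      v <- oracle_mrmr_objective(M, t, S)
      if (v > best) best <- v
    }
  }
  best
}

oracle_truth_triples <- function(records) {
  r <- unique(records[, c("pmid", "mirna", "disease")])
  keys <- character(0)
  for (i in seq_len(nrow(r))) for (j in seq_len(nrow(r))) {
    if (i < j && r$pmid[i] == r$pmid[j] && r$disease[i] == r$disease[j] &&
        r$mirna[i] != r$mirna[j]) {
      m <- sort(c(r$mirna[i], r$mirna[j]))
      keys <- c(keys, paste(r$disease[i], m[1], m[2]))
    }
  }
  sort(unique(keys))
}

oracle_pr_sweep <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  do.call(rbind, lapply(thr, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = tp / (tp + fp), recall = tp / (tp + fn),
               fpr = fp / (fp + tn))
  }))
}
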