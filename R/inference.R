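#' Interaction score matrices
#'
#' All network-inference scorers return an `md_scores` object: an N x N
#' numeric matrix over the MD nodes where higher means a stronger predicted
#' interaction, plus the algorithm tag and a directedness flag. The diagonal
#' (self-loops) carries no meaning and is excluded downstream.
#'
#' @param algorithm Character tag.
#' @param scores N x N numeric matrix with node labels as dimnames.
#' @param directed `TRUE` when `scores[i, j]` (predictor i -> target j) and
#'   `scores[j, i]` may differ, as for the tree-ensemble scorer.
#' @return An object of class `md_scores`.
#' @export
md_scores <- function(algorithm, scores, directed = FALSE) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  structure(list(algorithm = algorithm, scores = scores, directed = directed),
            class = "md_scores")
}

#' @export
print.md_scores <- function(x, ...) {
  cat(sprintf("md_scores [%s]: %d nodes, %s\n", x$algorithm, nrow(x$scores),
              if (x$directed) "directed" else "symmetric"))
  invisible(x)
}

as_values <- function(matrix, missing = "zero_fill") {
  if (inherits(matrix, "md_matrix")) dense_values(matrix, missing)
  else dense_values(md_matrix(matrix), missing)
}

#' Correlation interaction scores
#'
#' Scores every node pair with the absolute Pearson or Spearman correlation
#' of their expression columns. Zero-variance columns (and pairs without
#' enough complete observations under the `pairwise_complete` policy) score
#' 0 against all partners.
#'
#' @param matrix An `md_matrix` (or plain matrix) with >= 3 rows.
#' @param method `"pearson"` or `"spearman"`.
#' @param missing Missing-cell policy, see [dense_values()].
#' @return A symmetric `md_scores` in `[0, 1]`.
#' @export
correlation_scores <- function(matrix, method = c("pearson", "spearman"),
                               missing = c("zero_fill",
                                           "pairwise_complete")) {
  method <- match.arg(method)
  missing <- match.arg(missing)
  v <- as_values(matrix, missing)
  if (nrow(v) < 3L) stopf("need >= 3 samples for correlation scoring")
  use <- if (missing == "pairwise_complete") "pairwise.complete.obs" else
    "everything"
  r <- suppressWarnings(abs(stats::cor(v, method = method, use = use)))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  md_scores(method, r, directed = FALSE)
}

# centered distance matrix of a single variable (Szekely's A_jk)
dcenter <- function(x) {
  d <- abs(outer(x, x, "-"))
  d - outer(rowMeans(d), rep(1, length(x))) -
    outer(rep(1, length(x)), colMeans(d)) + mean(d)
}

#' Distance-correlation interaction scores
#'
#' Sample distance correlation of every column pair, computed from
#' double-centered pairwise-distance matrices (V-statistic). Captures
#' non-linear and non-monotone dependence; values lie in `[0, 1]` and a
#' constant column scores 0 against all partners.
#'
#' @inheritParams correlation_scores
#' @return A symmetric `md_scores` in `[0, 1]`.
#' @export
distance_correlation_scores <- function(matrix,
                                        missing = c("zero_fill",
                                                    "pairwise_complete")) {
  missing <- match.arg(missing)
  if (missing == "pairwise_complete")
    stopf("distance correlation requires a complete matrix; use zero_fill")
  v <- as_values(matrix)
  n <- nrow(v); p <- ncol(v)
  if (n < 3L) stopf("need >= 3 samples for distance correlation")
  A <- lapply(seq_len(p), function(j) dcenter(v[, j]))
  dvar <- vapply(A, function(a) mean(a * a), numeric(1))
  s <- matrix(0, p, p, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(p - 1)) {
    if (dvar[i] == 0) next
    for (j in seq((i + 1), p)) {
      if (dvar[j] == 0) next
      dcov2 <- mean(A[[i]] * A[[j]])
      if (dcov2 > 0) s[i, j] <- s[j, i] <- sqrt(dcov2 / sqrt(dvar[i] * dvar[j]))
    }
  }
  md_scores("dcor", s, directed = FALSE)
}

# equal-frequency discretization; heavy ties collapse bins rather than being
# split across them, so a constant column lands in a single bin
equal_freq_bin <- function(x, bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

plugin_mi <- function(bx, by) {
  tab <- table(bx, by)
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pr, pc)[nz]))
  max(0, mi)
}

#' Mutual-information matrix
#'
#' Empirical (maximum-likelihood plug-in) mutual information in nats between
#' every column pair after equal-frequency discretization. The diagonal
#' holds each column's entropy (MI of a variable with itself). Feeds the CLR
#' and MRNETB scorers.
#'
#' @inheritParams correlation_scores
#' @param bins Number of equal-frequency bins; default
#'   `max(2, floor(sqrt(n_samples)))`. Must be between 2 and the sample
#'   count.
#' @return A symmetric `md_scores` (algorithm `"mi"`) with nonnegative
#'   entries.
#' @export
mutual_information_matrix <- function(matrix, bins = NULL) {
  v <- as_values(matrix)
  m <- nrow(v); p <- ncol(v)
  if (is.null(bins)) bins <- max(2L, floor(sqrt(m)))
  if (bins < 2L || bins > m) stopf("bins must lie in [2, n_samples]")
  B <- vapply(seq_len(p), function(j) equal_freq_bin(v[, j], bins),
              integer(m))
  s <- matrix(0, p, p, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(p)) {
    for (j in i:p) {
      s[i, j] <- s[j, i] <- plugin_mi(B[, i], B[, j])
    }
  }
  md_scores("mi", s, directed = FALSE)
}

#' Context-likelihood-of-relatedness (CLR) scores
#'
#' Corrects a mutual-information matrix for each node's background MI
#' distribution: over row i's off-diagonal entries, `z_i = max(0,
#' (MI_ij - mean_i) / sd_i)` (0 when the row background has zero spread),
#' and the edge score combines both contexts as `sqrt(z_i^2 + z_j^2)`.
#'
#' @param mi A symmetric nonnegative `md_scores` from
#'   [mutual_information_matrix()].
#' @return A symmetric `md_scores` (algorithm `"clr"`).
#' @export
clr_scores <- function(mi) {
  M <- if (inherits(mi, "md_scores")) mi$scores else mi
  p <- nrow(M)
  if (p < 2L) stopf("need >= 2 nodes")
  Z <- matrix(0, p, p)
  for (i in seq_len(p)) {
    bg <- M[i, -i]
    mu <- mean(bg); sdev <- stats::sd(bg)
    if (is.finite(sdev) && sdev > 0) Z[i, ] <- pmax(0, (M[i, ] - mu) / sdev)
  }
  s <- sqrt(Z^2 + t(Z)^2)
  diag(s) <- 0
  dimnames(s) <- dimnames(M)
  md_scores("clr", s, directed = FALSE)
}

# MRMR objective of predictor set S for target rel/red values:
# sum_j [ rel_j - mean_{k in S, k != j} M[j, k] ]
mrnetb_objective <- function(rel, redsum, s) {
  if (s == 1L) return(sum(rel))
  sum(rel - redsum / (s - 1))
}

mrnetb_target <- function(M, t) {
  p <- nrow(M)
  P <- setdiff(seq_len(p), t)
  S <- P
  rel <- M[S, t]

  redsums <- function(S) {
    if (length(S) == 1L) return(stats::setNames(0, S))
    rowSums(M[S, S, drop = FALSE]) - diag(M)[S]
  }
  redsum <- redsums(S)

  repeat {
    moved <- FALSE
    # backward elimination: drop the variable whose removal most improves
    # the subset objective
    while (length(S) > 1L) {
      s <- length(S)
      R <- sum(rel); T <- sum(redsum)
      cur <- R - T / (s - 1)
      wo <- if (s == 2L) rev(rel) else (R - rel) - (T - 2 * redsum) / (s - 2)
      best <- which.max(wo)
      if (wo[best] <= cur + 1e-12) break
      r <- S[best]
      keep <- S != r
      redsum <- redsum[keep] - M[S[keep], r]
      S <- S[keep]
      rel <- M[S, t]
      moved <- TRUE
    }
    # sequential replacement: swap a selected variable for an unselected
    # one, or re-admit an eliminated one, while the objective improves
    A <- setdiff(P, S)
    if (length(A)) {
      s <- length(S)
      R <- sum(rel); T <- sum(redsum)
      cur <- mrnetb_objective(rel, redsum, s)
      best_gain <- 1e-12; best_S <- NULL
      cs <- colSums(M[S, A, drop = FALSE])  # sum over k in S of M[k, a]
      rel_a <- M[A, t]
      for (ri in seq_along(S)) {
        r <- S[ri]
        if (s == 1L) {
          obj <- rel_a
        } else {
          cross <- cs - M[r, A]
          obj <- (R - rel[ri] + rel_a) -
            (T - 2 * redsum[ri] + 2 * cross) / (s - 1)
        }
        ai <- which.max(obj)
        if (obj[ai] - cur > best_gain) {
          best_gain <- obj[ai] - cur
          best_S <- c(setdiff(S, r), A[ai])
        }
      }
      obj_add <- (R + rel_a) - (T + 2 * cs) / s
      ai <- which.max(obj_add)
      if (obj_add[ai] - cur > best_gain) {
        best_gain <- obj_add[ai] - cur
        best_S <- c(S, A[ai])
      }
      if (!is.null(best_S)) {
        S <- best_S
        rel <- M[S, t]
        redsum <- redsums(S)
        moved <- TRUE
      }
    }
    if (!moved) break
  }

  s <- length(S)
  u <- if (s == 1L) rel else rel - redsum / (s - 1)
  # raw per-variable objectives of the selected subset; clamping to a
  # nonnegative score happens at the matrix level
  out <- numeric(p)
  out[S] <- u
  out
}

#' Maximum-relevance minimum-redundancy backward (MRNETB) scores
#'
#' For each target node, selects the predictor subset maximizing the MRMR
#' objective (sum over selected predictors of their MI with the target minus
#' their mean MI with the other selected predictors) by backward elimination
#' followed by sequential replacement. A selected predictor's edge score is
#' its MRMR objective value in the final subset, clamped at 0; unselected
#' predictors score 0. The two directions are symmetrized by their
#' elementwise maximum.
#'
#' @inheritParams clr_scores
#' @return A symmetric `md_scores` (algorithm `"mrnetb"`).
#' @export
mrnetb_scores <- function(mi) {
  M <- if (inherits(mi, "md_scores")) mi$scores else mi
  p <- nrow(M)
  if (p < 2L) stopf("need >= 2 nodes")
  W <- vapply(seq_len(p), function(t) mrnetb_target(M, t), numeric(p))
  W[W < 0] <- 0
  W <- pmax(W, t(W))
  diag(W) <- 0
  dimnames(W) <- dimnames(M)
  md_scores("mrnetb", W, directed = FALSE)
}

#' Tree-ensemble (GENIE3-style) interaction scores
#'
#' For each target column, fits a randomized regression-forest of all other
#' columns and reads each predictor's total variance-reduction importance as
#' the directed predictor-to-target edge score, normalized to sum to 1 per
#' target (a zero-variance target keeps all-zero importances). The same seed
#' reproduces the same score matrix.
#'
#' @inheritParams correlation_scores
#' @param n_trees Trees per target ensemble.
#' @param k_candidates Candidate predictors per split: `"sqrt"` (square root
#'   of the predictor count, the usual random-forest default) or an integer.
#' @param seed Integer seed; per-target seeds are derived from it.
#' @return A directed `md_scores` (algorithm `"genie3"`), `scores[i, j]` =
#'   importance of predictor i for target j.
#' @export
genie3_scores <- function(matrix, n_trees = 100L, k_candidates = "sqrt",
                          seed = 1L) {
  v <- as_values(matrix)
  n <- nrow(v); p <- ncol(v)
  if (n < 5L) stopf("need >= 5 samples for tree-ensemble scoring")
  if (p < 2L) stopf("need >= 2 nodes")
  s <- matrix(0, p, p, dimnames = list(colnames(v), colnames(v)))
  for (j in seq_len(p)) {
    y <- v[, j]
    if (stats::sd(y) == 0) next
    X <- v[, -j, drop = FALSE]
    mtry <- if (identical(k_candidates, "sqrt"))
      max(1L, floor(sqrt(ncol(X)))) else as.integer(k_candidates)
    set.seed(seed + j)
    rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                     mtry = mtry)
    imp <- rf$importance[, "IncNodePurity"]
    tot <- sum(imp)
    if (tot > 0) imp <- imp / tot
    s[-j, j] <- imp
  }
  md_scores("genie3", s, directed = TRUE)
}

#' Run a set of network-inference algorithms
#'
#' Applies the requested scorers to one expression matrix and returns their
#' `md_scores` objects. The mutual-information matrix is computed once and
#' shared by the CLR and MRNETB scorers.
#'
#' @inheritParams correlation_scores
#' @param algorithms Subset of `c("clr", "mrnetb", "pearson", "spearman",
#'   "dcor", "genie3")`.
#' @param seed Seed for the tree-ensemble scorer.
#' @param n_trees,k_candidates Passed to [genie3_scores()].
#' @param bins Passed to [mutual_information_matrix()].
#' @return Named list of `md_scores`, one per algorithm.
#' @export
infer_scores <- function(matrix,
                         algorithms = c("clr", "mrnetb", "pearson",
                                        "spearman", "dcor", "genie3"),
                         seed = 1L, n_trees = 100L, k_candidates = "sqrt",
                         bins = NULL,
                         missing = c("zero_fill", "pairwise_complete")) {
  missing <- match.arg(missing)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  out <- list()
  mi <- NULL
  if (any(c("clr", "mrnetb") %in% algorithms)) {
    mi <- mutual_information_matrix(matrix, bins = bins)
  }
  for (alg in algorithms) {
    out[[alg]] <- switch(
      alg,
      pearson = correlation_scores(matrix, "pearson", missing = missing),
      spearman = correlation_scores(matrix, "spearman", missing = missing),
      dcor = distance_correlation_scores(matrix),
      clr = clr_scores(mi),
      mrnetb = mrnetb_scores(mi),
      genie3 = genie3_scores(matrix, n_trees = n_trees,
                             k_candidates = k_candidates, seed = seed)
    )
  }
  out
}
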