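test_that("correlation scorers recover perfect linear and monotone trends", {
  x <- c(1, 2, 3, 4, 5)
  m <- md_matrix(cbind(a = x, b = 2 * x + 1, c = x^3))
  pe <- correlation_scores(m, "pearson")$scores
  sp <- correlation_scores(m, "spearman")$scores
  expect_equal(pe["a", "b"], 1)
  expect_equal(sp["a", "c"], 1)
  expect_lt(pe["a", "c"], 1)
  expect_error(correlation_scores(md_matrix(m$values[1:2, ])), ">= 3")
})

test_that("correlation matrices match direct formula evaluation", {
  set.seed(7)
  v <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  v <- cbind(v, d = rep(2, 4))  # zero-variance column scores 0
  pe <- correlation_scores(md_matrix(v), "pearson")$scores
  sp <- correlation_scores(md_matrix(v), "spearman")$scores
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    expect_equal(pe[i, j], abs(oracle_pearson(v[, i], v[, j])))
    expect_equal(sp[i, j], abs(oracle_spearman(v[, i], v[, j])))
  }
})

test_that("distance correlation equals the double-centering definition", {
  set.seed(8)
  v <- cbind(x = rnorm(6), y = rnorm(6), z = rnorm(6)^2)
  dc <- distance_correlation_scores(md_matrix(v))$scores
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(dc[i, j], oracle_dcor(v[, i], v[, j]), tolerance = 1e-12)
  }
  # identical variables -> 1; constant column -> 0
  w <- cbind(x = v[, 1], same = v[, 1], const = rep(3, 6))
  dc <- distance_correlation_scores(md_matrix(w))$scores
  expect_equal(dc["x", "same"], 1)
  expect_equal(dc["x", "const"], 0)
})

test_that("plug-in mutual information matches hand-tabulated values", {
  # perfectly dependent two-bin variables: MI = ln 2
  m <- md_matrix(cbind(p = c(1, 1, 1, 1, 2, 2, 2, 2),
                       q = c(5, 5, 5, 5, 9, 9, 9, 9)))
  mi <- mutual_information_matrix(m, bins = 2)$scores
  expect_equal(mi["p", "q"], log(2))
  # diagonal is each column's entropy
  expect_equal(mi["p", "p"], log(2))
  # 8-sample toy against the contingency-table oracle
  set.seed(9)
  v <- matrix(rnorm(24), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  mi <- mutual_information_matrix(md_matrix(v), bins = 2)$scores
  for (i in 1:3) for (j in 1:3) {
    expect_equal(mi[i, j],
                 oracle_mi_binned(oracle_bin2(v[, i]), oracle_bin2(v[, j])))
  }
  expect_error(mutual_information_matrix(md_matrix(v), bins = 20), "bins")
})

test_that("independent columns have near-zero MI at large sample size", {
  # with b bins the plug-in estimator's bias is about (b - 1)^2 / (2n),
  # so test the independence limit at fixed bin count
  set.seed(10)
  v <- cbind(a = rnorm(2000), b = rnorm(2000))
  mi <- mutual_information_matrix(md_matrix(v), bins = 4)$scores
  expect_lt(mi["a", "b"], 0.05)
})

test_that("CLR z-scoring matches brute-force row background correction", {
  M <- random_scores_matrix(13, 4)
  diag(M) <- 2  # entropy-like diagonal must not leak into backgrounds
  clr <- clr_scores(md_scores("mi", M))$scores
  expect_equal(unname(clr), oracle_clr(M), tolerance = 1e-12)
  expect_equal(clr, t(clr))
  # flat off-diagonal background -> all scores zero
  flat <- matrix(0.4, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(clr_scores(md_scores("mi", flat))$scores == 0))
})

# MI-like matrix with a target (last variable) whose best predictor x1 has
# a redundant near-duplicate x2 and a weakly relevant x3
mrnetb_duplicate_matrix <- function() {
  M <- matrix(c(2.0, 1.5, 0.2, 0.90,
                1.5, 2.0, 0.2, 0.85,
                0.2, 0.2, 2.0, 0.30,
                0.90, 0.85, 0.30, 2.0), 4, 4,
              dimnames = rep(list(c("x1", "x2", "x3", "t")), 2))
  M
}

test_that("MRNETB reduces to MI for two variables and demotes duplicates", {
  M <- matrix(c(1, 0.7, 0.7, 0.9), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(mrnetb_scores(md_scores("mi", M))$scores["x", "y"], 0.7)
  # the redundant near-duplicate is eliminated and scores strictly below
  # the variable it copies
  M <- mrnetb_duplicate_matrix()
  w <- mrnetb_scores(md_scores("mi", M))$scores
  expect_lt(w["x2", "t"], w["x1", "t"])
  expect_equal(w["x1", "t"], 0.9)  # selected alone: objective = relevance
})

test_that("MRNETB search improves on the full set and is bounded by the optimum", {
  # the selection problem is NP-hard and backward search is a heuristic:
  # its objective always improves monotonically from the full predictor
  # set and can never exceed the exhaustive-subset optimum
  for (seed in 1:10) {
    p <- sample(3:5, 1)
    set.seed(seed)
    v <- matrix(rnorm(12 * p), 12, p)
    v[, p] <- v[, 1] + rnorm(12, 0, 0.5)
    M <- mutual_information_matrix(md_matrix(v))$scores
    for (t in seq_len(p)) {
      S <- which(mircons:::mrnetb_target(M, t) != 0)
      got <- oracle_mrmr_objective(M, t, S)
      expect_gte(got, oracle_mrmr_objective(M, t, setdiff(seq_len(p), t)))
      expect_lte(got, oracle_mrnetb_optimum(M, t) + 1e-10)
    }
  }
  # on structured instances the search does attain the optimum
  M <- mrnetb_duplicate_matrix()
  S <- which(mircons:::mrnetb_target(M, 4) != 0)
  expect_equal(oracle_mrmr_objective(M, 4, S), oracle_mrnetb_optimum(M, 4))
  expect_equal(S, 1L)  # the dominant predictor alone
  # complementary (non-redundant) predictors are kept together
  M2 <- matrix(c(1.0, 0.1, 0.6,
                 0.1, 1.0, 0.5,
                 0.6, 0.5, 1.0), 3, 3)
  S2 <- which(mircons:::mrnetb_target(M2, 3) != 0)
  expect_equal(oracle_mrmr_objective(M2, 3, S2), oracle_mrnetb_optimum(M2, 3))
  expect_equal(S2, c(1L, 2L))
})

test_that("tree-ensemble scores are normalized, directed and seeded", {
  set.seed(15)
  x1 <- rnorm(60); x2 <- rnorm(60); x3 <- x1 + rnorm(60, 0, 0.3)
  v <- cbind(x1 = x1, x2 = x2, x3 = x3, flat = rep(1, 60))
  g1 <- genie3_scores(md_matrix(v), seed = 4)
  expect_true(g1$directed)
  # per-target importances sum to 1, or 0 for the degenerate target
  sums <- colSums(g1$scores)
  expect_equal(unname(sums[c("x1", "x2", "x3")]), rep(1, 3))
  expect_equal(unname(sums["flat"]), 0)
  # the planted parent out-scores the independent noise column
  expect_gt(g1$scores["x1", "x3"], g1$scores["x2", "x3"])
  # identical seed reproduces; different seed is allowed to differ
  g2 <- genie3_scores(md_matrix(v), seed = 4)
  expect_identical(g1$scores, g2$scores)
  expect_error(genie3_scores(md_matrix(v[1:4, ])), ">= 5")
})

test_that("scorers are invariant to column permutation", {
  set.seed(16)
  v <- matrix(rnorm(80), 16, 5, dimnames = list(NULL, letters[1:5]))
  perm <- c(3, 5, 1, 4, 2)
  for (f in list(function(m) correlation_scores(m, "pearson")$scores,
                 function(m) correlation_scores(m, "spearman")$scores,
                 function(m) distance_correlation_scores(m)$scores,
                 function(m) mutual_information_matrix(m, bins = 3)$scores,
                 function(m) clr_scores(mutual_information_matrix(m, bins = 3))$scores,
                 function(m) mrnetb_scores(mutual_information_matrix(m, bins = 3))$scores)) {
    s <- f(md_matrix(v))
    sp <- f(md_matrix(v[, perm]))
    expect_equal(sp, s[perm, perm])
    expect_equal(sp, t(sp))  # symmetric scorers
  }
})

test_that("rank-based scorers ignore positive affine rescaling of a column", {
  set.seed(17)
  v <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, letters[1:5]))
  w <- v; w[, 2] <- 10 * w[, 2] + 3
  expect_equal(correlation_scores(md_matrix(w), "spearman")$scores,
               correlation_scores(md_matrix(v), "spearman")$scores)
  expect_equal(mutual_information_matrix(md_matrix(w), bins = 3)$scores,
               mutual_information_matrix(md_matrix(v), bins = 3)$scores)
  expect_equal(distance_correlation_scores(md_matrix(w))$scores,
               distance_correlation_scores(md_matrix(v))$scores,
               tolerance = 1e-10)
})
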