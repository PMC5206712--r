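#' Rank all interactions of one score matrix
#'
#' Extracts every ordered node pair (both orientations, self-loops excluded)
#' from a score matrix and ranks them in descending score order; equal
#' scores receive the average of the rank positions they span.
#'
#' @param scores An `md_scores` object.
#' @return A `ranked_list`: data.frame with columns `edge` (the id
#'   `"i->j"` over node indices), `from`, `to` (node indices) and `rank`,
#'   with the algorithm tag as attribute `"algorithm"`.
#' @export
rank_edges <- function(scores) {
  stopifnot(inherits(scores, "md_scores"))
  p <- nrow(scores$scores)
  idx <- which(row(scores$scores) != col(scores$scores))
  from <- row(scores$scores)[idx]
  to <- col(scores$scores)[idx]
  s <- scores$scores[idx]
  if (any(!is.finite(s))) stopf("scores must be finite")
  ranked_list(edges = edge_id(from, to),
              ranks = rank(-s, ties.method = "average"),
              algorithm = scores$algorithm, from = from, to = to)
}

#' Construct a ranked prediction list
#'
#' A ranked list assigns each interaction a positive rank, 1 = strongest
#' prediction, with ties carrying fractional average ranks. Lists are
#' usually produced by [rank_edges()]; this constructor also lets published
#' ranking orders be entered directly.
#'
#' @param edges Character vector of interaction identifiers.
#' @param ranks Numeric ranks (1 = best; average ranks on ties).
#' @param algorithm Name tag of the ranking algorithm.
#' @param from,to Optional integer node indices per edge.
#' @return A `ranked_list` data.frame.
#' @examples
#' ranked_list(c("I1", "I2", "I3"), c(2, 1, 3), "alg-1")
#' @export
ranked_list <- function(edges, ranks, algorithm = "unnamed",
                        from = NA_integer_, to = NA_integer_) {
  stopifnot(length(edges) == length(ranks))
  if (anyDuplicated(edges)) stopf("duplicate edge identifiers")
  ranks <- as.numeric(ranks)
  n <- length(ranks)
  if (any(!is.finite(ranks)) || any(ranks < 1) ||
      abs(sum(ranks) - n * (n + 1) / 2) > 1e-8 * max(1, n^2)) {
    stopf("ranks must cover 1..N with ties averaged")
  }
  out <- data.frame(edge = as.character(edges), from = from, to = to,
                    rank = ranks, stringsAsFactors = FALSE)
  attr(out, "algorithm") <- algorithm
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Normalized Borda rank
#'
#' Rank r among n candidates earns `n - r` Borda points (rank 1 gets the
#' maximum, `n - 1`; the last rank gets 0); normalizing by `n - 1` maps
#' every rank into `[0, 1]`. A single candidate scores 1 by convention.
#' Fractional (tied) ranks earn fractional points.
#'
#' @param ranks Numeric rank(s), 1 = best.
#' @param n Number of ranked candidates.
#' @return Normalized Borda rank(s) in `[0, 1]`.
#' @examples
#' borda_normalize(1:4, 4)  # 1, 2/3, 1/3, 0
#' @export
borda_normalize <- function(ranks, n) {
  if (n < 1) stopf("n must be >= 1")
  if (n == 1) return(rep(1, length(ranks)))
  (n - ranks) / (n - 1)
}

#' Borda-count consensus over several ranked lists
#'
#' Fuses K per-algorithm ranked lists over one common interaction set into a
#' single confidence score per interaction: each list's ranks are converted
#' to normalized Borda ranks and the K values are averaged, so an
#' interaction ranked first everywhere scores 1 and one ranked last
#' everywhere scores 0.
#'
#' Two arithmetic modes are supported. `exact` keeps full precision.
#' `paper_truncated` truncates every normalized Borda rank, and the final
#' average, to two decimals — the display arithmetic used in published
#' worked examples of this consensus scheme (where 2/3 enters the average
#' as 0.66, so four candidates ranked (1,3,4,2,2,3) average to 0.49 rather
#' than the exact 0.50).
#'
#' @param ranked A list of `ranked_list` objects covering the identical
#'   edge set.
#' @param mode `"exact"` or `"paper_truncated"`.
#' @return An `md_consensus` data.frame with columns `edge`, `from`, `to`
#'   and `final_rank` (in `[0, 1]`), sorted by decreasing `final_rank`;
#'   attributes `k` (number of fused lists), `mode` and `algorithms`.
#' @export
average_rank_consensus <- function(ranked, mode = c("exact",
                                                    "paper_truncated")) {
  mode <- match.arg(mode)
  if (!length(ranked)) stopf("need at least one ranked list")
  ref <- ranked[[1]]
  n <- nrow(ref)
  borda <- matrix(0, nrow = n, ncol = length(ranked))
  for (k in seq_along(ranked)) {
    rl <- ranked[[k]]
    if (nrow(rl) != n || !setequal(rl$edge, ref$edge))
      stopf("ranked lists cover different edge sets")
    b <- borda_normalize(rl$rank[match(ref$edge, rl$edge)], n)
    if (mode == "paper_truncated") b <- trunc2(b)
    borda[, k] <- b
  }
  final <- rowMeans(borda)
  if (mode == "paper_truncated") final <- trunc2(final)
  out <- data.frame(edge = ref$edge, from = ref$from, to = ref$to,
                    final_rank = final, stringsAsFactors = FALSE)
  out <- out[order(-out$final_rank, out$edge), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- length(ranked)
  attr(out, "mode") <- mode
  attr(out, "algorithms") <- vapply(ranked, attr, character(1), "algorithm")
  class(out) <- c("md_consensus", "data.frame")
  out
}

#' Size of the ordered interaction space
#'
#' Number of ordered MD-MD pairs over `n_nodes` nodes (self-pairs included),
#' i.e. `n_nodes^2`, computed without materializing any matrix. With the
#' 4,343 MD nodes of a full curated fold-change compendium this is
#' 18,861,649 potential interactions.
#'
#' @param n_nodes Node count.
#' @return `n_nodes^2` as a double.
#' @export
interaction_space_size <- function(n_nodes) {
  as.numeric(n_nodes)^2
}

#' Human-readable consensus listing
#'
#' Formats consensus output as a ranked table of
#' `"disease:miRNA => disease:miRNA"` interactions with their confidence
#' scores.
#'
#' @param consensus An `md_consensus` whose edges carry node indices.
#' @param dataset The `md_dataset` providing node labels.
#' @param top_n Rows to keep (default all).
#' @return data.frame with columns `rank`, `interaction`, `score`.
#' @export
consensus_table <- function(consensus, dataset, top_n = nrow(consensus)) {
  stopifnot(inherits(consensus, "md_consensus"))
  lab <- dataset$nodes$label
  n <- min(top_n, nrow(consensus))
  data.frame(
    rank = seq_len(n),
    interaction = paste(lab[consensus$from[seq_len(n)]],
                        lab[consensus$to[seq_len(n)]], sep = " => "),
    score = consensus$final_rank[seq_len(n)],
    stringsAsFactors = FALSE
  )
}
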