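#' Build the PMID co-citation truth network
#'
#' A same-disease miRNA pair counts as literature-validated when at least
#' one single PubMed ID carries records associating both miRNAs with that
#' disease. Records are first deduplicated by (pmid, mirna, disease); all
#' other same-disease pairs are unverified (label 0), which may simply mean
#' the pair has not been studied yet.
#'
#' @param data An `md_dataset` whose records carry PMIDs.
#' @return An object of class `md_truth`: list with `triples` (data.frame
#'   `mirna_a`, `mirna_b`, `disease`; miRNAs in sorted order) and `keys`
#'   (character set `disease || pair`).
#' @export
build_truth_network <- function(data) {
  r <- unique(data$records[, c("pmid", "mirna", "disease")])
  grp <- split(r$mirna, paste(r$pmid, r$disease, sep = "\r"))
  dis <- sub("^.*\r", "", names(grp))
  triples <- list()
  for (g in seq_along(grp)) {
    ms <- sort(unique(grp[[g]]))
    if (length(ms) < 2L) next
    pairs <- utils::combn(ms, 2L)
    triples[[length(triples) + 1L]] <- data.frame(
      mirna_a = pairs[1, ], mirna_b = pairs[2, ], disease = dis[g],
      stringsAsFactors = FALSE)
  }
  tr <- if (length(triples)) unique(do.call(rbind, triples)) else
    data.frame(mirna_a = character(), mirna_b = character(),
               disease = character(), stringsAsFactors = FALSE)
  rownames(tr) <- NULL
  structure(list(triples = tr,
                 keys = paste(tr$disease, pair_key(tr$mirna_a, tr$mirna_b),
                              sep = "\r")),
            class = "md_truth")
}

#' @export
print.md_truth <- function(x, ...) {
  cat(sprintf("md_truth: %d co-cited miRNA-pair/disease triples\n",
              nrow(x$triples)))
  invisible(x)
}

#' Keep only consensus edges of given interaction types
#'
#' @param consensus An `md_consensus` with node indices.
#' @param dataset The `md_dataset` providing node identities.
#' @param types Integer type codes to keep (see [classify_edge_type()]);
#'   default 3, the same-disease different-miRNA edges used for
#'   disease-specific analysis.
#' @return The filtered `md_consensus`.
#' @export
filter_edges_by_type <- function(consensus, dataset, types = 3L) {
  ty <- edge_types(consensus, dataset)
  out <- consensus[ty %in% types, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("k", "mode", "algorithms"))
    attr(out, a) <- attr(consensus, a)
  class(out) <- class(consensus)
  out
}

#' Label consensus edges against the truth network
#'
#' Each edge must be a type-3 (same-disease, different-miRNA) interaction;
#' it is labeled 1 when its miRNA pair and disease form a validated triple,
#' 0 otherwise.
#'
#' @param consensus A type-3-only `md_consensus` (see
#'   [filter_edges_by_type()]).
#' @param dataset The `md_dataset` providing node identities.
#' @param truth An `md_truth` from [build_truth_network()].
#' @return Integer vector of 0/1 labels aligned with `consensus` rows.
#' @export
label_edges <- function(consensus, dataset, truth) {
  ty <- edge_types(consensus, dataset)
  if (any(ty != 3L))
    stopf("labeling is defined for type-3 edges only; filter first")
  a <- dataset$nodes[consensus$from, ]
  b <- dataset$nodes[consensus$to, ]
  keys <- paste(a$disease, pair_key(a$mirna, b$mirna), sep = "\r")
  as.integer(keys %in% truth$keys)
}

#' Precision-recall and ROC sweep
#'
#' Sweeps every distinct score as a classification threshold (descending;
#' predictions at or above the threshold are positive) and reports the
#' confusion counts, precision, recall and false-positive rate at each,
#' plus trapezoidal areas under the ROC and precision-recall curves.
#'
#' @param scores Numeric prediction scores, higher = more confident.
#' @param labels 0/1 truth labels aligned with `scores`; both classes must
#'   be present.
#' @return A `pr_curve` data.frame with columns `threshold`, `tp`, `fp`,
#'   `fn`, `tn`, `precision`, `recall`, `fpr`; attributes `auroc` and
#'   `aupr`.
#' @export
precision_recall_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stopf("need at least one positive and one negative label")
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  cum_tp <- cumsum(l)
  cum_fp <- cumsum(1L - l)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each threshold
  thr <- s[last]
  tp <- cum_tp[last]; fp <- cum_fp[last]
  fn <- P - tp; tn <- N - fp
  out <- data.frame(threshold = thr, tp = tp, fp = fp, fn = fn, tn = tn,
                    precision = tp / (tp + fp), recall = tp / P,
                    fpr = fp / N)
  rownames(out) <- NULL
  roc_x <- c(0, out$fpr, 1); roc_y <- c(0, out$recall, 1)
  attr(out, "auroc") <- sum(diff(roc_x) * (roc_y[-1] + roc_y[-length(roc_y)]) / 2)
  pr_x <- c(0, out$recall); pr_y <- c(out$precision[1], out$precision)
  attr(out, "aupr") <- sum(diff(pr_x) * (pr_y[-1] + pr_y[-length(pr_y)]) / 2)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Area summaries of a precision-recall sweep
#'
#' @param curve A `pr_curve`.
#' @return Named numeric vector with `auroc` and `aupr`.
#' @export
curve_areas <- function(curve) {
  c(auroc = attr(curve, "auroc"), aupr = attr(curve, "aupr"))
}
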