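#' Classify an MD-MD edge by its endpoint identities
#'
#' Four interaction types arise between two (miRNA, disease) nodes:
#' \tabular{lll}{
#'   1 \tab same miRNA, same disease \tab self-loop, not analysed \cr
#'   2 \tab same miRNA, different disease \tab present in results \cr
#'   3 \tab different miRNA, same disease \tab used for disease analysis \cr
#'   4 \tab different miRNA, different disease \tab present in results
#' }
#'
#' @param mirna_a,disease_a,mirna_b,disease_b Endpoint identities
#'   (vectorized).
#' @return Integer type codes in 1..4.
#' @examples
#' classify_edge_type("m1", "d1", "m2", "d1")  # 3
#' @export
classify_edge_type <- function(mirna_a, disease_a, mirna_b, disease_b) {
  same_m <- mirna_a == mirna_b
  same_d <- disease_a == disease_b
  ifelse(same_m, ifelse(same_d, 1L, 2L), ifelse(same_d, 3L, 4L))
}

#' Edge types of a consensus result
#'
#' @param consensus An `md_consensus` carrying node indices.
#' @param dataset The `md_dataset` providing node identities.
#' @return Integer vector of type codes aligned with `consensus` rows.
#' @export
edge_types <- function(consensus, dataset) {
  a <- dataset$nodes[consensus$from, ]
  b <- dataset$nodes[consensus$to, ]
  classify_edge_type(a$mirna, a$disease, b$mirna, b$disease)
}

#' Build a disease-specific miRNA interaction network (DMIN)
#'
#' Collects the type-3 consensus edges of one disease whose confidence
#' (final consensus rank) passes the filter, collapsing the two directed
#' orientations of each miRNA pair into one undirected edge weighted by the
#' larger of the two confidences. The default filter is the explicit
#' confidence threshold 0.9; alternatively `top_fraction` keeps the highest
#' scoring fraction of the full consensus edge set (the threshold is then
#' the corresponding confidence quantile), since the top decile of a
#' consensus run typically corresponds to confidence about 0.9 and above.
#'
#' @param consensus An `md_consensus` with node indices.
#' @param dataset The `md_dataset` providing node identities.
#' @param disease Disease name (normalized as in the dataset).
#' @param min_confidence Minimum confidence weight, default 0.9.
#' @param top_fraction If non-`NULL`, overrides `min_confidence` with the
#'   `1 - top_fraction` quantile of all consensus confidences.
#' @return An object of class `dmin`: list with `disease`, `edges`
#'   (data.frame `mirna_a`, `mirna_b`, `weight`; miRNAs sorted within each
#'   pair), `vertices` (endpoint union) and `min_confidence` (the applied
#'   threshold). Unknown diseases yield an empty network with a warning.
#' @export
build_dmin <- function(consensus, dataset, disease, min_confidence = 0.9,
                       top_fraction = NULL) {
  stopifnot(inherits(consensus, "md_consensus"))
  if (!is.null(top_fraction)) {
    min_confidence <- stats::quantile(consensus$final_rank,
                                      probs = 1 - top_fraction,
                                      names = FALSE, type = 7)
  }
  if (!disease %in% dataset$nodes$disease)
    warning(sprintf("disease '%s' not present in dataset", disease))
  ty <- edge_types(consensus, dataset)
  a <- dataset$nodes[consensus$from, ]
  keep <- ty == 3L & a$disease == disease &
    consensus$final_rank >= min_confidence
  sub <- consensus[keep, , drop = FALSE]
  if (nrow(sub)) {
    ma <- dataset$nodes$mirna[sub$from]
    mb <- dataset$nodes$mirna[sub$to]
    lo <- pmin(ma, mb); hi <- pmax(ma, mb)
    w <- tapply(sub$final_rank, paste(lo, hi, sep = "||"), max)
    parts <- strsplit(names(w), "||", fixed = TRUE)
    edges <- data.frame(mirna_a = vapply(parts, `[`, character(1), 1L),
                        mirna_b = vapply(parts, `[`, character(1), 2L),
                        weight = as.numeric(w), stringsAsFactors = FALSE)
    edges <- edges[order(-edges$weight, edges$mirna_a, edges$mirna_b), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(mirna_a = character(), mirna_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(disease = disease, edges = edges,
                 vertices = sort(unique(c(edges$mirna_a, edges$mirna_b))),
                 min_confidence = min_confidence),
            class = "dmin")
}

#' @export
print.dmin <- function(x, ...) {
  cat(sprintf("dmin [%s]: %d miRNAs, %d edges (confidence >= %.3g)\n",
              x$disease, length(x$vertices), nrow(x$edges),
              x$min_confidence))
  invisible(x)
}

#' Conserved signature component of a disease class
#'
#' Intersects the edge sets of the disease-specific networks of all
#' diseases in a class: an miRNA-miRNA edge belongs to the signature only
#' when it passes the confidence filter in every member network. The
#' surviving edge set is split into connected components (a class can carry
#' more than one signature subnetwork).
#'
#' @param dmins List of `dmin` objects (one per member disease).
#' @param class_name Name of the disease class.
#' @return An object of class `md_signature`: list with `disease_class`,
#'   `member_diseases`, `edges` (data.frame `mirna_a`, `mirna_b`,
#'   `min_weight` — the smallest member-network weight), `mirnas` (endpoint
#'   union) and `components` (list of edge data.frames, one per connected
#'   component, largest first).
#' @export
intersect_class_signature <- function(dmins, class_name = "class") {
  if (!length(dmins)) stopf("need at least one disease network")
  stopifnot(all(vapply(dmins, inherits, logical(1), "dmin")))
  keys <- lapply(dmins, function(d) pair_key(d$edges$mirna_a,
                                             d$edges$mirna_b))
  common <- Reduce(intersect, keys)
  if (length(common)) {
    min_w <- vapply(common, function(k) {
      min(vapply(seq_along(dmins), function(i) {
        dmins[[i]]$edges$weight[match(k, keys[[i]])]
      }, numeric(1)))
    }, numeric(1))
    parts <- strsplit(common, "||", fixed = TRUE)
    edges <- data.frame(mirna_a = vapply(parts, `[`, character(1), 1L),
                        mirna_b = vapply(parts, `[`, character(1), 2L),
                        min_weight = unname(min_w),
                        stringsAsFactors = FALSE)
    edges <- edges[order(-edges$min_weight, edges$mirna_a), ]
    rownames(edges) <- NULL
    g <- igraph::graph_from_data_frame(edges[, c("mirna_a", "mirna_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    members <- split(names(comp$membership), comp$membership)
    members <- members[order(-vapply(members, length, integer(1)))]
    components <- lapply(members, function(vs) {
      sub <- edges[edges$mirna_a %in% vs & edges$mirna_b %in% vs, ,
                   drop = FALSE]
      rownames(sub) <- NULL
      sub
    })
    names(components) <- NULL
  } else {
    edges <- data.frame(mirna_a = character(), mirna_b = character(),
                        min_weight = numeric(), stringsAsFactors = FALSE)
    components <- list()
  }
  structure(list(disease_class = class_name,
                 member_diseases = vapply(dmins, `[[`, character(1),
                                          "disease"),
                 edges = edges,
                 mirnas = sort(unique(c(edges$mirna_a, edges$mirna_b))),
                 components = components),
            class = "md_signature")
}

#' @export
print.md_signature <- function(x, ...) {
  cat(sprintf(
    "md_signature [%s]: %d diseases intersected, %d edges over %d miRNAs, %d component(s)\n",
    x$disease_class, length(x$member_diseases), nrow(x$edges),
    length(x$mirnas), length(x$components)))
  invisible(x)
}

#' Export a network as a CSV edge list
#'
#' Writes one row per edge with columns `mirna_a`, `mirna_b`, `context`
#' (the disease or disease-class name) and `confidence`; the file can be
#' imported by standard network tools and read back with
#' [import_edgelist_csv()].
#'
#' @param network A `dmin` or `md_signature`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_edgelist_csv <- function(network, path) {
  if (inherits(network, "dmin")) {
    df <- data.frame(mirna_a = network$edges$mirna_a,
                     mirna_b = network$edges$mirna_b,
                     context = rep(network$disease,
                                   nrow(network$edges)),
                     confidence = network$edges$weight,
                     stringsAsFactors = FALSE)
  } else if (inherits(network, "md_signature")) {
    df <- data.frame(mirna_a = network$edges$mirna_a,
                     mirna_b = network$edges$mirna_b,
                     context = rep(network$disease_class,
                                   nrow(network$edges)),
                     confidence = network$edges$min_weight,
                     stringsAsFactors = FALSE)
  } else {
    stopf("network must be a dmin or md_signature")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_edgelist_csv
#' @export
import_edgelist_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(mirna_a = "character",
                                 mirna_b = "character",
                                 context = "character",
                                 confidence = "numeric"))
}

#' Bundled disease-class layout for cancers
#'
#' Four tissue/organ-specific cancer classes commonly used to mine
#' pan-cancer signatures: gastrointestinal, endocrine, leukemia/blood and
#' nerve cancers. Disease names are normalized (lower case).
#'
#' @return Named list mapping class name to member disease names.
#' @export
default_disease_classes <- function() {
  list(
    gastrointestinal = c("esophageal cancer", "gastroesophageal cancer",
                         "gastrointestinal cancer", "gastric cancer",
                         "colorectal cancer"),
    endocrine = c("hepatocellular carcinoma", "pancreatic cancer",
                  "thyroid carcinoma follicular",
                  "thyroid carcinoma papillary"),
    leukemia = c("hematological tumors", "acute myeloid leukemia",
                 "chronic lymphatic leukemia",
                 "acute myelogenous leukemia"),
    nerve = c("neuroblastoma", "medulloblastoma", "glioblastoma")
  )
}
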