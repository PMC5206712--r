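#' Configuration of a full pipeline run
#'
#' @param input Path to a record file (canonical schema), or an
#'   `md_dataset`.
#' @param out_dir Output directory; created if absent.
#' @param method Expression-matrix scoring scheme, see
#'   [build_expression_matrix()].
#' @param algorithms Inference algorithms to fuse; the consensus divides by
#'   however many are configured (K).
#' @param consensus_mode `"exact"` or `"paper_truncated"`, see
#'   [average_rank_consensus()].
#' @param min_confidence,top_fraction Network filter: the explicit
#'   confidence threshold is used unless `top_fraction` is set, which
#'   overrides it with a quantile cutoff (see [build_dmin()]).
#' @param classes Named list mapping disease-class names to disease lists;
#'   default: one class per disease present in the data.
#' @param n_trees,k_candidates,bins Estimator settings, see
#'   [genie3_scores()] and [mutual_information_matrix()].
#' @param missing Missing-cell policy for scoring, see [dense_values()].
#' @param seed Run seed; all stage randomness derives from it.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir, method = "average",
                       algorithms = c("clr", "mrnetb", "pearson",
                                      "spearman", "dcor", "genie3"),
                       consensus_mode = "exact", min_confidence = 0.9,
                       top_fraction = NULL, classes = NULL,
                       n_trees = 100L, k_candidates = "sqrt", bins = NULL,
                       missing = "zero_fill", seed = 1L) {
  if (!length(algorithms)) stopf("algorithm list must be non-empty")
  if (!is.null(top_fraction) &&
      (top_fraction <= 0 || top_fraction > 1))
    stopf("top_fraction must lie in (0, 1]")
  structure(list(input = input, out_dir = out_dir, method = method,
                 algorithms = algorithms, consensus_mode = consensus_mode,
                 min_confidence = min_confidence,
                 top_fraction = top_fraction, classes = classes,
                 n_trees = n_trees, k_candidates = k_candidates,
                 bins = bins, missing = missing, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full consensus network-inference pipeline
#'
#' Orchestrates parse, matrix construction, the configured inference
#' algorithms, Borda consensus, truth-network validation, disease-network
#' construction and class-signature intersection as one reproducible run.
#' Every stage output is written under `out_dir` as CSV and listed in the
#' returned manifest; the manifest plus the seed reproduce the run.
#'
#' @param cfg A [run_config()].
#' @return The run manifest (list): `params` (parameter echo), `paths`
#'   (stage output files), `timings` (per-stage seconds), `k_algorithms`,
#'   and summaries (`n_records`, `n_nodes`, `validation` areas when
#'   computable). Also written as `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(); timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    timings[[name]] <<- round(tic() - t0, 3)
    out
  }

  dataset <- stage("parse", {
    ds <- if (inherits(cfg$input, "md_dataset")) cfg$input else
      parse_records(cfg$input)
    p <- file.path(cfg$out_dir, "records.csv")
    write_records(ds, p)
    paths$records <- p
    ds
  })

  em <- stage("matrix", {
    m <- build_expression_matrix(dataset, cfg$method)
    p <- file.path(cfg$out_dir, sprintf("matrix_%s.csv", cfg$method))
    write_matrix_csv(m, p)
    paths$matrix <- p
    m
  })

  scores <- stage("infer", {
    sc <- infer_scores(em, algorithms = cfg$algorithms,
                       seed = cfg$seed + 1000L, n_trees = cfg$n_trees,
                       k_candidates = cfg$k_candidates, bins = cfg$bins,
                       missing = cfg$missing)
    paths$scores <- vapply(names(sc), function(a) {
      p <- file.path(cfg$out_dir, sprintf("scores_%s.csv", a))
      utils::write.csv(sc[[a]]$scores, p)
      p
    }, character(1))
    sc
  })

  consensus <- stage("consensus", {
    ranked <- lapply(scores, rank_edges)
    cons <- average_rank_consensus(ranked, mode = cfg$consensus_mode)
    p <- file.path(cfg$out_dir, "consensus.csv")
    utils::write.csv(consensus_table(cons, dataset), p, row.names = FALSE)
    paths$consensus <- p
    cons
  })

  validation <- stage("validate", {
    truth <- build_truth_network(dataset)
    cons3 <- filter_edges_by_type(consensus, dataset, types = 3L)
    out <- NULL
    if (nrow(cons3)) {
      labels <- label_edges(cons3, dataset, truth)
      if (any(labels == 1L) && any(labels == 0L)) {
        curve <- precision_recall_curve(cons3$final_rank, labels)
        p <- file.path(cfg$out_dir, "validation_curve.csv")
        utils::write.csv(as.data.frame(curve), p, row.names = FALSE)
        paths$validation <- p
        out <- as.list(curve_areas(curve))
        out$n_positive <- sum(labels)
        out$n_edges <- length(labels)
      }
    }
    out
  })

  classes <- cfg$classes
  if (is.null(classes)) {
    ds_diseases <- unique(dataset$nodes$disease)
    classes <- stats::setNames(as.list(ds_diseases), ds_diseases)
  }

  dmins_by_class <- stage("dmin", {
    paths$dmin <- character(0)
    lapply(classes, function(member_diseases) {
      lapply(member_diseases, function(d) {
        net <- build_dmin(consensus, dataset, d,
                          min_confidence = cfg$min_confidence,
                          top_fraction = cfg$top_fraction)
        p <- file.path(cfg$out_dir, sprintf("dmin_%s.csv",
                                            gsub("[^a-z0-9]+", "_", d)))
        export_edgelist_csv(net, p)
        paths$dmin <<- c(paths$dmin, p)
        net
      })
    })
  })

  signatures <- stage("signature", {
    paths$signature <- character(0)
    lapply(names(classes), function(cl) {
      sig <- intersect_class_signature(dmins_by_class[[cl]], cl)
      p <- file.path(cfg$out_dir, sprintf("signature_%s.csv",
                                          gsub("[^a-z0-9]+", "_", cl)))
      export_edgelist_csv(sig, p)
      paths$signature <<- c(paths$signature, p)
      sig
    })
  })
  names(signatures) <- names(classes)

  manifest <- list(
    params = cfg[setdiff(names(cfg), "input")],
    k_algorithms = length(cfg$algorithms),
    n_records = nrow(dataset$records),
    n_nodes = nrow(dataset$nodes),
    validation = validation,
    paths = paths,
    timings = timings
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest$objects <- list(dataset = dataset, consensus = consensus,
                           dmins = dmins_by_class, signatures = signatures)
  invisible(manifest)
}
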