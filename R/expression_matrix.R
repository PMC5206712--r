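#' Build a disease-specific miRNA expression matrix
#'
#' Turns a record dataset into a samples x MD-node fold-change matrix under
#' one of three scoring schemes for records that report both a minimum and a
#' maximum fold-change:
#' \describe{
#'   \item{`average`}{each cell is the mean of the record's minimum and
#'     maximum fold-change (the single value when only a minimum exists).}
#'   \item{`maxmin`}{instead of averaging, every study containing at least
#'     one dual-valued record is expanded into two rows: a `:min` row holding
#'     all minimum values and a `:max` row holding the maximum where present
#'     (the single value repeated otherwise). Studies with no dual-valued
#'     record contribute one row.}
#'   \item{`missingmax`}{records lacking a maximum first have one imputed as
#'     the mean of the same MD node's maxima over all other studies (falling
#'     back to the record's own minimum when the node has no maximum
#'     anywhere); the average rule is then applied to the completed records.}
#' }
#' Cells for (study, node) pairs never observed are `NA` and flagged in the
#' missing mask — they are resolved only at scoring time (see
#' [dense_values()]).
#'
#' @param data An `md_dataset` from [parse_records()] or [build_md_index()].
#' @param method One of `"average"`, `"maxmin"`, `"missingmax"`.
#' @return An object of class `md_matrix`: list with `values` (numeric
#'   matrix, `NA` = unobserved; rownames = sample labels, colnames = node
#'   labels), `missing` (logical mask, `TRUE` = unobserved) and `method`.
#' @examples
#' r <- data.frame(study_id = "s1", pmid = "p1", disease = "d1",
#'                 mirna = "mir-1", fc_min = 2.3, fc_max = 2.9)
#' build_expression_matrix(build_md_index(r), "average")$values
#' @export
build_expression_matrix <- function(data,
                                    method = c("average", "maxmin",
                                               "missingmax")) {
  method <- match.arg(method)
  switch(method,
         average = build_average_matrix(data),
         maxmin = build_maxmin_matrix(data),
         missingmax = build_missing_max_matrix(data))
}

new_md_matrix <- function(values, method) {
  structure(list(values = values, missing = is.na(values), method = method),
            class = "md_matrix")
}

#' Wrap a plain matrix as an expression matrix
#'
#' Convenience constructor for scoring matrices that did not come from a
#' record dataset (e.g. simulated data). `NA` cells are treated as missing.
#'
#' @param values Numeric matrix, samples in rows, variables in columns.
#' @return An `md_matrix`.
#' @export
md_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  new_md_matrix(values, method = "custom")
}

#' @export
print.md_matrix <- function(x, ...) {
  cat(sprintf("md_matrix (%s scoring): %d samples x %d MD nodes, %.1f%% cells observed\n",
              x$method, nrow(x$values), ncol(x$values),
              100 * mean(!x$missing)))
  invisible(x)
}

check_nonempty <- function(data) {
  if (!inherits(data, "md_dataset")) stopf("expected an md_dataset")
  if (nrow(data$records) == 0L) stopf("dataset has no records")
}

empty_cells <- function(data) {
  matrix(NA_real_, nrow = length(data$studies), ncol = nrow(data$nodes),
         dimnames = list(data$studies, data$nodes$label))
}

#' @rdname build_expression_matrix
#' @export
build_average_matrix <- function(data) {
  check_nonempty(data)
  vals <- empty_cells(data)
  r <- data$records
  cell <- ifelse(is.na(r$fc_max), r$fc_min, (r$fc_min + r$fc_max) / 2)
  vals[cbind(match(r$study_id, data$studies), r$node)] <- cell
  new_md_matrix(vals, "average")
}

#' @rdname build_expression_matrix
#' @export
build_maxmin_matrix <- function(data) {
  check_nonempty(data)
  r <- data$records
  dual_study <- vapply(split(!is.na(r$fc_max), r$study_id), any, logical(1))
  dual_study <- dual_study[data$studies]

  rows <- unlist(lapply(data$studies, function(s) {
    if (dual_study[[s]]) paste0(s, c(":min", ":max")) else s
  }))
  vals <- matrix(NA_real_, nrow = length(rows), ncol = nrow(data$nodes),
                 dimnames = list(rows, data$nodes$label))
  for (i in seq_len(nrow(r))) {
    s <- r$study_id[i]
    if (dual_study[[s]]) {
      vals[paste0(s, ":min"), r$node[i]] <- r$fc_min[i]
      vals[paste0(s, ":max"), r$node[i]] <-
        if (is.na(r$fc_max[i])) r$fc_min[i] else r$fc_max[i]
    } else {
      vals[s, r$node[i]] <- r$fc_min[i]
    }
  }
  new_md_matrix(vals, "maxmin")
}

#' @rdname build_expression_matrix
#' @export
build_missing_max_matrix <- function(data) {
  check_nonempty(data)
  r <- data$records
  # per-node mean of observed maxima and how many studies contribute them
  agg_sum <- tapply(r$fc_max, r$node, sum, na.rm = TRUE)
  agg_n <- tapply(!is.na(r$fc_max), r$node, sum)
  for (i in which(is.na(r$fc_max))) {
    nd <- as.character(r$node[i])
    n_other <- agg_n[[nd]]  # this record has no max, so all maxima are "other"
    r$fc_max[i] <- if (n_other > 0) agg_sum[[nd]] / n_other else r$fc_min[i]
  }
  data$records <- r
  m <- build_average_matrix(data)
  m$method <- "missingmax"
  m
}

#' Resolve missing cells for scoring
#'
#' Network-inference scorers need a complete matrix. Two policies are
#' offered: `zero_fill` scores an unobserved MD node in a study as 0 (no
#' reported differential expression) and is the default for every scorer;
#' `pairwise_complete` keeps `NA`s so that the correlation scorers can use
#' pairwise-complete observations (other scorers do not accept it).
#'
#' @param matrix An `md_matrix`.
#' @param policy `"zero_fill"` or `"pairwise_complete"`.
#' @return A plain numeric matrix.
#' @export
dense_values <- function(matrix, policy = c("zero_fill",
                                            "pairwise_complete")) {
  policy <- match.arg(policy)
  v <- matrix$values
  if (policy == "zero_fill") v[is.na(v)] <- 0
  v
}

#' Read/write expression matrices as labeled CSV
#'
#' Rows are samples, columns MD nodes; an empty field marks an unobserved
#' cell. The round trip `write_matrix_csv()` then `read_matrix_csv()`
#' reproduces values, mask and labels.
#'
#' @param matrix An `md_matrix`.
#' @param path File path.
#' @return `write_matrix_csv()` returns `path` invisibly;
#'   `read_matrix_csv()` returns an `md_matrix` (method `"file"`).
#' @export
write_matrix_csv <- function(matrix, path) {
  df <- data.frame(sample = rownames(matrix$values), matrix$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  mode(vals) <- "numeric"
  rownames(vals) <- df[[1]]
  new_md_matrix(vals, "file")
}
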