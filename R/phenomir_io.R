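#' Field mapping for fold-change record tables
#'
#' Describes how the columns of an input table map onto the canonical record
#' schema (`study_id`, `pmid`, `disease`, `mirna`, `fc_min`, `fc_max`). The
#' defaults name the canonical columns themselves; pass other column names to
#' adapt exports from curated miRNA-disease databases.
#'
#' @param study_id,pmid,disease,mirna,fc_min,fc_max Column names in the input
#'   table holding each canonical field.
#' @return A named character vector of class `phenomir_dialect`.
#' @examples
#' phenomir_dialect(mirna = "miRNA", fc_min = "FoldChange")
#' @export
phenomir_dialect <- function(study_id = "study_id", pmid = "pmid",
                             disease = "disease", mirna = "mirna",
                             fc_min = "fc_min", fc_max = "fc_max") {
  structure(
    c(study_id = study_id, pmid = pmid, disease = disease,
      mirna = mirna, fc_min = fc_min, fc_max = fc_max),
    class = "phenomir_dialect"
  )
}

#' Parse miRNA-disease fold-change records into a dataset
#'
#' Reads a table of per-study miRNA fold-change observations (one row per
#' study x miRNA x disease) and builds a validated dataset. Rows carrying no
#' fold-change value at all, and rows whose fold-change fields fail numeric
#' parsing or whose miRNA/disease name is empty, are dropped and counted.
#' Duplicate (study, miRNA, disease) rows are collapsed by averaging their
#' fold-change values. miRNA and disease names are case-folded and
#' whitespace-trimmed; no alias resolution is attempted.
#'
#' A row with only a maximum fold-change keeps that value as its single
#' (minimum) fold-change, so that every retained record has a finite
#' `fc_min`.
#'
#' @param source Path to a CSV/TSV file, or a `data.frame`, holding the
#'   records. Tab or comma separation is auto-detected for files.
#' @param dialect A [phenomir_dialect()] mapping canonical fields to the
#'   source's column names.
#' @return An object of class `md_dataset`: a list with elements
#'   \describe{
#'     \item{records}{data.frame of retained records with columns
#'       `study_id`, `pmid`, `disease`, `mirna`, `fc_min`, `fc_max`
#'       (`NA` when absent) and `node`, the MD-node index.}
#'     \item{nodes}{data.frame of distinct (miRNA, disease) nodes, ordered
#'       lexicographically by (disease, miRNA), with a `label` column
#'       `"disease:mirna"`.}
#'     \item{studies}{character vector of distinct study identifiers, in
#'       first-appearance order of the sorted records.}
#'   }
#'   The attribute `"drop_report"` records row accounting (see
#'   [drop_report()]).
#' @seealso [build_md_index()], [write_records()]
#' @export
parse_records <- function(source, dialect = phenomir_dialect()) {
  if (is.character(source)) {
    if (!file.exists(source)) stopf("cannot read records: no file '%s'", source)
    first <- readLines(source, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    raw <- utils::read.csv(source, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  } else if (is.data.frame(source)) {
    raw <- source
  } else {
    stopf("source must be a file path or a data.frame")
  }

  missing_cols <- setdiff(unname(dialect[c("study_id", "pmid", "disease",
                                           "mirna", "fc_min")]),
                          names(raw))
  if (length(missing_cols)) {
    stopf("dialect refers to absent column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  has_max_col <- dialect[["fc_max"]] %in% names(raw)

  n_total <- nrow(raw)
  if (n_total == 0L) {
    ds <- build_md_index(empty_records())
    attr(ds, "drop_report") <- list(total = 0L, retained = 0L,
                                    dropped_missing_fc = 0L,
                                    dropped_malformed = 0L,
                                    collapsed_duplicates = 0L)
    return(ds)
  }

  as_num <- function(x) suppressWarnings(as.numeric(as.character(x)))
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))

  fc_min_raw <- as.character(raw[[dialect[["fc_min"]]]])
  fc_max_raw <- if (has_max_col) as.character(raw[[dialect[["fc_max"]]]]) else
    rep(NA_character_, n_total)
  fc_min <- as_num(fc_min_raw)
  fc_max <- as_num(fc_max_raw)

  # rows with no fold-change information at all
  no_fc <- blank(fc_min_raw) & blank(fc_max_raw)
  # rows with a non-blank fold-change field that fails numeric parsing, or
  # with an empty miRNA/disease name, are malformed
  bad_num <- (!blank(fc_min_raw) & is.na(fc_min)) |
    (!blank(fc_max_raw) & is.na(fc_max))
  bad_name <- blank(raw[[dialect[["mirna"]]]]) |
    blank(raw[[dialect[["disease"]]]])
  malformed <- !no_fc & (bad_num | bad_name)
  keep <- !no_fc & !malformed

  rec <- data.frame(
    study_id = trimws(as.character(raw[[dialect[["study_id"]]]]))[keep],
    pmid     = trimws(as.character(raw[[dialect[["pmid"]]]]))[keep],
    disease  = normalize_name(raw[[dialect[["disease"]]]])[keep],
    mirna    = normalize_name(raw[[dialect[["mirna"]]]])[keep],
    fc_min   = fc_min[keep],
    fc_max   = fc_max[keep],
    stringsAsFactors = FALSE
  )
  # a record with only a maximum keeps it as its single fold-change value
  only_max <- is.na(rec$fc_min) & !is.na(rec$fc_max)
  rec$fc_min[only_max] <- rec$fc_max[only_max]
  rec$fc_max[only_max] <- NA_real_

  n_retained <- nrow(rec)

  # collapse duplicate (study, mirna, disease) rows by averaging
  key <- paste(rec$study_id, rec$mirna, rec$disease, sep = "\r")
  n_dup <- n_retained - length(unique(key))
  if (n_dup > 0L) {
    grp <- split(seq_len(n_retained), key)
    rows <- vapply(grp, `[`, integer(1), 1L)
    rec_c <- rec[rows, , drop = FALSE]
    ord <- order(vapply(grp, min, integer(1)))  # keep input order
    grp <- grp[ord]; rec_c <- rec_c[ord, , drop = FALSE]
    rec_c$fc_min <- vapply(grp, function(i) mean(rec$fc_min[i]), numeric(1))
    rec_c$fc_max <- vapply(grp, function(i) {
      v <- rec$fc_max[i]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    rec <- rec_c
  }
  rownames(rec) <- NULL

  ds <- build_md_index(rec)
  attr(ds, "drop_report") <- list(
    total = n_total,
    retained = n_retained,
    dropped_missing_fc = sum(no_fc),
    dropped_malformed = sum(malformed),
    collapsed_duplicates = n_dup
  )
  ds
}

empty_records <- function() {
  data.frame(study_id = character(), pmid = character(),
             disease = character(), mirna = character(),
             fc_min = numeric(), fc_max = numeric(),
             stringsAsFactors = FALSE)
}

#' Index records into the miRNA-disease (MD) node universe
#'
#' Every distinct (miRNA, disease) pair becomes one MD node: the same miRNA
#' observed under two diseases yields two distinct nodes, because its
#' expression profile is disease-specific. Node indexing is deterministic:
#' lexicographic by (disease, miRNA), so a permutation of the input records
#' yields the same node table.
#'
#' @param records A data.frame with at least columns `study_id`, `pmid`,
#'   `disease`, `mirna`, `fc_min` and optionally `fc_max`.
#' @return An `md_dataset` (see [parse_records()]).
#' @examples
#' r <- data.frame(study_id = c("s1", "s2"), pmid = c("p1", "p2"),
#'                 disease = "d1", mirna = "mir-1", fc_min = c(2, 3),
#'                 fc_max = NA_real_)
#' build_md_index(r)$nodes
#' @export
build_md_index <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"fc_max" %in% names(records)) records$fc_max <- NA_real_
  needed <- c("study_id", "pmid", "disease", "mirna", "fc_min")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stopf("records lack column(s): %s",
                          paste(miss, collapse = ", "))
  stopifnot(all(is.finite(records$fc_min)))

  # sort records deterministically, then index nodes lexicographically
  ord <- order(records$disease, records$mirna, records$study_id)
  records <- records[ord, c(needed, "fc_max"), drop = FALSE]
  rownames(records) <- NULL

  nd <- unique(records[, c("disease", "mirna")])
  nd <- nd[order(nd$disease, nd$mirna), , drop = FALSE]
  rownames(nd) <- NULL
  nd$label <- paste(nd$disease, nd$mirna, sep = ":")

  records$node <- match(paste(records$disease, records$mirna, sep = ":"),
                        nd$label)

  structure(
    list(records = records, nodes = nd, studies = unique(records$study_id)),
    class = "md_dataset"
  )
}

#' @export
print.md_dataset <- function(x, ...) {
  cat(sprintf(
    "md_dataset: %d records | %d MD nodes | %d studies | %d diseases\n",
    nrow(x$records), nrow(x$nodes), length(x$studies),
    length(unique(x$nodes$disease))))
  rep <- attr(x, "drop_report")
  if (!is.null(rep)) {
    cat(sprintf("  parsed %d rows: %d retained, %d without fold-change, %d malformed, %d duplicates collapsed\n",
                rep$total, rep$retained, rep$dropped_missing_fc,
                rep$dropped_malformed, rep$collapsed_duplicates))
  }
  invisible(x)
}

#' Row accounting from parsing
#'
#' @param dataset An `md_dataset` returned by [parse_records()].
#' @return A list with `total`, `retained`, `dropped_missing_fc`,
#'   `dropped_malformed` and `collapsed_duplicates` counts;
#'   `retained + dropped_missing_fc + dropped_malformed == total`.
#' @export
drop_report <- function(dataset) attr(dataset, "drop_report")

#' Write records in the canonical schema
#'
#' Serializes a dataset's records (or a bare record data.frame) as CSV with
#' the canonical header `study_id,pmid,disease,mirna,fc_min,fc_max`; an
#' absent `fc_max` is written as an empty field. Re-parsing the file with
#' [parse_records()] reproduces the dataset.
#'
#' @param x An `md_dataset` or record data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(x, path) {
  rec <- if (inherits(x, "md_dataset")) x$records else x
  rec <- rec[, c("study_id", "pmid", "disease", "mirna", "fc_min", "fc_max")]
  utils::write.csv(rec, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
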