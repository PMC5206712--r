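#' Configuration for the synthetic record generator
#'
#' Defines a PhenomiR-like study design with a planted, recoverable
#' correlated miRNA module. Defaults describe a desk-scale benchmark: 3
#' diseases in one class, 30 miRNAs of which 3 form a module with pairwise
#' fold-change correlation 0.9, and 60 studies per disease — enough signal
#' for every scorer family to recover the module, while keeping a full
#' six-algorithm run to a couple of minutes.
#'
#' @param n_mirnas miRNA pool size.
#' @param n_diseases Number of diseases.
#' @param n_studies_per_disease Studies (samples) per disease.
#' @param module_size Number of miRNAs in the planted co-regulated module.
#' @param module_correlation Target pairwise fold-change correlation of
#'   module members within a disease, in (0, 1).
#' @param dual_value_fraction Probability that a record reports both a
#'   minimum and a maximum fold-change.
#' @param missing_fraction Probability that a (study, miRNA) measurement is
#'   omitted.
#' @param pmid_cocitation_rate Probability that a study's PMID covers all
#'   its miRNA records (enabling truth-network co-citation); otherwise each
#'   record receives its own PMID.
#' @param seed Integer seed; the same configuration and seed reproduce a
#'   byte-identical record file.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_mirnas = 30L, n_diseases = 3L,
                         n_studies_per_disease = 60L, module_size = 3L,
                         module_correlation = 0.9,
                         dual_value_fraction = 0.3, missing_fraction = 0.1,
                         pmid_cocitation_rate = 0.8, seed = 1L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas),
              n_diseases = as.integer(n_diseases),
              n_studies_per_disease = as.integer(n_studies_per_disease),
              module_size = as.integer(module_size),
              module_correlation = module_correlation,
              dual_value_fraction = dual_value_fraction,
              missing_fraction = missing_fraction,
              pmid_cocitation_rate = pmid_cocitation_rate,
              seed = as.integer(seed))
  if (cfg$module_size > cfg$n_mirnas)
    stopf("module_size cannot exceed n_mirnas")
  probs <- c(cfg$module_correlation, cfg$dual_value_fraction,
             cfg$missing_fraction, cfg$pmid_cocitation_rate)
  if (any(probs < 0 | probs > 1))
    stopf("rates and correlations must lie in [0, 1]")
  if (any(c(cfg$n_mirnas, cfg$n_diseases, cfg$n_studies_per_disease,
            cfg$module_size) < 1L))
    stopf("counts must be positive")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic miRNA-disease record set with planted structure
#'
#' Emulates the record structure of a curated miRNA-disease fold-change
#' database: multiple studies per disease, dual- and single-valued
#' fold-changes, missing measurements and PMIDs shared across the records
#' of a study. Module miRNAs draw their fold-change from a shared latent
#' factor per study (`x = sqrt(rho) * z + sqrt(1 - rho) * noise`, shifted
#' to a positive fold-change scale), so their within-disease pairwise
#' correlation is approximately `module_correlation`; background miRNAs are
#' independent noise. Dual-valued records add a positive jitter as the
#' maximum fold-change.
#'
#' @param cfg A [synth_config()].
#' @param class_layout Named list mapping disease-class names to disease
#'   names; default one class `"class1"` holding all generated diseases.
#' @return List with elements `dataset` (an `md_dataset`), `records` (the
#'   raw record data.frame, canonical schema), `truth` (a `ground_truth`:
#'   `module_members` plus `planted_edges`, a per-class list of sorted
#'   miRNA-pair data.frames) and `class_layout`.
#' @export
generate_dataset <- function(cfg = synth_config(), class_layout = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  mirnas <- sprintf("mir-%03d", seq_len(cfg$n_mirnas))
  diseases <- sprintf("disease-%02d", seq_len(cfg$n_diseases))
  if (is.null(class_layout)) class_layout <- list(class1 = diseases)
  unknown <- setdiff(unlist(class_layout), diseases)
  if (length(unknown)) stopf("class_layout names unknown disease(s): %s",
                             paste(unknown, collapse = ", "))
  module <- mirnas[seq_len(cfg$module_size)]
  rho <- cfg$module_correlation

  set.seed(cfg$seed)
  rows <- vector("list", cfg$n_diseases * cfg$n_studies_per_disease)
  ri <- 0L
  pmid_counter <- 0L
  for (d in diseases) {
    for (s in seq_len(cfg$n_studies_per_disease)) {
      study <- sprintf("%s-study-%03d", d, s)
      z <- stats::rnorm(1)
      x <- ifelse(mirnas %in% module,
                  sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(cfg$n_mirnas),
                  stats::rnorm(cfg$n_mirnas))
      fc_min <- round(2 + x, 4)
      observed <- stats::runif(cfg$n_mirnas) >= cfg$missing_fraction
      dual <- stats::runif(cfg$n_mirnas) < cfg$dual_value_fraction
      fc_max <- ifelse(dual, round(fc_min + 0.1 +
                                     abs(stats::rnorm(cfg$n_mirnas, 0, 0.5)),
                                   4), NA_real_)
      cocited <- stats::runif(1) < cfg$pmid_cocitation_rate
      n_obs <- sum(observed)
      if (n_obs == 0L) next
      if (cocited) {
        pmid_counter <- pmid_counter + 1L
        pmid <- rep(sprintf("PMID%06d", pmid_counter), n_obs)
      } else {
        pmid <- sprintf("PMID%06d", pmid_counter + seq_len(n_obs))
        pmid_counter <- pmid_counter + n_obs
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(study_id = study, pmid = pmid, disease = d,
                               mirna = mirnas[observed],
                               fc_min = fc_min[observed],
                               fc_max = fc_max[observed],
                               stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows[seq_len(ri)])
  rownames(records) <- NULL

  pairs <- if (cfg$module_size >= 2L) utils::combn(sort(module), 2L) else
    matrix(character(), nrow = 2)
  pair_df <- data.frame(mirna_a = pairs[1, ], mirna_b = pairs[2, ],
                        stringsAsFactors = FALSE)
  truth <- structure(
    list(module_members = module,
         planted_edges = stats::setNames(
           rep(list(pair_df), length(class_layout)), names(class_layout))),
    class = "ground_truth")

  list(dataset = build_md_index(records), records = records, truth = truth,
       class_layout = class_layout)
}

#' Planted-signature recovery report
#'
#' Compares a recovered signature component with the generator's planted
#' edge set for its class: precision is the fraction of recovered edges
#' that were planted, recall the fraction of planted edges recovered.
#'
#' @param truth A `ground_truth` from [generate_dataset()].
#' @param recovered An `md_signature`.
#' @param class_name Class to compare against; defaults to the signature's
#'   own class when present in the ground truth.
#' @return data.frame with `n_planted`, `n_recovered`, `n_overlap`,
#'   `precision`, `recall`.
#' @export
signature_recovery <- function(truth, recovered,
                               class_name = recovered$disease_class) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(recovered, "md_signature"))
  planted <- truth$planted_edges[[class_name]]
  if (is.null(planted)) stopf("no planted edges for class '%s'", class_name)
  pk <- pair_key(planted$mirna_a, planted$mirna_b)
  rk <- pair_key(recovered$edges$mirna_a, recovered$edges$mirna_b)
  ov <- length(intersect(pk, rk))
  data.frame(
    n_planted = length(pk), n_recovered = length(rk), n_overlap = ov,
    precision = if (length(rk)) ov / length(rk) else NA_real_,
    recall = if (length(pk)) ov / length(pk) else NA_real_
  )
}
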