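# Shared fixtures, built in code.

# The published worked example: six algorithms ranking four interactions.
table1_orders <- function() {
  list(alg1 = c("I4", "I2", "I1", "I3"),
       alg2 = c("I2", "I3", "I4", "I1"),
       alg3 = c("I2", "I3", "I1", "I4"),
       alg4 = c("I2", "I4", "I3", "I1"),
       alg5 = c("I2", "I4", "I3", "I1"),
       alg6 = c("I3", "I2", "I4", "I1"))
}

table1_ranked_lists <- function() {
  lapply(names(table1_orders()), function(a) {
    e <- table1_orders()[[a]]
    ranked_list(edges = e, ranks = seq_along(e), algorithm = a)
  })
}

# a small record table in the style of a curated fold-change dump:
# dual- and single-valued fold-changes across two diseases
toy_records <- function() {
  data.frame(
    study_id = c("study-1", "study-1", "study-1", "study-2", "study-2",
                 "study-3", "study-3"),
    pmid = c("p1", "p1", "p1", "p2", "p2", "p3", "p3"),
    disease = c("d1", "d1", "d2", "d1", "d1", "d1", "d2"),
    mirna = c("m1", "m2", "m1", "m1", "m2", "m2", "m3"),
    fc_min = c(2.3, 3.0, 1.5, 4.0, 2.0, 5.0, 1.0),
    fc_max = c(2.9, NA, NA, 6.0, 6.7, 3.1, NA),
    stringsAsFactors = FALSE
  )
}

random_records <- function(seed, n_rows = 40, n_mirnas = 6, n_diseases = 3,
                           n_studies = 8) {
  set.seed(seed)
  data.frame(
    study_id = sample(sprintf("s%02d", 1:n_studies), n_rows, replace = TRUE),
    pmid = sample(sprintf("p%02d", 1:n_studies), n_rows, replace = TRUE),
    disease = sample(sprintf("d%d", 1:n_diseases), n_rows, replace = TRUE),
    mirna = sample(sprintf("m%d", 1:n_mirnas), n_rows, replace = TRUE),
    fc_min = round(runif(n_rows, 0.5, 8), 3),
    fc_max = ifelse(runif(n_rows) < 0.4, round(runif(n_rows, 8, 12), 3),
                    NA_real_),
    stringsAsFactors = FALSE
  )
}

random_scores_matrix <- function(seed, p, labels = sprintf("n%d", 1:p)) {
  set.seed(seed)
  s <- matrix(runif(p * p), p, p, dimnames = list(labels, labels))
  s <- (s + t(s)) / 2
  diag(s) <- 0
  s
}
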