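test_that("edge types follow the endpoint-identity taxonomy", {
  expect_equal(classify_edge_type("m1", "d1", "m1", "d1"), 1L)  # self-loop
  expect_equal(classify_edge_type("m1", "d1", "m1", "d2"), 2L)
  expect_equal(classify_edge_type("m1", "d1", "m2", "d1"), 3L)
  expect_equal(classify_edge_type("m1", "d1", "m2", "d2"), 4L)
  expect_equal(classify_edge_type(c("a", "a"), c("x", "x"),
                                  c("a", "b"), c("y", "x")),
               c(2L, 3L))
})

test_that("disease networks keep only qualifying same-disease edges", {
  rec <- data.frame(study_id = "s", pmid = "p",
                    disease = c("dx", "dx", "dy"),
                    mirna = c("m1", "m2", "m1"),
                    fc_min = 1:3, fc_max = NA_real_)
  ds <- build_md_index(rec)
  # one strong type-3 edge in dx (nodes 1,2), everything else weak
  cons <- data.frame(edge = c("1->2", "2->1", "1->3", "3->2"),
                     from = c(1L, 2L, 1L, 3L), to = c(2L, 1L, 3L, 2L),
                     final_rank = c(0.95, 0.91, 0.99, 0.99))
  class(cons) <- c("md_consensus", "data.frame")
  net <- build_dmin(cons, ds, "dx", min_confidence = 0.9)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 0.95)  # max over the two directions
  expect_equal(net$vertices, c("m1", "m2"))
  # nothing above threshold -> empty network
  empty <- build_dmin(cons, ds, "dx", min_confidence = 0.96)
  expect_equal(nrow(empty$edges), 0L)
  expect_warning(build_dmin(cons, ds, "nowhere"), "not present")
})

test_that("dmin construction equals a brute-force filter-and-collapse scan", {
  g <- generate_dataset(synth_config(n_mirnas = 6, n_diseases = 2,
                                     n_studies_per_disease = 12, seed = 41))
  em <- build_expression_matrix(g$dataset, "average")
  cons <- average_rank_consensus(lapply(
    infer_scores(em, algorithms = c("pearson", "spearman")), rank_edges))
  thr <- 0.7
  for (d in unique(g$dataset$nodes$disease)) {
    net <- build_dmin(cons, g$dataset, d, min_confidence = thr)
    seen <- list()
    for (i in seq_len(nrow(cons))) {
      a <- g$dataset$nodes[cons$from[i], ]; b <- g$dataset$nodes[cons$to[i], ]
      if (a$disease != d || b$disease != d || a$mirna == b$mirna) next
      if (cons$final_rank[i] < thr) next
      k <- paste(sort(c(a$mirna, b$mirna)), collapse = "+")
      prev <- if (is.null(seen[[k]])) 0 else seen[[k]]
      seen[[k]] <- max(prev, cons$final_rank[i])
    }
    got <- setNames(net$edges$weight,
                    paste(net$edges$mirna_a, net$edges$mirna_b, sep = "+"))
    expect_equal(got[order(names(got))],
                 unlist(seen)[order(names(seen))], tolerance = 1e-12)
    # raising the threshold never adds an edge
    stricter <- build_dmin(cons, g$dataset, d, min_confidence = thr + 0.1)
    expect_true(all(paste(stricter$edges$mirna_a, stricter$edges$mirna_b)
                    %in% paste(net$edges$mirna_a, net$edges$mirna_b)))
  }
})

test_that("signature intersection is idempotent, monotone and order-free", {
  mk_dmin <- function(d, pairs, w = 0.95) {
    edges <- data.frame(mirna_a = pmin(pairs[, 1], pairs[, 2]),
                        mirna_b = pmax(pairs[, 1], pairs[, 2]),
                        weight = rep(w, nrow(pairs)),
                        stringsAsFactors = FALSE)
    structure(list(disease = d, edges = edges,
                   vertices = sort(unique(c(edges$mirna_a, edges$mirna_b))),
                   min_confidence = 0.9), class = "dmin")
  }
  tri <- cbind(c("a", "a", "b"), c("b", "c", "c"))
  g1 <- mk_dmin("d1", rbind(tri, c("a", "x")))
  g2 <- mk_dmin("d2", rbind(tri, c("b", "y")))
  g3 <- mk_dmin("d3", rbind(tri, c("c", "z"), c("x", "y")))

  # idempotence
  self <- intersect_class_signature(list(g1, g1))
  expect_setequal(paste(self$edges$mirna_a, self$edges$mirna_b),
                  paste(g1$edges$mirna_a, g1$edges$mirna_b))
  # shared triangle survives, private edges do not
  sig <- intersect_class_signature(list(g1, g2, g3), "toy")
  expect_setequal(paste(sig$edges$mirna_a, sig$edges$mirna_b),
                  c("a b", "a c", "b c"))
  expect_equal(sig$mirnas, c("a", "b", "c"))
  expect_length(sig$components, 1)
  # order invariance
  sig_rev <- intersect_class_signature(list(g3, g1, g2), "toy")
  expect_setequal(paste(sig_rev$edges$mirna_a, sig_rev$edges$mirna_b),
                  paste(sig$edges$mirna_a, sig$edges$mirna_b))
  # monotone: adding a member disease never adds an edge
  g4 <- mk_dmin("d4", rbind(tri[1:2, , drop = FALSE]))
  smaller <- intersect_class_signature(list(g1, g2, g3, g4), "toy")
  expect_true(all(paste(smaller$edges$mirna_a, smaller$edges$mirna_b) %in%
                    paste(sig$edges$mirna_a, sig$edges$mirna_b)))
  # intersection with an empty member is empty
  g_empty <- mk_dmin("d5", tri[0, , drop = FALSE])
  expect_equal(nrow(intersect_class_signature(list(g1, g_empty))$edges), 0L)
  expect_error(intersect_class_signature(list()), "at least one")
})

test_that("disconnected signature edges split into components", {
  mk <- function(pairs) {
    edges <- data.frame(mirna_a = pairs[, 1], mirna_b = pairs[, 2],
                        weight = 0.99, stringsAsFactors = FALSE)
    structure(list(disease = "d", edges = edges,
                   vertices = unique(c(pairs)), min_confidence = 0.9),
              class = "dmin")
  }
  two <- mk(cbind(c("a", "b", "p"), c("b", "c", "q")))
  sig <- intersect_class_signature(list(two), "cls")
  expect_length(sig$components, 2)
  expect_equal(nrow(sig$components[[1]]), 2)  # a-b-c chain first (largest)
  expect_equal(nrow(sig$components[[2]]), 1)
})

test_that("edge-list CSV round trips and counts rows by edges", {
  g <- generate_dataset(synth_config(n_mirnas = 5, n_diseases = 1,
                                     n_studies_per_disease = 12, seed = 47))
  em <- build_expression_matrix(g$dataset, "average")
  cons <- average_rank_consensus(lapply(
    infer_scores(em, algorithms = c("pearson", "spearman")), rank_edges))
  net <- build_dmin(cons, g$dataset, "disease-01", min_confidence = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  export_edgelist_csv(net, path)
  back <- import_edgelist_csv(path)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$mirna_a, net$edges$mirna_a)
  expect_equal(back$confidence, net$edges$weight)
  expect_equal(unique(back$context), "disease-01")
  expect_equal(length(readLines(path)), nrow(net$edges) + 1L)
  # empty network -> header-only file
  empty <- build_dmin(cons, g$dataset, "disease-01", min_confidence = 1.01)
  export_edgelist_csv(empty, path)
  expect_equal(length(readLines(path)), 1L)
})

test_that("the bundled cancer class layout is well formed", {
  classes <- default_disease_classes()
  expect_setequal(names(classes),
                  c("gastrointestinal", "endocrine", "leukemia", "nerve"))
  expect_true(all(vapply(classes, length, integer(1)) >= 3))
  expect_true(all(unlist(classes) == tolower(unlist(classes))))
})
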