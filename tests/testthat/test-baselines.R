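test_that("prevalence predictor reproduces the toy frequency map", {
  dag <- toy_dag()
  corpus <- toy_corpus(dag)
  prev <- prevalence_predictor(corpus, dag)
  want <- c(R = 1.0, A = 0.5, B = 0.5, A1 = 0.25, B1 = 0.25, B2 = 0.25)
  for (g in names(prev$scores)) {
    expect_equal(prev$scores[[g]][names(want)], want)
  }
  # identical maps for any two genes
  expect_identical(prev$scores[[1]], prev$scores[[2]])
  expect_error(prevalence_predictor(toy_corpus_raw(), dag), "propagated")
})

test_that("prevalence cap keeps the highest-frequency terms", {
  # chain ontology: deeper terms are strictly rarer once one gene sits at
  # each depth
  n <- 12
  ids <- sprintf("T%02d", 1:n)
  dag <- ontology_dag(
    terms = data.frame(id = ids, namespace = "BP"),
    edges = data.frame(child = ids[-1], parent = ids[-n]))
  corpus <- propagate_annotations(
    annotation_set(setNames(as.list(ids), sprintf("g%02d", 1:n))), dag)
  prev <- prevalence_predictor(corpus, dag, cap = 5)
  kept <- names(prev$scores[[1]])
  expect_length(kept, 5)
  expect_setequal(kept, ids[1:5])  # lowest-frequency terms dropped
  # frequencies are non-increasing from parent to child
  expect_true(all(diff(prev$scores[[1]][ids[1:5]]) <= 0))
})

test_that("root-only predictor is maximally precise and scores 1/|truth|", {
  dag <- toy_dag()
  ro <- root_only_predictor(dag, "MF", targets = c("g1", "g2"))
  expect_equal(ro$scores$g1, c(R = 1.0))
  curve <- gene_pr_curve(dag, ro$scores$g1, c("A", "A1", "R"))
  expect_equal(curve$precision, 1)
  expect_equal(average_precision(curve), 1 / 3)
  expect_error(root_only_predictor(dag, "BP", "g1"), "no root")
})

test_that("IEA carry-forward closes prior terms at score 1.0", {
  dag <- toy_dag()
  prior <- annotation_set(
    list(g1 = "A", g2 = "B1"),
    records = data.frame(gene = c("g1", "g2"), term = c("A", "B1"),
                         evidence = c("IEA", "EXP"), species = "x",
                         qualifier = ""))
  cf <- iea_carryforward_predictor(prior, dag)
  expect_equal(cf$scores$g1, c(A = 1.0, R = 1.0))
  expect_true(all(unlist(cf$scores) == 1.0))
  # evidence filter: only g1 has IEA
  cf_iea <- iea_carryforward_predictor(prior, dag, codes = "IEA")
  expect_equal(names(cf_iea$scores), "g1")
  # gene with no prior terms is absent
  expect_false("g9" %in% names(cf$scores))
})

test_that("species incidence scores genes by their species' term frequency", {
  dag <- toy_dag()
  raw <- annotation_set(
    list(x1 = "A1", x2 = "A", y1 = "B1", y2 = "B2"),
    species = c(x1 = "sx", x2 = "sx", y1 = "sy", y2 = "sy"))
  corpus <- propagate_annotations(raw, dag)
  sp <- species_incidence_predictor(corpus, dag)
  # A occurs in both sx genes, never in sy: non-prediction for y genes
  expect_equal(sp$scores$x1[["A"]], 1)
  expect_false("A" %in% names(sp$scores$y1))
  # same species -> identical score maps
  expect_identical(sp$scores$x1, sp$scores$x2)
  expect_error(species_incidence_predictor(corpus, dag, targets = "z",
                                           species = c(z = "sz")), "sz")
  # degenerate single-species corpus: every term AUROC is 0.5
  one <- propagate_annotations(annotation_set(
    list(g1 = "A1", g2 = "B1", g3 = "B2"),
    species = c(g1 = "s", g2 = "s", g3 = "s")), dag)
  pred <- species_incidence_predictor(one, dag)
  labels <- c(g1 = TRUE, g2 = FALSE, g3 = FALSE)
  sc <- vapply(names(labels), function(g) pred$scores[[g]][["A"]], 1.0)
  expect_identical(term_auroc(sc, labels)$auroc, 0.5)
})

test_that("rank aggregation reproduces its hand-worked examples", {
  ps <- function(map, alg) prediction_set(map, algorithm = alg)
  # aggregating k copies of one predictor reproduces its ranking
  base <- ps(list(g = c(t1 = 0.9, t2 = 0.5, t3 = 0.1)), "a")
  agg <- aggregate_predictions(list(base, ps(base$scores, "b"),
                                    ps(base$scores, "c")))
  expect_equal(order(-agg$scores$g), order(-base$scores$g))
  # opposite rankings of 2 items -> tie
  opp <- aggregate_predictions(list(
    ps(list(g = c(t1 = 0.9, t2 = 0.1)), "a"),
    ps(list(g = c(t1 = 0.1, t2 = 0.9)), "b")))
  expect_identical(unname(opp$scores$g[["t1"]]), unname(opp$scores$g[["t2"]]))
  # alg1: g1>g2>g3, alg2: g1>g3>g2 -> aggregate top item is g1
  a1 <- ps(list(g1 = c(t = 0.9), g2 = c(t = 0.5), g3 = c(t = 0.1)), "a")
  a2 <- ps(list(g1 = c(t = 0.8), g2 = c(t = 0.2), g3 = c(t = 0.6)), "b")
  agg2 <- aggregate_predictions(list(a1, a2), axis = "genes_within_term")
  sc <- vapply(c("g1", "g2", "g3"), function(g) agg2$scores[[g]][["t"]], 1.0)
  expect_equal(names(which.max(sc)), "g1")
  expect_error(aggregate_predictions(list(base)), "at least 2")
  expect_error(aggregate_predictions(list(
    ps(list(gA = c(t = 0.5)), "a"), ps(list(gB = c(t = 0.5)), "b"))),
    "disjoint")
})

test_that("aggregation is invariant to relabeling and monotone rescaling", {
  set.seed(11)
  mk <- function(alg, scores) prediction_set(scores, algorithm = alg)
  genes <- sprintf("g%d", 1:6)
  scores1 <- lapply(setNames(genes, genes), function(g) {
    setNames(runif(4, 0.05, 1), sprintf("t%d", 1:4))
  })
  scores2 <- lapply(setNames(genes, genes), function(g) {
    setNames(runif(4, 0.05, 1), sprintf("t%d", 1:4))
  })
  a <- mk("a", scores1); b <- mk("b", scores2)
  agg_ab <- aggregate_predictions(list(a, b))
  agg_ba <- aggregate_predictions(list(b, a))
  expect_equal(agg_ab$scores, agg_ba$scores)
  # strictly monotone transform of one input's scores
  b_mono <- mk("b", lapply(scores2, function(s) s^2 / 2 + 0.01))
  expect_equal(aggregate_predictions(list(a, b_mono))$scores, agg_ab$scores)
})

test_that("prevalence scores are monotone along edges", {
  for (seed in 1:3) {
    dag <- generate_ontology(n_terms = 40, namespaces = "BP", seed = seed)
    corpus <- propagate_annotations(
      generate_corpus(dag, n_genes = 50, mf_dispersion = 3, seed = seed), dag)
    prev <- prevalence_predictor(corpus, dag)
    s <- prev$scores[[1]]
    for (child in names(s)) {
      for (parent in intersect(dag$parents[[child]], names(s))) {
        expect_gte(s[[parent]], s[[child]])
      }
    }
  }
})
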