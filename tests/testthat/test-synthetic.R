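test_that("generated ontologies are valid, rooted and deterministic", {
  one <- generate_ontology(n_terms = 1, namespaces = "BP", seed = 1)
  expect_equal(nrow(one$terms), 1)
  expect_equal(ancestors(one, one$roots[["BP"]]), one$roots[["BP"]])

  a <- generate_ontology(n_terms = 80, namespaces = c("BP", "MF"), seed = 5)
  b <- generate_ontology(n_terms = 80, namespaces = c("BP", "MF"), seed = 5)
  expect_identical(a$parents, b$parents)
  expect_false(identical(
    a$parents, generate_ontology(80, namespaces = c("BP", "MF"),
                                 seed = 6)$parents))
  # construction guarantees acyclicity: the constructor's topological sort
  # accepted it, and every non-root has a same-namespace parent
  expect_length(a$roots, 2)
  expect_error(generate_ontology(n_terms = 0), ">= 1")
})

test_that("corpus generation matches its stated distributional knobs", {
  dag <- generate_ontology(n_terms = 100, namespaces = "BP", seed = 2)
  # degenerate dispersion: every gene gets exactly one raw term
  c1 <- generate_corpus(dag, n_genes = 50, mf_dispersion = 1, seed = 2)
  expect_true(all(lengths(c1$assignments) == 1))
  # law of large numbers: mean raw terms within 10% of the configured mean
  c2 <- generate_corpus(dag, n_genes = 2000, mf_dispersion = 4, seed = 2)
  mean_terms <- nrow(c2$records) / n_genes(c2)
  expect_lt(abs(mean_terms - 4) / 4, 0.1)
  expect_error(generate_corpus(dag, n_genes = 0), ">= 1")
  # determinism
  expect_identical(generate_corpus(dag, 100, seed = 9)$records,
                   generate_corpus(dag, 100, seed = 9)$records)
})

test_that("species skew induces within-species annotation correlation", {
  dag <- generate_ontology(n_terms = 80, namespaces = "BP", seed = 4)
  corpus <- generate_corpus(dag, n_genes = 400, mf_dispersion = 4,
                            n_species = 4, species_skew = 0.8, seed = 4)
  prop <- propagate_annotations(corpus, dag)
  terms <- sort(unique(unlist(prop$assignments, use.names = FALSE)))
  mat <- vapply(prop$assignments, function(ts) terms %in% ts,
                logical(length(terms)))
  sp <- prop$species[colnames(mat)]
  set.seed(4)
  pair_cor <- function(same) {
    vals <- numeric(0)
    while (length(vals) < 150) {
      i <- sample(ncol(mat), 2)
      if ((sp[i[1]] == sp[i[2]]) != same) next
      v <- suppressWarnings(cor(mat[, i[1]], mat[, i[2]]))
      if (!is.na(v)) vals <- c(vals, v)
    }
    mean(vals)
  }
  expect_gt(pair_cor(TRUE), pair_cor(FALSE))
})

test_that("gold updates honor confirmation bias and target selection", {
  dag <- generate_ontology(n_terms = 120, namespaces = "BP", seed = 3)
  corpus <- generate_corpus(dag, n_genes = 300, mf_dispersion = 4,
                            iea_fraction = 0.8, seed = 3)
  iea_pairs <- with(corpus$records[corpus$records$evidence == "IEA", ],
                    paste(gene, term))

  gold1 <- generate_gold_update(dag, corpus, n_targets = 60,
                                confirmation_bias = 1, seed = 3)
  pairs1 <- with(gold1$records, paste(gene, term))
  expect_true(all(pairs1 %in% iea_pairs))

  gold0 <- generate_gold_update(dag, corpus, n_targets = 60,
                                confirmation_bias = 0, seed = 3)
  pairs0 <- with(gold0$records, paste(gene, term))
  # upgrade fraction is approximately chance overlap only
  expect_lt(mean(pairs0 %in% iea_pairs), 0.25)

  # every selected gene passes the waiting-period selection rule
  for (gold in list(gold1, gold0)) {
    selected <- select_evaluation_targets(corpus, gold)
    expect_setequal(names(gold$assignments), selected)
  }
  expect_error(generate_gold_update(dag, corpus, n_targets = 1000), "exceeds")
})

test_that("simulated predictor families behave as specified", {
  dag <- generate_ontology(n_terms = 100, namespaces = "BP", seed = 6)
  corpus <- generate_corpus(dag, n_genes = 300, mf_dispersion = 4, seed = 6)
  gold <- generate_gold_update(dag, corpus, n_targets = 50,
                               confirmation_bias = 0.3, seed = 6)
  gold_prop <- propagate_annotations(gold, dag)

  # noise 0: AP = 1 for every evaluated gene
  perfect <- simulate_predictor(dag, corpus, gold, "noisy_oracle",
                                noise = 0, seed = 6)
  aps0 <- vapply(names(perfect$scores), function(g) {
    average_precision(gene_pr_curve(dag, perfect$scores[[g]],
                                    gold_prop$assignments[[g]]))
  }, numeric(1))
  expect_true(all(abs(aps0 - 1) < 1e-12))

  # mean AP strictly decreases as noise steps through {0, 0.5, 1}
  mean_ap <- vapply(c(0, 0.5, 1), function(nz) {
    p <- simulate_predictor(dag, corpus, gold, "noisy_oracle", noise = nz,
                            seed = 60)
    mean(vapply(names(p$scores), function(g) {
      average_precision(gene_pr_curve(dag, p$scores[[g]],
                                      gold_prop$assignments[[g]]))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ap) < 0))

  # binary oracle emits only 1.0 scores
  bin <- simulate_predictor(dag, corpus, gold, "binary_oracle", noise = 0.3,
                            seed = 6)
  expect_true(all(unlist(bin$scores) == 1.0))

  # prevalence mimic: informativeness rate 0 against its own threshold
  mimic <- simulate_predictor(dag, corpus, gold, "prevalence_mimic", seed = 6)
  ic <- information_content(dag, propagate_annotations(corpus, dag))
  tau <- informativeness_threshold(dag, ic, mimic, gold_prop$assignments)
  rates <- vapply(names(mimic$scores), function(g) {
    informativeness_score(dag, ic, mimic$scores[[g]],
                          gold_prop$assignments[[g]])$score
  }, numeric(1))
  expect_equal(informativeness_rate(rates, tau), 0)

  expect_error(simulate_predictor(dag, corpus, gold, "nope"), "arg")
})

test_that("benchmark worlds are bit-identical under a fixed seed", {
  w1 <- generate_benchmark_world(seed = 11, n_terms = 40, n_genes = 80,
                                 n_targets = 15)
  w2 <- generate_benchmark_world(seed = 11, n_terms = 40, n_genes = 80,
                                 n_targets = 15)
  expect_identical(w1$dag$parents, w2$dag$parents)
  expect_identical(w1$corpus_before$records, w2$corpus_before$records)
  expect_identical(w1$gold_update$records, w2$gold_update$records)
  for (nm in names(w1$predictors)) {
    expect_identical(w1$predictors[[nm]]$scores, w2$predictors[[nm]]$scores)
  }
  # gold genes live in the corpus and each gains >= 1 strong term
  expect_true(all(names(w1$gold_update$assignments) %in%
                    names(w1$corpus_before$assignments)))
  expect_true(all(w1$gold_update$records$evidence %in% c("EXP", "TAS", "IC")))
  # adding a predictor leaves the corpus untouched
  w3 <- generate_benchmark_world(
    seed = 11, n_terms = 40, n_genes = 80, n_targets = 15,
    predictors = c(default_predictor_specs(),
                   list(list(family = "noisy_oracle", noise = 0.9))))
  expect_identical(w3$corpus_before$records, w1$corpus_before$records)
  expect_identical(w3$gold_update$records, w1$gold_update$records)
})
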