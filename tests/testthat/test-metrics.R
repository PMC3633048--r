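# Toy truth used throughout: gene with raw {A1}, closure {A1, A, R}.
toy_truth <- c("A", "A1", "R")

test_that("gene PR curves match hand counts on the toy DAG", {
  dag <- toy_dag()
  perfect <- gene_pr_curve(dag, c(A1 = 0.9), toy_truth)
  expect_equal(nrow(perfect), 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  wrong <- gene_pr_curve(dag, c(B1 = 0.9), toy_truth)  # closure {B1,B,R}
  expect_equal(wrong$precision, 1 / 3)
  expect_equal(wrong$recall, 1 / 3)

  root_only <- gene_pr_curve(dag, c(R = 1.0), toy_truth)
  expect_equal(root_only$precision, 1)
  expect_equal(root_only$recall, 1 / 3)

  expect_error(gene_pr_curve(dag, c(A1 = 0.9), character(0)), "empty truth")
  # thresholds strictly descending, recall non-decreasing
  multi <- gene_pr_curve(dag, c(A1 = 0.9, B1 = 0.5, B2 = 0.5), toy_truth)
  expect_true(all(diff(multi$threshold) < 0))
  expect_true(all(diff(multi$recall) >= 0))
})

test_that("average precision sums precision-weighted recall steps", {
  dag <- toy_dag()
  expect_equal(average_precision(gene_pr_curve(dag, c(A1 = 1), toy_truth)), 1)
  expect_equal(average_precision(gene_pr_curve(dag, c(R = 1), toy_truth)),
               1 / 3)
  expect_equal(average_precision(gene_pr_curve(dag, numeric(0), toy_truth)), 0)
})

test_that("average precision equals the brute-force oracle on random instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed, n_terms = 25)
    got <- average_precision(gene_pr_curve(inst$dag, inst$scores, inst$truth))
    expect_equal(got, bf_average_precision(inst$dag, inst$scores, inst$truth),
                 tolerance = 1e-12)
  }
})

test_that("score summary applies the missing-gene policy", {
  expect_equal(cafa_score_summary(c(g1 = 1, g2 = 0)), 0.5)
  expect_equal(cafa_score_summary(c(g1 = 1, g2 = 1, g3 = 1)), 1)
  expect_equal(cafa_score_summary(c(g1 = 1, g2 = NA)), 0.5)
  expect_equal(cafa_score_summary(c(g1 = 1, g2 = NA), missing = "exclude"), 1)
  expect_error(cafa_score_summary(numeric(0)), "no evaluation genes")
  # 3-gene fixture from the toy DAG: APs {1, 1/3, 0}
  dag <- toy_dag()
  aps <- c(
    average_precision(gene_pr_curve(dag, c(A1 = 1), toy_truth)),
    average_precision(gene_pr_curve(dag, c(R = 1), toy_truth)),
    NA)
  expect_equal(cafa_score_summary(setNames(aps, c("g1", "g2", "g3"))), 4 / 9)
})

test_that("term AUROC handles ties, absences and degenerate labels", {
  labels <- c(a = TRUE, b = FALSE, c = FALSE)
  expect_equal(term_auroc(c(a = 0.9, b = 0.1, c = 0.2), labels)$auroc, 1)
  expect_equal(term_auroc(c(a = 0.5, b = 0.9, c = 0.1), labels)$auroc, 0.5)
  # all genes identically scored -> 0.5 exactly
  expect_identical(term_auroc(c(a = 0.7, b = 0.7, c = 0.7), labels)$auroc, 0.5)
  # absent scores tied at the bottom
  expect_equal(term_auroc(c(b = 0.9), labels)$auroc, 0.25)
  expect_true(is.na(term_auroc(c(a = 1), c(a = TRUE))$auroc))
})

test_that("term AUROC equals pairwise counting on random inputs", {
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(4:20, 1)
    genes <- sprintf("g%d", seq_len(n))
    labels <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), genes)
    if (!any(labels)) labels[1] <- TRUE
    if (all(labels)) labels[n] <- FALSE
    scored <- sample(genes, sample(0:n, 1))
    scores <- setNames(sample(seq(0.1, 1, 0.1), length(scored),
                              replace = TRUE), scored)
    expect_equal(term_auroc(scores, labels)$auroc, bf_auroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(99)
  genes <- sprintf("g%d", 1:15)
  labels <- setNames(rep(c(TRUE, FALSE), c(5, 10)), genes)
  scores <- setNames(runif(12, 0.05, 1), sample(genes, 12))
  base <- term_auroc(scores, labels)$auroc
  expect_equal(term_auroc(scores^3, labels)$auroc, base)
  expect_equal(term_auroc(scores / 2 + 0.4, labels)$auroc, base)
})

test_that("evaluable-term selection enforces the 10-100 member window", {
  mk_gold <- function(counts) {
    genes <- sprintf("g%d", seq_len(max(counts) + 5))
    assignments <- lapply(setNames(genes, genes), function(g) character(0))
    for (i in seq_along(counts)) {
      t <- sprintf("t%d", i)
      for (g in genes[seq_len(counts[i])]) {
        assignments[[g]] <- c(assignments[[g]], t)
      }
    }
    annotation_set(assignments, propagated = TRUE)
  }
  gold <- mk_gold(c(9, 10, 55, 100, 101))
  expect_equal(select_evaluable_terms(gold), c("t2", "t3", "t4"))
})

test_that("informativeness scoring and threshold behave on the toy world", {
  dag <- toy_dag()
  corpus <- toy_corpus(dag)
  ic <- information_content(dag, corpus)
  prev <- prevalence_predictor(corpus, dag)
  # predicting the most specific true term scores its IC under Resnik
  r <- informativeness_score(dag, ic, c(A1 = 0.9), toy_truth)
  expect_equal(r$score, 2)
  expect_equal(r$pred_term, "A1")
  # cross-branch prediction: only common ancestor is the root
  expect_equal(informativeness_score(dag, ic, c(B1 = 0.9), toy_truth)$score, 0)
  expect_equal(informativeness_score(dag, ic, numeric(0), toy_truth)$score, 0)

  # tau over a single gene whose truth is {A1,A,R}: prevalence's 6-term list
  # includes A1 itself, so tau = ic(A1) = 2 bits
  truths <- list(g1 = toy_truth)
  tau <- informativeness_threshold(dag, ic, prev, truths, top_n = 10)
  expect_equal(tau, 2)
  # tau is invariant to duplicating a gene
  expect_equal(informativeness_threshold(dag, ic, prevalence_predictor(
    corpus, dag, targets = c("g1", "g1b")), c(truths, list(g1b = toy_truth))),
    tau)
  # root-only match gives tau = 0
  expect_equal(informativeness_threshold(
    dag, ic, prediction_set(list(g1 = c(R = 1)), algorithm = "prevalence"),
    truths), 0)
  expect_error(informativeness_threshold(dag, ic, prev, list()), "empty")
})

test_that("informativeness rate counts strict exceedances", {
  expect_equal(informativeness_rate(c(1, 2, 3, 4), tau = 2.5), 0.5)
  expect_equal(informativeness_rate(c(3, 3), tau = 3), 0)  # strict
  expect_equal(informativeness_rate(c(4, 5), tau = 3), 1)
})

test_that("multifunctionality counts propagated terms per gene", {
  dag <- toy_dag()
  corpus <- toy_corpus(dag)
  expect_equal(multifunctionality_score(corpus, "g1"), 3)
  expect_equal(multifunctionality_score(corpus, "nobody"), 0)
  expect_equal(multifunctionality_score(propagate_annotations(corpus, dag),
                                        "g1"), 3)
  expect_error(multifunctionality_score(toy_corpus_raw(), "g1"), "propagated")
})

test_that("multifunctionality correlation is Spearman on shared terms", {
  mf <- c(t1 = 1, t2 = 2, t3 = 3, t4 = 4, t5 = 5)
  expect_equal(multifunctionality_correlation(mf, mf * 10), 1)
  expect_equal(multifunctionality_correlation(mf, rev(unname(mf)) |>
                                                setNames(names(mf))), -1)
  # one swap in 5 items: Spearman = 1 - 6*sum(d^2)/(n(n^2-1)) = 1 - 12/120
  swapped <- c(t1 = 1, t2 = 3, t3 = 2, t4 = 4, t5 = 5)
  expect_equal(multifunctionality_correlation(mf, swapped), 0.9)
  expect_error(multifunctionality_correlation(mf[1:2], mf[1:2]), "at least 3")
})
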