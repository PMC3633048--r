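# Shared fixtures: the 6-term toy DAG (root R; A,B is_a R; A1 is_a A;
# B1,B2 is_a B), the 4-gene corpus C4 (g1:{A1} g2:{A} g3:{B1} g4:{B2}),
# and independent brute-force oracles used to cross-check the package's
# closure, average-precision and AUROC implementations.

toy_dag <- function(namespace = "MF") {
  ontology_dag(
    terms = data.frame(id = c("R", "A", "B", "A1", "B1", "B2"),
                       namespace = namespace),
    edges = data.frame(child = c("A", "B", "A1", "B1", "B2"),
                       parent = c("R", "R", "A", "B", "B")))
}

toy_corpus_raw <- function() {
  annotation_set(list(g1 = "A1", g2 = "A", g3 = "B1", g4 = "B2"))
}

toy_corpus <- function(dag = toy_dag()) {
  propagate_annotations(toy_corpus_raw(), dag)
}

# --- oracles (independent code paths) ---------------------------------

# reflexive reachability by iterated parent expansion to a fixpoint
bf_ancestors <- function(dag, term) {
  out <- term
  repeat {
    step <- unique(c(out, unlist(dag$parents[out], use.names = FALSE)))
    if (length(step) == length(out)) return(sort(out))
    out <- step
  }
}

bf_closure <- function(dag, terms) {
  if (!length(terms)) return(character(0))
  sort(unique(unlist(lapply(terms, bf_ancestors, dag = dag))))
}

# AP oracle: enumerate every distinct threshold, recompute predicted set
# from scratch with the brute-force closure, sum rectangle areas
bf_average_precision <- function(dag, scores, truth) {
  if (!length(scores)) return(0)
  th <- sort(unique(as.numeric(scores)), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in th) {
    pred <- bf_closure(dag, names(scores)[scores >= t])
    tp <- length(intersect(pred, truth))
    prec <- tp / length(pred)
    rec <- tp / length(truth)
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

# AUROC oracle: explicit pairwise comparison counting, absent scores a
# common value below everything
bf_auroc <- function(scores, labels) {
  full <- stats::setNames(rep(-Inf, length(labels)), names(labels))
  full[names(scores)] <- scores
  pos <- full[labels]
  neg <- full[!labels]
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1 else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# exhaustive descendant-max oracle for score propagation (explicit empty)
bf_propagate_scores <- function(dag, scores) {
  closure <- bf_closure(dag, names(scores))
  out <- stats::setNames(rep(NA_real_, length(closure)), closure)
  for (a in closure) {
    implied <- names(scores)[vapply(names(scores), function(s) {
      a %in% bf_ancestors(dag, s)
    }, logical(1))]
    out[[a]] <- max(scores[implied])
  }
  out
}

# random small instance: DAG <= n terms, a scored prediction map and a
# non-empty closed truth set
random_instance <- function(seed, n_terms = 20, namespace = "BP") {
  set.seed(seed)
  dag <- generate_ontology(n_terms = sample(5:n_terms, 1), max_parents = 3,
                           namespaces = namespace, depth = 4,
                           seed = seed + 10000)
  active <- dag$terms$id
  set.seed(seed)
  truth_raw <- sample(active, sample(1:3, 1))
  truth <- propagate_annotation_set(dag, truth_raw)
  k <- sample(1:min(6, length(active)), 1)
  terms <- sample(active, k)
  scores <- stats::setNames(round(runif(k, 0.01, 1), 3), terms)
  scores <- scores[scores > 0]
  list(dag = dag, scores = scores, truth = truth)
}
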