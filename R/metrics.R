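#' Gene-centric precision-recall curve
#'
#' Sweeps the distinct submitted scores in descending order; at each
#' threshold t the predicted set is the up-propagation of every term scored
#' at or above t, and precision = |predicted AND truth| / |predicted|,
#' recall = |predicted AND truth| / |truth|. Equal-scored terms enter
#' together, so thresholds are strictly descending and recall is
#' non-decreasing along the curve.
#'
#' @param dag an [ontology_dag()].
#' @param scores named numeric vector of submitted term scores in (0, 1].
#' @param truth the gene's ancestor-closed true term set (non-empty).
#' @return A data.frame of class `pr_curve` with columns `threshold`,
#'   `precision`, `recall`; zero rows when there are no predictions.
#' @export
gene_pr_curve <- function(dag, scores, truth) {
  truth <- unique(as.character(truth))
  if (!length(truth)) stop("empty truth set: gene should be excluded upstream")
  if (!length(scores)) {
    out <- data.frame(threshold = numeric(0), precision = numeric(0),
                      recall = numeric(0))
    class(out) <- c("pr_curve", "data.frame")
    return(out)
  }
  thresholds <- sort(unique(as.numeric(scores)), decreasing = TRUE)
  prec <- rec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    raw <- names(scores)[scores >= thresholds[i]]
    pred <- propagate_annotation_set(dag, raw, lenient = TRUE)
    tp <- length(intersect(pred, truth))
    prec[i] <- tp / length(pred)
    rec[i] <- tp / length(truth)
  }
  out <- data.frame(threshold = thresholds, precision = prec, recall = rec)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Average precision of a precision-recall curve
#'
#' Step-wise area under the curve: sum over points of
#' precision_i * (recall_i - recall_(i-1)) with recall_0 = 0. This is the
#' per-gene summary used as the gene-centric evaluation score. A gene with
#' no predictions (empty curve) scores 0.
#'
#' @param curve a `pr_curve` from [gene_pr_curve()].
#' @return A score in \[0, 1\].
#' @export
average_precision <- function(curve) {
  if (!nrow(curve)) return(0)
  sum(curve$precision * diff(c(0, curve$recall)))
}

#' Summarize per-gene scores for one algorithm
#'
#' Arithmetic mean over evaluation genes. Genes with no predictions (NA
#' entries) contribute 0 under the default policy, because the evaluation
#' averages across all targets; `missing = "exclude"` drops them instead.
#'
#' @param ap named numeric vector of per-gene average precisions, with `NA`
#'   marking genes the algorithm did not predict for.
#' @param missing "zero" (default) or "exclude".
#' @return The mean score.
#' @export
cafa_score_summary <- function(ap, missing = c("zero", "exclude")) {
  missing <- match.arg(missing)
  if (!length(ap)) stop("no evaluation genes")
  if (missing == "zero") {
    ap[is.na(ap)] <- 0
  } else {
    ap <- ap[!is.na(ap)]
    if (!length(ap)) stop("no evaluation genes left after excluding missing")
  }
  mean(ap)
}

#' Term-centric AUROC with mid-rank tie handling
#'
#' Mann-Whitney formulation: genes are ranked by their submitted score for
#' the term, with non-predictions imputed as a common value below every
#' submitted score (all tied at the bottom) and ties resolved by mid-ranks.
#' Equivalent to (wins + ties/2) / (n_pos * n_neg) over all
#' positive-negative gene pairs. Invariant under strictly monotone score
#' transforms.
#'
#' @param scores named numeric vector of scores for the genes that received
#'   a prediction for this term (subset of `names(labels)`).
#' @param labels named logical vector over all evaluation genes; `TRUE` for
#'   genes annotated to the term.
#' @return A list with `n_pos`, `n_neg` and `auroc` (`NA` when either class
#'   is empty, in which case the term is skipped upstream).
#' @export
term_auroc <- function(scores, labels) {
  stopifnot(is.logical(labels), !is.null(names(labels)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos < 1 || n_neg < 1) {
    return(list(n_pos = n_pos, n_neg = n_neg, auroc = NA_real_))
  }
  full <- stats::setNames(rep(-Inf, length(labels)), names(labels))
  sc <- scores[names(scores) %in% names(labels)]
  full[names(sc)] <- sc
  r <- rank(full, ties.method = "average")
  auroc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(n_pos = n_pos, n_neg = n_neg, auroc = auroc)
}

#' Select terms evaluable from the function-centric perspective
#'
#' Terms annotated to between `min_members` and `max_members` evaluation
#' genes (inclusive) in the propagated gold standard; outside that window a
#' term is either too sparse for a meaningful ranking or too generic.
#'
#' @param gold a propagated [annotation_set()] restricted to the evaluation
#'   genes.
#' @param min_members,max_members member-count window (defaults 10 and 100).
#' @return Sorted character vector of term ids.
#' @export
select_evaluable_terms <- function(gold, min_members = 10L,
                                   max_members = 100L) {
  stopifnot(inherits(gold, "annotation_set"))
  if (!n_genes(gold)) stop("empty gold standard")
  tab <- table(unlist(gold$assignments, use.names = FALSE))
  sort(names(tab)[tab >= min_members & tab <= max_members])
}

# Pick a predictor's top-n proposed terms: by descending score, breaking
# score ties by descending IC (the measure asks about the most *specific*
# predictions), then term id for determinism.
top_n_terms <- function(dag, ic, scores, top_n) {
  if (!length(scores)) return(character(0))
  icv <- vapply(names(scores), function(t) ic_value(dag, ic, t), numeric(1))
  icv[!is.finite(icv)] <- .Machine$double.xmax
  ord <- order(-as.numeric(scores), -icv, names(scores))
  names(scores)[ord][seq_len(min(top_n, length(scores)))]
}

#' Informativeness of a gene's predictions
#'
#' The best semantic similarity between any of the predictor's top-n
#' proposed terms and any term of the gene's true (ancestor-closed)
#' annotation. Score ties in the top-n pick are broken towards more
#' specific (higher-IC) terms. A gene with no predictions scores 0 and is
#' never informative.
#'
#' @param dag an [ontology_dag()].
#' @param ic an `ic_table` from [information_content()].
#' @param scores the gene's submitted term -> score map.
#' @param truth the gene's ancestor-closed true term set (non-empty).
#' @param top_n how many top-scoring submitted terms count as proposed
#'   functions (default 10).
#' @param measure "resnik" (bits) or "lin" (\[0, 1\]).
#' @return List with `score`, `pred_term`, `truth_term`.
#' @export
informativeness_score <- function(dag, ic, scores, truth, top_n = 10L,
                                  measure = c("resnik", "lin")) {
  measure <- match.arg(measure)
  truth <- unique(as.character(truth))
  if (!length(truth)) stop("empty truth set")
  if (!length(scores)) {
    return(list(score = 0, pred_term = NA_character_,
                truth_term = NA_character_))
  }
  top <- top_n_terms(dag, ic, scores, top_n)
  simfun <- if (measure == "resnik") resnik_similarity else lin_similarity
  best <- 0
  bp <- bt <- NA_character_
  for (p in top) {
    nsp <- dag$terms[p, "namespace"]
    if (is.na(nsp)) next
    for (t in truth) {
      if (!identical(dag$terms[t, "namespace"], nsp)) next
      s <- simfun(dag, ic, p, t)
      if (s > best) { best <- s; bp <- p; bt <- t }
    }
  }
  list(score = best, pred_term = bp, truth_term = bt)
}

#' Informativeness threshold from the prevalence null
#'
#' tau is the best informativeness score the prevalence null predictor ever
#' achieves over the whole evaluation set: a prediction counts as
#' informative only if it beats (strictly) the best "prediction" that could
#' be made from annotation prevalence alone.
#'
#' @param dag an [ontology_dag()].
#' @param ic an `ic_table`.
#' @param prevalence the prevalence [prediction_set()]; must cover every
#'   evaluation gene.
#' @param truths named list, gene id -> ancestor-closed true term set.
#' @param top_n,measure as in [informativeness_score()].
#' @return tau, the threshold (bits for Resnik).
#' @export
informativeness_threshold <- function(dag, ic, prevalence, truths,
                                      top_n = 10L,
                                      measure = c("resnik", "lin")) {
  measure <- match.arg(measure)
  if (!length(truths)) stop("empty evaluation set")
  missing <- setdiff(names(truths), names(prevalence$scores))
  if (length(missing)) {
    stop("prevalence predictions missing for evaluation gene: ", missing[1])
  }
  best <- vapply(names(truths), function(g) {
    informativeness_score(dag, ic, prevalence$scores[[g]], truths[[g]],
                          top_n = top_n, measure = measure)$score
  }, numeric(1))
  max(best)
}

#' Fraction of genes with informative predictions
#'
#' @param scores named numeric vector of per-gene informativeness scores
#'   (0 for genes with no predictions).
#' @param tau threshold from [informativeness_threshold()]; informative
#'   means strictly greater than `tau`.
#' @return Fraction in \[0, 1\].
#' @export
informativeness_rate <- function(scores, tau) {
  if (!length(scores)) stop("no evaluation genes")
  mean(scores > tau)
}

#' Multifunctionality of a gene
#'
#' Number of propagated terms annotated to the gene (simple-count
#' definition). Unknown genes score 0.
#'
#' @param corpus a propagated [annotation_set()].
#' @param gene a gene id.
#' @export
multifunctionality_score <- function(corpus, gene) {
  stopifnot(inherits(corpus, "annotation_set"))
  if (!isTRUE(corpus$propagated)) stop("corpus must be propagated")
  length(corpus$assignments[[gene]])
}

#' Rank correlation between term multifunctionality and informative gains
#'
#' Spearman rank correlation between a per-term multifunctionality summary
#' (e.g. mean member multifunctionality) and a per-term count of
#' informative-prediction events, over the terms present in both.
#'
#' @param term_mf named numeric vector, term -> mean member
#'   multifunctionality.
#' @param term_gain named numeric vector, term -> count of informative
#'   predictions attributed to the term.
#' @return Spearman correlation in \[-1, 1\]; requires >= 3 common terms.
#' @export
multifunctionality_correlation <- function(term_mf, term_gain) {
  common <- intersect(names(term_mf), names(term_gain))
  if (length(common) < 3) {
    stop("need at least 3 terms with defined values, got ", length(common))
  }
  stats::cor(term_mf[common], term_gain[common], method = "spearman")
}
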