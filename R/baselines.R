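#' Prevalence null predictor
#'
#' Assigns every target gene the identical term -> score map, where the
#' score of a term is the fraction of corpus genes annotated to it (within
#' its namespace), so the namespace root gets weight exactly 1.0 and terms
#' lower down get decreasing weights. Only the `cap` highest-frequency terms
#' per namespace are kept (ties broken by term id, ascending). A control,
#' not a competitor: it can be computed without any information about the
#' targets.
#'
#' @param corpus a propagated [annotation_set()] (the prior annotation
#'   corpus).
#' @param dag an [ontology_dag()].
#' @param targets gene ids to emit predictions for; defaults to the corpus
#'   genes.
#' @param cap per-namespace term cap (default 1000).
#' @param namespace optionally restrict to one namespace.
#' @return A [prediction_set()] labeled "prevalence".
#' @export
prevalence_predictor <- function(corpus, dag, targets = NULL, cap = 1000L,
                                 namespace = NULL) {
  stopifnot(inherits(corpus, "annotation_set"), inherits(dag, "ontology_dag"))
  if (!isTRUE(corpus$propagated)) stop("prevalence requires a propagated corpus")
  if (!n_genes(corpus)) stop("empty corpus")
  if (!is.null(namespace)) corpus <- filter_namespace(corpus, dag, namespace)
  if (!n_genes(corpus)) stop("empty corpus after namespace filtering")
  if (is.null(targets)) targets <- names(corpus$assignments)

  tab <- table(unlist(corpus$assignments, use.names = FALSE))
  counts <- stats::setNames(as.integer(tab), names(tab))
  ns <- dag$terms[names(counts), "namespace"]
  counts <- counts[!is.na(ns)]
  ns <- ns[!is.na(ns)]
  map <- numeric(0)
  for (nm in intersect(unique(ns), names(dag$roots))) {
    root <- dag$roots[[nm]]
    if (!root %in% names(counts)) next
    cn <- counts[ns == nm]
    freq <- cn / counts[[root]]
    ord <- order(-freq, names(freq))
    freq <- freq[ord][seq_len(min(cap, length(freq)))]
    map <- c(map, freq)
  }
  if (!length(map)) stop("no annotated namespace roots in corpus")
  scores <- stats::setNames(rep(list(map), length(targets)), targets)
  prediction_set(scores, algorithm = "prevalence")
}

#' Root-only degenerate predictor
#'
#' Predicts just the namespace root, with score 1.0, for every target. By
#' the true-path rule this is always a correct (precise) prediction —
#' precision 1 at its only threshold — which is exactly the degenerate
#' behavior that makes the unnormalized gene-centric score misleading.
#'
#' @param dag an [ontology_dag()].
#' @param namespace which namespace root to predict.
#' @param targets gene ids.
#' @return A [prediction_set()] labeled "root_only".
#' @export
root_only_predictor <- function(dag, namespace, targets) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!namespace %in% names(dag$roots)) {
    stop("namespace ", namespace, " has no root")
  }
  root <- unname(dag$roots[[namespace]])
  scores <- stats::setNames(
    rep(list(stats::setNames(1.0, root)), length(targets)), targets)
  prediction_set(scores, algorithm = "root_only")
}

#' Carry-forward predictor from pre-existing annotations
#'
#' Uses each gene's pre-existing (typically weak-evidence, IEA-style)
#' annotations, ancestor-closed, all with score 1.0, as if they were a
#' submission. Genes with no prior annotations make no predictions. A
#' retrospective "post-diction" baseline: it tests how competitive simply
#' resubmitting the existing computational annotations would have been.
#'
#' @param prior a raw [annotation_set()] of pre-deadline annotations.
#' @param dag an [ontology_dag()].
#' @param codes optionally restrict to these evidence codes (e.g. "IEA");
#'   requires `prior$records`.
#' @param targets optionally restrict to these genes.
#' @return A [prediction_set()] labeled "iea_carryforward".
#' @export
iea_carryforward_predictor <- function(prior, dag, codes = NULL,
                                       targets = NULL) {
  stopifnot(inherits(prior, "annotation_set"))
  if (!is.null(codes)) {
    if (is.null(prior$records)) stop("evidence filtering requires records")
    r <- prior$records
    prior <- annotation_from_records(r[r$evidence %in% codes, , drop = FALSE])
  }
  genes <- names(prior$assignments)
  if (!is.null(targets)) genes <- intersect(genes, targets)
  scores <- list()
  for (g in genes) {
    closed <- propagate_annotation_set(dag, prior$assignments[[g]],
                                       lenient = TRUE)
    if (!length(closed)) next
    scores[[g]] <- stats::setNames(rep(1.0, length(closed)), closed)
  }
  prediction_set(scores, algorithm = "iea_carryforward")
}

#' Per-species term-incidence predictor
#'
#' Scores gene g for term t by the fraction of g's-species corpus genes
#' annotated to t, so all genes from a given species receive the same
#' ranking. Terms absent from a species' corpus are non-predictions for its
#' genes. A diagnostic for species-specific annotation bias.
#'
#' @param corpus a propagated [annotation_set()] carrying species labels.
#' @param dag an [ontology_dag()].
#' @param targets gene ids to predict for (default: corpus genes).
#' @param species optional named character vector gene -> taxon for targets
#'   not in the corpus.
#' @return A [prediction_set()] labeled "species_incidence".
#' @export
species_incidence_predictor <- function(corpus, dag, targets = NULL,
                                        species = NULL) {
  stopifnot(inherits(corpus, "annotation_set"))
  if (!isTRUE(corpus$propagated)) stop("requires a propagated corpus")
  sp <- corpus$species
  if (is.null(sp)) stop("corpus carries no species labels")
  if (is.null(targets)) targets <- names(corpus$assignments)
  sp_of <- function(g) {
    s <- if (!is.null(species) && g %in% names(species)) species[[g]] else sp[[g]]
    if (is.null(s) || is.na(s)) stop("no species label for target ", g)
    s
  }
  by_species <- split(names(corpus$assignments), sp[names(corpus$assignments)])
  freq_cache <- list()
  species_freq <- function(s) {
    if (!is.null(freq_cache[[s]])) return(freq_cache[[s]])
    gs <- by_species[[s]]
    if (is.null(gs)) stop("target species absent from corpus: ", s)
    tab <- table(unlist(corpus$assignments[gs], use.names = FALSE))
    f <- stats::setNames(as.numeric(tab) / length(gs), names(tab))
    freq_cache[[s]] <<- f
    f
  }
  scores <- lapply(stats::setNames(targets, targets), function(g) {
    species_freq(sp_of(g))
  })
  prediction_set(scores, algorithm = "species_incidence")
}

# normalized mid-ranks in [0,1]; higher input value => higher rank.
# A single item gets rank 1 by convention.
norm_rank <- function(x) {
  n <- length(x)
  if (n == 1) return(stats::setNames(1, names(x)))
  stats::setNames((rank(x, ties.method = "average") - 1) / (n - 1), names(x))
}

#' Aggregate prediction sets by average normalized rank
#'
#' The naive reference combiner: along the chosen axis, items are ranked
#' per algorithm (mid-ranks for ties, missing items tied at the bottom),
#' ranks are normalized to \[0, 1\], averaged across algorithms, and the
#' means re-ranked; final mid-ranks divided by the item count give scores
#' in (0, 1]. Invariant to algorithm relabeling and to strictly monotone
#' rescaling of any input's scores. Not a competitor algorithm — it merely
#' averages the others' outputs after the fact.
#'
#' @param predsets list of at least two [prediction_set()]s over a shared
#'   target universe.
#' @param axis "terms_within_gene" (feeds the gene-centric score) or
#'   "genes_within_term" (feeds the function-centric AUROC).
#' @param algorithm label for the output (default "aggregate").
#' @return A [prediction_set()].
#' @export
aggregate_predictions <- function(predsets,
                                  axis = c("terms_within_gene",
                                           "genes_within_term"),
                                  algorithm = "aggregate") {
  axis <- match.arg(axis)
  if (length(predsets) < 2) stop("need at least 2 prediction sets to aggregate")
  stopifnot(all(vapply(predsets, inherits, logical(1), "prediction_set")))
  universes <- lapply(predsets, function(p) names(p$scores))
  if (!length(Reduce(intersect, universes))) {
    stop("prediction sets have disjoint target universes")
  }
  genes <- sort(unique(unlist(universes)))

  if (axis == "terms_within_gene") {
    out <- list()
    for (g in genes) {
      terms <- sort(unique(unlist(
        lapply(predsets, function(p) names(p$scores[[g]])))))
      if (!length(terms)) next
      nr <- vapply(predsets, function(p) {
        s <- stats::setNames(rep(-Inf, length(terms)), terms)
        sg <- p$scores[[g]]
        s[names(sg)] <- sg
        norm_rank(s)
      }, numeric(length(terms)))
      m <- rowMeans(matrix(nr, nrow = length(terms)))
      out[[g]] <- stats::setNames(
        rank(m, ties.method = "average") / length(m), terms)
    }
    return(prediction_set(out, algorithm = algorithm))
  }

  # genes_within_term: rank the full target universe per term
  terms <- sort(unique(unlist(
    lapply(predsets, function(p) unlist(lapply(p$scores, names),
                                        use.names = FALSE)))))
  final_mat <- matrix(NA_real_, nrow = length(genes), ncol = length(terms),
                      dimnames = list(genes, terms))
  for (t in terms) {
    nr <- vapply(predsets, function(p) {
      v <- vapply(genes, function(g) {
        s <- p$scores[[g]]
        if (!is.null(s) && t %in% names(s)) s[[t]] else -Inf
      }, numeric(1))
      norm_rank(v)
    }, numeric(length(genes)))
    m <- rowMeans(matrix(nr, nrow = length(genes)))
    final_mat[, t] <- rank(m, ties.method = "average") / length(m)
  }
  per_gene <- lapply(stats::setNames(genes, genes), function(g) {
    stats::setNames(final_mat[g, ], colnames(final_mat))
  })
  prediction_set(per_gene, algorithm = algorithm)
}
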