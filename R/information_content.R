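#' Information content of ontology terms over an annotation corpus
#'
#' Computes, for every term used at least once in an ancestor-closed corpus,
#' its annotation frequency p(t) = (genes annotated to t) / (genes annotated
#' to the namespace root of t) and its information content IC(t) = -log2 p(t)
#' in bits. On a propagated corpus p is monotone along edges, so IC(child) >=
#' IC(parent) and IC(root) = 0 exactly.
#'
#' @param dag an [ontology_dag()].
#' @param corpus a propagated [annotation_set()] with at least one gene.
#' @return An object of class `ic_table`: list with named numeric vectors
#'   `p` and `ic`, plus `corpus_size`.
#' @export
information_content <- function(dag, corpus) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(corpus, "annotation_set"))
  if (!isTRUE(corpus$propagated)) {
    stop("information content requires an ancestor-closed (propagated) corpus")
  }
  genes <- names(corpus$assignments)
  if (!length(genes)) stop("empty corpus")
  tab <- table(unlist(corpus$assignments, use.names = FALSE))
  counts <- stats::setNames(as.integer(tab), names(tab))
  ns <- dag$terms[names(counts), "namespace"]
  keep <- !is.na(ns)
  counts <- counts[keep]
  ns <- ns[keep]
  root_count <- stats::setNames(rep(NA_integer_, length(dag$roots)),
                                names(dag$roots))
  present <- intersect(dag$roots, names(counts))
  for (nm in names(dag$roots)) {
    if (dag$roots[[nm]] %in% names(counts)) {
      root_count[[nm]] <- counts[[dag$roots[[nm]]]]
    }
  }
  denom <- root_count[ns]
  ok <- !is.na(denom) & denom > 0
  p <- counts[ok] / denom[ok]
  structure(list(p = p, ic = -log2(p), corpus_size = length(genes)),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat("ic_table: ", length(x$ic), " terms over ", x$corpus_size,
      " genes; IC range [", format(min(x$ic), digits = 3), ", ",
      format(max(x$ic), digits = 3), "] bits\n", sep = "")
  invisible(x)
}

# IC of a term for similarity purposes: table value if present, 0 for a
# namespace root, +Inf for a term never used in the corpus (infinitely
# specific relative to the corpus).
ic_value <- function(dag, ic, term) {
  if (term %in% names(ic$ic)) return(unname(ic$ic[[term]]))
  if (term %in% dag$roots) return(0)
  Inf
}

check_same_namespace <- function(dag, a, b) {
  nsa <- term_namespace(dag, a)
  nsb <- term_namespace(dag, b)
  if (!identical(nsa, nsb)) {
    stop("terms ", a, " (", nsa, ") and ", b, " (", nsb,
         ") are in different namespaces")
  }
  nsa
}

#' Resnik semantic similarity
#'
#' IC of the most-informative common ancestor (MICA) of two same-namespace
#' terms. Common ancestors absent from the IC table contribute only if they
#' are the namespace root (IC 0), so a MICA always exists and the measure is
#' bounded above by min(IC(a), IC(b)).
#'
#' @param dag an [ontology_dag()].
#' @param ic an `ic_table` from [information_content()].
#' @param a,b term ids in the same namespace.
#' @return Similarity in bits (>= 0).
#' @export
resnik_similarity <- function(dag, ic, a, b) {
  ns <- check_same_namespace(dag, a, b)
  if (!a %in% names(dag$ancestors)) stop("unknown or obsolete term: ", a)
  if (!b %in% names(dag$ancestors)) stop("unknown or obsolete term: ", b)
  common <- intersect(dag$ancestors[[a]], dag$ancestors[[b]])
  vals <- ic$ic[intersect(common, names(ic$ic))]
  if (dag$roots[[ns]] %in% common) vals <- c(vals, 0)
  if (!length(vals)) return(0)
  max(vals)
}

#' Lin semantic similarity
#'
#' 2 * IC(MICA) / (IC(a) + IC(b)), dimensionless in \[0, 1\]. Returns 0 by
#' convention when both terms are roots (zero denominator) and when either
#' term never occurs in the corpus (its IC is unbounded).
#'
#' @inheritParams resnik_similarity
#' @export
lin_similarity <- function(dag, ic, a, b) {
  mica <- resnik_similarity(dag, ic, a, b)
  ia <- ic_value(dag, ic, a)
  ib <- ic_value(dag, ic, b)
  if (!is.finite(ia) || !is.finite(ib)) return(0)
  if (ia + ib == 0) return(0)
  min(1, 2 * mica / (ia + ib))
}
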