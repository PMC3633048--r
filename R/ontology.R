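#' Construct an ontology DAG
#'
#' Builds the rooted, acyclic `is_a` graph that all propagation, information
#' content and similarity computations operate on. Terms are partitioned into
#' namespaces (BP, MF, CC); each namespace has exactly one root (a term with
#' no parents). Obsolete terms are retained as metadata but carry no edges
#' and are excluded from every closure query.
#'
#' @param terms data.frame with columns `id` (unique), `namespace`
#'   (one of "BP", "MF", "CC"), and optionally `name` and `obsolete`.
#' @param edges data.frame with columns `child`, `parent`, one row per
#'   `is_a` relation. May be `NULL` for an edgeless ontology.
#' @return An object of class `ontology_dag` with precomputed reflexive
#'   ancestor closures, children maps, per-term depth (longest path from the
#'   namespace root) and the designated root of each namespace.
#' @examples
#' dag <- ontology_dag(
#'   terms = data.frame(id = c("R", "A"), namespace = "MF"),
#'   edges = data.frame(child = "A", parent = "R"))
#' ancestors(dag, "A")
#' @export
ontology_dag <- function(terms, edges = NULL) {
  stopifnot(is.data.frame(terms), "id" %in% names(terms),
            "namespace" %in% names(terms))
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  terms$id <- as.character(terms$id)
  terms$namespace <- as.character(terms$namespace)
  if (anyDuplicated(terms$id)) {
    stop("duplicate term id: ", terms$id[duplicated(terms$id)][1])
  }
  bad_ns <- setdiff(unique(terms$namespace), c("BP", "MF", "CC"))
  if (length(bad_ns)) stop("unknown namespace: ", bad_ns[1])
  if (is.null(terms$name)) terms$name <- terms$id
  if (is.null(terms$obsolete)) terms$obsolete <- FALSE
  terms$obsolete <- as.logical(terms$obsolete)
  rownames(terms) <- terms$id

  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown)) {
    stop("edge references unknown term: ", unknown[1])
  }
  # obsolete terms carry no edges
  obs <- terms$id[terms$obsolete]
  drop <- edges$child %in% obs | edges$parent %in% obs
  edges <- edges[!drop, , drop = FALSE]

  active <- terms$id[!terms$obsolete]
  parents <- lapply(
    split(edges$parent, factor(edges$child, levels = active)), unique)
  children <- lapply(
    split(edges$child, factor(edges$parent, levels = active)), unique)

  # Kahn topological sort, parents first; leftover terms sit on a cycle.
  n_par <- vapply(parents, length, integer(1))
  queue <- active[n_par == 0L]
  remaining <- n_par
  order <- character(0)
  while (length(queue)) {
    t <- queue[[1]]
    queue <- queue[-1]
    order <- c(order, t)
    for (ch in children[[t]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(active)) {
    cyc <- setdiff(active, order)
    stop("cycle detected in is_a graph involving term: ", cyc[1])
  }

  # one root per namespace
  roots <- character(0)
  for (ns in unique(terms$namespace[!terms$obsolete])) {
    cand <- active[n_par[active] == 0L &
                     terms[active, "namespace"] == ns]
    if (length(cand) > 1) {
      stop("namespace ", ns, " has multiple parentless terms: ",
           paste(cand, collapse = ", "))
    }
    if (length(cand) == 1) roots[[ns]] <- cand
  }
  # every non-root active term needs >= 1 parent in its own namespace
  for (t in active) {
    if (t %in% roots) next
    ps <- parents[[t]]
    if (!length(ps)) {
      stop("namespace ", terms[t, "namespace"],
           " has multiple parentless terms: ",
           paste(sort(c(roots[[terms[t, "namespace"]]], t)), collapse = ", "))
    }
    if (!any(terms[ps, "namespace"] == terms[t, "namespace"])) {
      stop("term ", t, " has no parent in its own namespace")
    }
  }

  anc <- vector("list", length(active))
  names(anc) <- active
  depth <- stats::setNames(integer(length(active)), active)
  for (t in order) {
    ps <- parents[[t]]
    if (!length(ps)) {
      anc[[t]] <- t
      depth[[t]] <- 0L
    } else {
      anc[[t]] <- sort(unique(c(t, unlist(anc[ps], use.names = FALSE))))
      depth[[t]] <- max(depth[ps]) + 1L
    }
  }

  structure(
    list(terms = terms, parents = parents, children = children,
         roots = roots, ancestors = anc, depth = depth),
    class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  act <- sum(!x$terms$obsolete)
  cat("ontology_dag: ", act, " active terms (",
      sum(x$terms$obsolete), " obsolete), ",
      sum(lengths(x$parents)), " is_a edges, namespaces: ",
      paste(sprintf("%s [root %s]", names(x$roots), x$roots),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

term_namespace <- function(dag, term) {
  ns <- dag$terms[term, "namespace"]
  if (is.na(ns)) stop("unknown term: ", term)
  ns
}

#' Reflexive ancestor closure of a term
#'
#' Returns the term itself plus every term reachable by following `is_a`
#' edges up to the namespace root (the "true-path rule" closure).
#'
#' @param dag an [ontology_dag()].
#' @param term a single term id; must exist and not be obsolete.
#' @return Sorted character vector of term ids, including `term`.
#' @export
ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"), length(term) == 1)
  if (!term %in% dag$terms$id) stop("unknown term: ", term)
  if (dag$terms[term, "obsolete"]) stop("obsolete term: ", term)
  dag$ancestors[[term]]
}

#' Direct and transitive descendants of a term
#'
#' @param dag an [ontology_dag()].
#' @param term a single non-obsolete term id.
#' @return Sorted character vector of term ids whose closure contains
#'   `term` (includes `term` itself).
#' @export
descendants <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"), length(term) == 1)
  if (!term %in% names(dag$ancestors)) stop("unknown or obsolete term: ", term)
  hits <- vapply(dag$ancestors, function(a) term %in% a, logical(1))
  sort(names(dag$ancestors)[hits])
}

#' Up-propagate a set of annotated terms
#'
#' The union of reflexive ancestor closures over a term set. Idempotent:
#' propagating a propagated set returns it unchanged.
#'
#' @param dag an [ontology_dag()].
#' @param terms character vector of term ids (possibly empty).
#' @param lenient if `TRUE`, unknown or obsolete ids are skipped with a
#'   warning instead of raising an error (real annotation files contain
#'   retired ids).
#' @return Sorted character vector: the ancestor-closed set.
#' @export
propagate_annotation_set <- function(dag, terms, lenient = FALSE) {
  stopifnot(inherits(dag, "ontology_dag"))
  terms <- unique(as.character(terms))
  if (!length(terms)) return(character(0))
  known <- terms %in% names(dag$ancestors)
  if (!all(known)) {
    if (lenient) {
      warning("skipping ", sum(!known), " unknown/obsolete term id(s): ",
              paste(utils::head(terms[!known], 3), collapse = ", "))
      terms <- terms[known]
      if (!length(terms)) return(character(0))
    } else {
      stop("unknown or obsolete term: ", terms[!known][1])
    }
  }
  sort(unique(unlist(dag$ancestors[terms], use.names = FALSE)))
}

#' Up-propagate prediction scores
#'
#' Every ancestor of a scored term receives the maximum score among the
#' scored terms that imply it, except terms the submitter scored explicitly,
#' which keep their submitted score verbatim even when that breaks the
#' child-below-parent consistency (submitted intent is preserved rather than
#' re-normalized).
#'
#' @param dag an [ontology_dag()].
#' @param scores named numeric vector, term id -> score in (0, 1].
#' @param explicit character vector of term ids submitted verbatim; must be
#'   a subset of `names(scores)`. Defaults to all scored terms.
#' @param lenient skip unknown term ids with a warning instead of erroring.
#' @return Named numeric vector over the ancestor closure of the scored
#'   terms.
#' @export
propagate_prediction_scores <- function(dag, scores,
                                        explicit = names(scores),
                                        lenient = FALSE) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!length(scores)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("scores must be a named vector of term -> score")
  }
  if (any(!is.finite(scores)) || any(scores <= 0 | scores > 1)) {
    stop("prediction scores must lie in (0, 1]")
  }
  if (!all(explicit %in% names(scores))) {
    stop("explicit terms must be a subset of the scored terms")
  }
  known <- names(scores) %in% names(dag$ancestors)
  if (!all(known)) {
    if (lenient) {
      warning("skipping ", sum(!known), " unknown/obsolete scored term(s)")
      scores <- scores[known]
      explicit <- intersect(explicit, names(scores))
      if (!length(scores)) return(stats::setNames(numeric(0), character(0)))
    } else {
      stop("unknown or obsolete term: ", names(scores)[!known][1])
    }
  }
  closure <- unique(unlist(dag$ancestors[names(scores)], use.names = FALSE))
  out <- stats::setNames(rep(0, length(closure)), closure)
  for (t in names(scores)) {
    a <- dag$ancestors[[t]]
    out[a] <- pmax(out[a], scores[[t]])
  }
  out[explicit] <- scores[explicit]
  out
}
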