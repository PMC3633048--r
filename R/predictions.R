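#' Prediction sets: per-algorithm scored term assignments
#'
#' A prediction set maps each target gene to a term -> score map with every
#' score in (0.00, 1.00]. Absence of a (gene, term) pair means
#' non-prediction — a score of 0.00 is never allowed. At most `cap` terms
#' may be scored per gene and namespace (submission rule).
#'
#' @param scores named list, gene id -> named numeric vector
#'   (term id -> score in (0, 1]).
#' @param algorithm label for the predictor.
#' @param explicit named list, gene id -> term ids submitted verbatim
#'   (defaults to all scored terms per gene).
#' @param dag optional [ontology_dag()]; when supplied, the per-namespace
#'   term cap is enforced.
#' @param cap maximum scored terms per gene and namespace (default 1000).
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(scores, algorithm = "predictor", explicit = NULL,
                           dag = NULL, cap = 1000L) {
  stopifnot(is.list(scores))
  scores <- scores[lengths(scores) > 0]
  for (g in names(scores)) {
    s <- scores[[g]]
    if (is.null(names(s)) || any(!nzchar(names(s)))) {
      stop("gene ", g, ": scores must be named by term id")
    }
    if (anyDuplicated(names(s))) {
      stop("gene ", g, ": duplicate term in score map")
    }
    if (any(!is.finite(s)) || any(s <= 0 | s > 1)) {
      stop("gene ", g, ": scores must lie in (0.00, 1.00]")
    }
    if (!is.null(dag)) {
      ns <- dag$terms[names(s), "namespace"]
      per_ns <- table(ns[!is.na(ns)])
      if (any(per_ns > cap)) {
        stop("gene ", g, ": more than ", cap, " scored terms in namespace ",
             names(per_ns)[which(per_ns > cap)[1]])
      }
    }
  }
  if (is.null(explicit)) {
    explicit <- lapply(scores, names)
  } else {
    explicit <- explicit[names(scores)]
    for (g in names(scores)) {
      if (!all(explicit[[g]] %in% names(scores[[g]]))) {
        stop("gene ", g, ": explicit terms must be a subset of scored terms")
      }
    }
  }
  structure(list(algorithm = algorithm, scores = scores, explicit = explicit),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("prediction_set '", x$algorithm, "': ", length(x$scores),
      " targets, ", sum(lengths(x$scores)), " scored (gene, term) pairs\n",
      sep = "")
  invisible(x)
}

#' Read a CAFA-style prediction submission
#'
#' Whitespace-separated three-column lines `<target> <term> <score>`;
#' comment lines start with `#`. Scores must lie in (0.00, 1.00] — the value
#' 0.00 is not allowed and raises an error quoting the offending line, as
#' does a score above 1.00 or a 1001st term for one target in one
#' namespace.
#'
#' @param path file path, or a character string of submission text.
#' @param dag optional [ontology_dag()] used to validate term ids and
#'   enforce the per-namespace cap.
#' @param algorithm label for the resulting [prediction_set()].
#' @param cap per-gene, per-namespace term cap (default 1000).
#' @param lenient skip lines with unknown term ids (warning) instead of
#'   erroring; requires `dag`.
#' @export
read_predictions <- function(path, dag = NULL, algorithm = NULL,
                             cap = 1000L, lenient = FALSE) {
  from_file <- length(path) == 1 && !grepl("\n", path, fixed = TRUE) &&
    file.exists(path)
  lines <- read_lines_or_text(path)
  if (is.null(algorithm)) {
    algorithm <- if (from_file) sub("\\.[^.]*$", "", basename(path)) else "predictor"
  }
  genes <- character(0)
  terms <- character(0)
  vals <- numeric(0)
  skipped <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != 3) {
      stop("prediction parse error at line ", i,
           ": expected 3 whitespace-separated fields, got ", length(f),
           " (\"", ln, "\")")
    }
    sc <- suppressWarnings(as.numeric(f[3]))
    if (is.na(sc)) stop("prediction parse error at line ", i,
                        ": non-numeric score (\"", ln, "\")")
    if (sc == 0) stop("invalid score at line ", i, " (\"", ln,
                      "\"): the value 0.00 is not allowed")
    if (sc < 0 || sc > 1) stop("invalid score at line ", i, " (\"", ln,
                               "\"): scores must lie in (0.00, 1.00]")
    if (!is.null(dag) && !(f[2] %in% names(dag$ancestors))) {
      if (lenient) { skipped <- skipped + 1L; next }
      stop("unknown or obsolete term at line ", i, ": ", f[2])
    }
    genes <- c(genes, f[1]); terms <- c(terms, f[2]); vals <- c(vals, sc)
  }
  if (skipped) warning("skipped ", skipped, " line(s) with unknown term ids")
  scores <- lapply(split(seq_along(genes), genes)[unique(genes)], function(idx) {
    if (anyDuplicated(terms[idx])) {
      stop("duplicate (target, term) pair for target ", genes[idx[1]])
    }
    stats::setNames(vals[idx], terms[idx])
  })
  prediction_set(scores, algorithm = algorithm, dag = dag, cap = cap)
}

#' Write a prediction set as a three-column TSV
#'
#' Scores are rendered with four decimals; reading the output back yields
#' the same scored pairs (up to ordering) for four-decimal scores.
#'
#' @param predset a [prediction_set()].
#' @param path output path; `NULL` returns the lines.
#' @export
write_predictions <- function(predset, path = NULL) {
  stopifnot(inherits(predset, "prediction_set"))
  out <- character(0)
  for (g in sort(names(predset$scores))) {
    s <- predset$scores[[g]]
    ord <- order(-s, names(s))
    out <- c(out, sprintf("%s\t%s\t%.4f", g, names(s)[ord], s[ord]))
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

# Restrict a prediction set's scored terms to one namespace; genes left
# without scored terms are dropped.
filter_predictions <- function(predset, dag, namespace) {
  stopifnot(inherits(predset, "prediction_set"))
  scores <- lapply(predset$scores, function(s) {
    ns <- dag$terms[names(s), "namespace"]
    s[!is.na(ns) & ns == namespace]
  })
  explicit <- lapply(names(scores), function(g) {
    intersect(predset$explicit[[g]], names(scores[[g]]))
  })
  names(explicit) <- names(scores)
  keep <- lengths(scores) > 0
  prediction_set(scores[keep], algorithm = predset$algorithm,
                 explicit = explicit[keep])
}

#' Up-propagate every gene's scores in a prediction set
#'
#' Applies [propagate_prediction_scores()] gene-wise: ancestors of scored
#' terms receive the maximum implied score, explicit submissions keep their
#' value. Assessment is defined over propagated predictions, so this is the
#' form to feed to function-centric metrics and to cross-algorithm
#' aggregation.
#'
#' @param predset a [prediction_set()].
#' @param dag an [ontology_dag()].
#' @return A [prediction_set()] with ancestor-closed score maps (all terms
#'   explicit).
#' @export
propagate_predictions <- function(predset, dag) {
  stopifnot(inherits(predset, "prediction_set"))
  scores <- lapply(names(predset$scores), function(g) {
    propagate_prediction_scores(dag, predset$scores[[g]],
                                explicit = predset$explicit[[g]],
                                lenient = TRUE)
  })
  names(scores) <- names(predset$scores)
  prediction_set(scores, algorithm = predset$algorithm)
}
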