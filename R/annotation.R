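#' Annotation sets: gene -> term assignments
#'
#' The container for gold-standard and prior annotation corpora. Exists in
#' raw form (terms as annotated) and ancestor-closed form (after
#' [propagate_annotations()]). Genes never map to an empty set; evidence-code
#' level detail is carried in the optional `records` data.frame.
#'
#' @param assignments named list, gene id -> character vector of term ids.
#'   Genes with no terms are dropped.
#' @param species optional named character vector, gene id -> taxon label.
#' @param records optional data.frame of annotation records with columns
#'   `gene`, `term`, `evidence`, `species`, `qualifier`; required by
#'   evidence-aware operations such as [select_evaluation_targets()].
#' @param propagated logical; `TRUE` when every gene's set is its own
#'   ancestor closure.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(assignments, species = NULL, records = NULL,
                           propagated = FALSE) {
  stopifnot(is.list(assignments))
  assignments <- lapply(assignments, function(x) sort(unique(as.character(x))))
  assignments <- assignments[lengths(assignments) > 0]
  if (!is.null(species)) species <- species[names(assignments)]
  structure(list(assignments = assignments, species = species,
                 records = records, propagated = isTRUE(propagated)),
            class = "annotation_set")
}

# Build an annotation_set from a records data.frame (one row per
# gene/term/evidence triple).
annotation_from_records <- function(records, propagated = FALSE) {
  if (is.null(records) || nrow(records) == 0) {
    return(annotation_set(list(), records = empty_records()))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  assignments <- lapply(split(records$term, records$gene), unique)
  species <- NULL
  if (!is.null(records$species)) {
    first <- !duplicated(records$gene)
    species <- stats::setNames(records$species[first], records$gene[first])
  }
  annotation_set(assignments, species = species, records = records,
                 propagated = propagated)
}

empty_records <- function() {
  data.frame(gene = character(), term = character(), evidence = character(),
             species = character(), qualifier = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set: ", length(x$assignments), " genes, ",
      length(unique(unlist(x$assignments, use.names = FALSE))), " terms",
      if (isTRUE(x$propagated)) " (propagated)" else " (raw)", "\n", sep = "")
  invisible(x)
}

#' Number of genes in an annotation set
#' @param x an [annotation_set()].
#' @export
n_genes <- function(x) length(x$assignments)

#' Up-propagate every gene's annotations
#'
#' Replaces each gene's term set with its ancestor closure. Annotations to
#' obsolete or unknown terms are dropped with a warning under
#' `lenient = TRUE` (the default, since real files contain retired ids);
#' genes left with no valid terms are removed.
#'
#' @param annset an [annotation_set()].
#' @param dag an [ontology_dag()].
#' @param lenient skip unknown/obsolete term ids with a warning.
#' @return A propagated [annotation_set()] (raw `records` are kept as-is).
#' @export
propagate_annotations <- function(annset, dag, lenient = TRUE) {
  stopifnot(inherits(annset, "annotation_set"))
  closed <- lapply(annset$assignments, function(ts) {
    propagate_annotation_set(dag, ts, lenient = lenient)
  })
  annotation_set(closed, species = annset$species, records = annset$records,
                 propagated = TRUE)
}

#' Restrict an annotation set to one namespace
#'
#' @param annset an [annotation_set()].
#' @param dag an [ontology_dag()].
#' @param namespace "BP", "MF" or "CC".
#' @return An [annotation_set()] whose terms all belong to `namespace`;
#'   genes with no terms left are dropped.
#' @export
filter_namespace <- function(annset, dag, namespace) {
  stopifnot(inherits(annset, "annotation_set"),
            namespace %in% c("BP", "MF", "CC"))
  keep_term <- function(ts) {
    ns <- dag$terms[ts, "namespace"]
    ts[!is.na(ns) & ns == namespace]
  }
  assignments <- lapply(annset$assignments, keep_term)
  records <- annset$records
  if (!is.null(records) && nrow(records)) {
    ns <- dag$terms[records$term, "namespace"]
    records <- records[!is.na(ns) & ns == namespace, , drop = FALSE]
    rownames(records) <- NULL
  }
  annotation_set(assignments, species = annset$species, records = records,
                 propagated = annset$propagated)
}

GAF_ASPECT <- c(BP = "P", MF = "F", CC = "C")

#' Read a GAF 2.x annotation file
#'
#' Parses a tab-separated Gene Association File, keeping rows whose evidence
#' code is in the whitelist and whose aspect matches the requested
#' namespace. Rows with a NOT qualifier are excluded from the positive set.
#' Comment lines start with `!`.
#'
#' @param path GAF file path, or a character string of GAF text.
#' @param evidence_whitelist evidence codes to keep; `NULL` keeps all.
#'   Default is the strong-evidence set `c("EXP", "TAS", "IC")`.
#' @param namespace which ontology aspect to keep ("BP", "MF" or "CC").
#' @return A raw [annotation_set()] with per-record evidence retained.
#' @export
read_gaf <- function(path, evidence_whitelist = c("EXP", "TAS", "IC"),
                     namespace = "BP") {
  stopifnot(namespace %in% names(GAF_ASPECT))
  if (!is.null(evidence_whitelist) && !length(evidence_whitelist)) {
    stop("evidence whitelist must be non-empty (use NULL to keep all codes)")
  }
  lines <- read_lines_or_text(path)
  keep <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "!")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 15 || length(f) > 17) {
      stop("GAF parse error at line ", i, ": expected 15-17 columns, got ",
           length(f))
    }
    if (grepl("\\bNOT\\b", f[4])) next
    if (!is.null(evidence_whitelist) && !(f[7] %in% evidence_whitelist)) next
    if (f[9] != GAF_ASPECT[[namespace]]) next
    keep[[length(keep) + 1]] <- data.frame(
      gene = f[2], term = f[5], evidence = f[7], species = f[13],
      qualifier = f[4], stringsAsFactors = FALSE)
  }
  annotation_from_records(do.call(rbind, keep))
}

#' Write an annotation set as GAF 2.1
#'
#' Requires per-record evidence (`records`); the inverse of [read_gaf()] up
#' to column padding.
#'
#' @param annset an [annotation_set()] carrying `records`.
#' @param dag an [ontology_dag()], used for the aspect column.
#' @param path output path; `NULL` returns the lines.
#' @export
write_gaf <- function(annset, dag, path = NULL) {
  stopifnot(inherits(annset, "annotation_set"))
  r <- annset$records
  if (is.null(r)) stop("annotation set has no evidence records to write")
  ns <- dag$terms[r$term, "namespace"]
  aspect <- GAF_ASPECT[ns]
  rows <- sprintf("DB\t%s\t%s\t%s\t%s\tREF:0\t%s\t\t%s\t\t\tprotein\t%s\t20110101\tontoeval\t\t",
                  r$gene, r$gene, r$qualifier, r$term, r$evidence, aspect,
                  r$species)
  out <- c("!gaf-version: 2.1", rows)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

#' Select waiting-period evaluation targets
#'
#' Genes that received at least one strong-evidence annotation in `after`
#' for a term that was not strongly evidenced in `before` — the genes whose
#' function became "known" during the waiting period and so can serve as
#' evaluation targets.
#'
#' @param before,after raw [annotation_set()]s carrying evidence `records`,
#'   filtered to the same namespace.
#' @param strong_codes evidence codes treated as strong;
#'   default `c("EXP", "TAS", "IC")`.
#' @return Sorted character vector of gene ids.
#' @export
select_evaluation_targets <- function(before, after,
                                      strong_codes = c("EXP", "TAS", "IC")) {
  ra <- after$records
  if (is.null(ra)) stop("'after' annotation set carries no evidence records")
  rb <- before$records
  key <- function(d) paste(d$gene, d$term, sep = "\r")
  strong_before <- if (is.null(rb) || !nrow(rb)) character(0) else {
    key(rb[rb$evidence %in% strong_codes, , drop = FALSE])
  }
  sa <- ra[ra$evidence %in% strong_codes, , drop = FALSE]
  if (!nrow(sa)) return(character(0))
  new <- sa[!(key(sa) %in% strong_before), , drop = FALSE]
  sort(unique(new$gene))
}

#' Restrict an annotation set to a subset of genes
#'
#' @param annset an [annotation_set()].
#' @param genes gene ids to keep.
#' @export
filter_genes <- function(annset, genes) {
  stopifnot(inherits(annset, "annotation_set"))
  assignments <- annset$assignments[intersect(names(annset$assignments), genes)]
  records <- annset$records
  if (!is.null(records) && nrow(records)) {
    records <- records[records$gene %in% genes, , drop = FALSE]
    rownames(records) <- NULL
  }
  annotation_set(assignments, species = annset$species, records = records,
                 propagated = annset$propagated)
}
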