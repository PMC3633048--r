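# OBO 1.2 flat-file reading/writing. Only the subset of the format the
# evaluation needs: [Term] stanzas with id, name, namespace, is_a,
# relationship: part_of and is_obsolete. Typedefs, intersections and
# cross-products are out of scope.

NAMESPACE_MAP <- c(biological_process = "BP", molecular_function = "MF",
                   cellular_component = "CC", BP = "BP", MF = "MF", CC = "CC")

#' Load an ontology from OBO text
#'
#' Parses OBO 1.2-style `[Term]` stanzas into an [ontology_dag()]. Obsolete
#' terms are retained as metadata but excluded from all edges and closure
#' queries. By default only `is_a` edges are used; `part_of` relationships
#' are parsed and can be included as edges via `use_part_of = TRUE`.
#'
#' @param path path to an OBO file, or a character string containing OBO
#'   text (detected by embedded newlines).
#' @param use_part_of include `relationship: part_of` pairs as edges.
#' @return An [ontology_dag()].
#' @export
load_obo <- function(path, use_part_of = FALSE) {
  lines <- read_lines_or_text(path)
  lines <- sub("\\s+$", "", lines)

  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1]] <- cur
    terms
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) {
        cur <- list(id = NULL, name = NA_character_, namespace = NA_character_,
                    obsolete = FALSE, is_a = character(0),
                    part_of = character(0))
      }
      next
    }
    if (!in_term || !nzchar(ln)) next
    tag <- sub(":.*$", "", ln)
    val <- sub("^[^:]+:\\s*", "", ln)
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "namespace") cur$namespace <- val
    else if (tag == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (tag == "is_obsolete") cur$obsolete <- identical(tolower(val), "true")
    else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        cur$part_of <- c(cur$part_of, parts[2])
      }
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no [Term] stanzas found in OBO input")

  ns_raw <- vapply(terms, function(t) t$namespace, character(1))
  ns <- unname(NAMESPACE_MAP[ns_raw])
  if (anyNA(ns)) {
    stop("term ", terms[[which(is.na(ns))[1]]]$id,
         " has a missing or unrecognized namespace tag")
  }
  tdf <- data.frame(
    id = vapply(terms, function(t) t$id, character(1)),
    name = vapply(terms, function(t) t$name, character(1)),
    namespace = ns,
    obsolete = vapply(terms, function(t) t$obsolete, logical(1)),
    stringsAsFactors = FALSE)

  edge_list <- lapply(terms, function(t) {
    ps <- t$is_a
    if (use_part_of) ps <- c(ps, t$part_of)
    if (!length(ps)) return(NULL)
    data.frame(child = t$id, parent = ps, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_list)
  ontology_dag(tdf, edges)
}

#' Serialize an ontology to OBO text
#'
#' @param dag an [ontology_dag()].
#' @param path output file path; if `NULL` the OBO text is returned as a
#'   character vector of lines.
#' @export
write_obo <- function(dag, path = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  ns_long <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    stanza <- c("[Term]",
                paste0("id: ", t$id),
                paste0("name: ", t$name),
                paste0("namespace: ", ns_long[[t$namespace]]))
    if (isTRUE(t$obsolete)) {
      stanza <- c(stanza, "is_obsolete: true")
    } else {
      for (p in dag$parents[[t$id]]) stanza <- c(stanza, paste0("is_a: ", p))
    }
    out <- c(out, stanza, "")
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}
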