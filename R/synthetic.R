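# Synthetic benchmark worlds: ontology, annotation corpus, waiting-period
# gold-standard update, and simulated predictor families with known ground
# truth. Everything is deterministic under a single integer seed, which
# fans out to per-component sub-seeds so adding a predictor never perturbs
# corpus generation.

# sample() without the length-1 surprise
sample_safe <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Generate a random layered ontology
#'
#' One rooted DAG per namespace: the root sits on layer 0, every other term
#' is assigned to a strictly deeper layer and receives 1..`max_parents`
#' parents drawn from strictly shallower layers of the same namespace, which
#' guarantees acyclicity and a single root by construction.
#'
#' @param n_terms terms per namespace (>= 1).
#' @param max_parents maximum parents per non-root term.
#' @param namespaces character vector from `c("BP", "MF", "CC")`.
#' @param depth number of layers below the root.
#' @param seed integer seed.
#' @return An [ontology_dag()].
#' @export
generate_ontology <- function(n_terms = 300L, max_parents = 3L,
                              namespaces = c("BP", "MF"), depth = 6L,
                              seed = 1L) {
  if (n_terms < 1) stop("n_terms must be >= 1 per namespace")
  if (max_parents < 1 || depth < 1) stop("max_parents and depth must be >= 1")
  set.seed(seed)
  tdfs <- list()
  edfs <- list()
  offset <- 0L
  for (ns in namespaces) {
    ids <- sprintf("GO:%07d", offset + seq_len(n_terms))
    offset <- offset + n_terms
    layer <- integer(n_terms)
    if (n_terms > 1) {
      d <- min(depth, n_terms - 1L)
      layer[2:(1 + d)] <- seq_len(d)  # keep every layer inhabited
      if (n_terms > 1 + d) {
        layer[(2 + d):n_terms] <- sample_safe(seq_len(d), n_terms - 1L - d,
                                              replace = TRUE)
      }
      for (i in 2:n_terms) {
        cand <- ids[layer < layer[i]]
        k <- sample.int(min(max_parents, length(cand)), 1)
        edfs[[length(edfs) + 1]] <- data.frame(
          child = ids[i], parent = sample_safe(cand, k),
          stringsAsFactors = FALSE)
      }
    }
    tdfs[[ns]] <- data.frame(
      id = ids, name = sprintf("synthetic %s term %d", ns, seq_len(n_terms)),
      namespace = ns, obsolete = FALSE, stringsAsFactors = FALSE)
  }
  ontology_dag(do.call(rbind, tdfs),
               if (length(edfs)) do.call(rbind, edfs) else NULL)
}

#' Generate a synthetic annotation corpus
#'
#' Per-gene raw term counts are heavy-tailed (1 + geometric with mean
#' `mf_dispersion`), emulating gene multifunctionality; terms are drawn
#' biased towards leaves (weight (depth+1)^2). Species labels are assigned
#' round-robin over `n_species` taxa; with `species_skew > 0` each species
#' prefers its own random 20% subset of terms, emulating species-specific
#' curation bias. Each record gets an IEA evidence code with probability
#' `iea_fraction`, otherwise a strong code (EXP/TAS/IC).
#'
#' @param dag an [ontology_dag()].
#' @param n_genes number of genes (>= 1).
#' @param mf_dispersion mean raw terms per gene (>= 1); 1 gives exactly one
#'   raw term per gene.
#' @param n_species number of taxa.
#' @param species_skew in \[0, 1\]; 0 disables per-species term-usage skew.
#' @param iea_fraction fraction of records with weak (IEA) evidence.
#' @param seed integer seed.
#' @return A raw [annotation_set()] with evidence records.
#' @export
generate_corpus <- function(dag, n_genes = 2000L, mf_dispersion = 4,
                            n_species = 4L, species_skew = 0,
                            iea_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (mf_dispersion < 1) stop("mf_dispersion must be >= 1")
  set.seed(seed)
  active <- dag$terms$id[!dag$terms$obsolete]
  pool <- setdiff(active, dag$roots)
  if (!length(pool)) stop("ontology has no non-root terms to annotate")
  w <- (as.numeric(dag$depth[pool]) + 1)^2
  genes <- sprintf("G%05d", seq_len(n_genes))
  taxa <- sprintf("taxon:%d", 9000 + seq_len(n_species))
  species <- taxa[(seq_len(n_genes) - 1L) %% n_species + 1L]
  pref <- lapply(seq_len(n_species), function(i) {
    sample_safe(pool, max(1L, floor(length(pool) * 0.2)))
  })
  counts <- 1L + stats::rgeom(n_genes, 1 / mf_dispersion)
  recs <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    wi <- w
    if (species_skew > 0) {
      sp_i <- (i - 1L) %% n_species + 1L
      boost <- pool %in% pref[[sp_i]]
      wi[boost] <- wi[boost] * (1 + 9 * species_skew)
    }
    k <- min(counts[i], length(pool))
    ts <- sample_safe(pool, k, prob = wi)
    ev <- ifelse(stats::runif(k) < iea_fraction, "IEA",
                 sample_safe(c("EXP", "TAS", "IC"), k, replace = TRUE))
    recs[[i]] <- data.frame(gene = genes[i], term = ts, evidence = ev,
                            species = species[i], qualifier = "",
                            stringsAsFactors = FALSE)
  }
  annotation_from_records(do.call(rbind, recs))
}

#' Generate a waiting-period gold-standard update
#'
#' Selects genes to receive new strong-evidence annotations, emulating the
#' set of targets whose function became known during the assessment's
#' waiting period. With probability `confirmation_bias` a new strong term is
#' an "upgrade" of one of the gene's existing weak (IEA) annotations — the
#' confirmation-bias mechanism by which already-annotated genes attract
#' experimental confirmation — otherwise a fresh term near the gene's
#' existing closure (a child of a closure term, i.e. a sibling or
#' refinement) is chosen so that semantic-similarity metrics have signal.
#'
#' @param dag an [ontology_dag()].
#' @param corpus the raw prior corpus from [generate_corpus()].
#' @param n_targets genes to update (<= corpus genes).
#' @param confirmation_bias probability in \[0, 1\] of upgrading an existing
#'   IEA term.
#' @param mean_new_terms mean number of new strong terms per gene (>= 1).
#' @param seed integer seed.
#' @return A raw [annotation_set()] of strong-evidence additions; every
#'   gene passes [select_evaluation_targets()] by construction.
#' @export
generate_gold_update <- function(dag, corpus, n_targets = 200L,
                                 confirmation_bias = 0.3,
                                 mean_new_terms = 2, seed = 1L) {
  stopifnot(inherits(corpus, "annotation_set"))
  genes <- names(corpus$assignments)
  if (n_targets > length(genes)) stop("n_targets exceeds corpus size")
  set.seed(seed)
  strong_codes <- c("EXP", "TAS", "IC")
  rec <- corpus$records
  iea_pool <- split(rec$term[rec$evidence == "IEA"],
                    rec$gene[rec$evidence == "IEA"])
  strong_before <- split(rec$term[rec$evidence %in% strong_codes],
                         rec$gene[rec$evidence %in% strong_codes])
  cand_genes <- if (confirmation_bias >= 1) {
    intersect(genes, names(iea_pool))
  } else genes
  if (n_targets > length(cand_genes)) {
    stop("not enough candidate genes with IEA annotations for upgrades")
  }
  targets <- sample_safe(cand_genes, n_targets)
  active <- setdiff(dag$terms$id[!dag$terms$obsolete], dag$roots)
  out <- vector("list", length(targets))
  for (gi in seq_along(targets)) {
    g <- targets[[gi]]
    closure <- propagate_annotation_set(dag, corpus$assignments[[g]],
                                        lenient = TRUE)
    avoid <- c(strong_before[[g]], character(0))
    n_new <- 1L + stats::rpois(1, max(0, mean_new_terms - 1))
    picked <- character(0)
    for (j in seq_len(n_new)) {
      up_pool <- setdiff(iea_pool[[g]], c(avoid, picked))
      t <- NULL
      if (stats::runif(1) < confirmation_bias && length(up_pool)) {
        t <- sample_safe(up_pool, 1)
      } else if (confirmation_bias >= 1) {
        if (!length(up_pool)) break
        t <- sample_safe(up_pool, 1)
      } else {
        near <- unique(unlist(dag$children[closure], use.names = FALSE))
        near <- setdiff(near, c(avoid, picked, dag$roots))
        t <- if (length(near)) sample_safe(near, 1) else {
          sample_safe(setdiff(active, c(avoid, picked)), 1)
        }
      }
      picked <- c(picked, t)
    }
    if (!length(picked)) next
    out[[gi]] <- data.frame(
      gene = g, term = picked,
      evidence = sample_safe(strong_codes, length(picked), replace = TRUE),
      species = corpus$species[[g]] %||% "taxon:0", qualifier = "",
      stringsAsFactors = FALSE)
  }
  annotation_from_records(do.call(rbind, out))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Simulate a predictor of a given family
#'
#' Families:
#' \describe{
#'   \item{noisy_oracle}{scores the gene's true new (gold) terms highly,
#'     with a `noise` fraction replaced by random same-namespace terms and
#'     scores jittered in (0.5, 1].}
#'   \item{homology_copy}{copies the prior annotations of a designated
#'     "homolog" (the corpus gene sharing the most raw terms), ancestor
#'     closed at score 1.0, emulating IEA-style carry-over from sequence
#'     similarity.}
#'   \item{prevalence_mimic}{exactly reproduces the prevalence null.}
#'   \item{binary_oracle}{a noisy oracle whose scores are all snapped to
#'     1.0 (binary-score submissions).}
#' }
#'
#' @param dag an [ontology_dag()].
#' @param corpus the raw prior corpus.
#' @param gold the raw gold-standard update (defines the target genes).
#' @param family one of the four family names.
#' @param noise in \[0, 1\]; used by the oracle families.
#' @param seed integer seed.
#' @param algorithm label; defaults to the family name.
#' @return A [prediction_set()].
#' @export
simulate_predictor <- function(dag, corpus, gold,
                               family = c("noisy_oracle", "homology_copy",
                                          "prevalence_mimic",
                                          "binary_oracle"),
                               noise = 0.2, seed = 1L, algorithm = NULL) {
  family <- match.arg(family)
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]")
  if (is.null(algorithm)) algorithm <- family
  set.seed(seed)
  targets <- names(gold$assignments)
  active <- dag$terms$id[!dag$terms$obsolete]
  ns_pool <- split(setdiff(active, dag$roots),
                   dag$terms[setdiff(active, dag$roots), "namespace"])

  if (family %in% c("noisy_oracle", "binary_oracle")) {
    scores <- list()
    for (g in targets) {
      truth <- gold$assignments[[g]]
      terms <- truth
      repl <- stats::runif(length(terms)) < noise
      for (idx in which(repl)) {
        ns <- dag$terms[terms[idx], "namespace"]
        terms[idx] <- sample_safe(ns_pool[[ns]], 1)
      }
      vals <- stats::runif(length(terms), 0.5, 1)
      if (family == "binary_oracle") vals <- rep(1.0, length(terms))
      s <- tapply(vals, terms, max)
      scores[[g]] <- stats::setNames(as.numeric(s), names(s))
    }
    return(prediction_set(scores, algorithm = algorithm))
  }

  if (family == "homology_copy") {
    gene_terms <- corpus$assignments
    term_index <- list()
    for (g in names(gene_terms)) {
      for (t in gene_terms[[g]]) term_index[[t]] <- c(term_index[[t]], g)
    }
    scores <- list()
    for (g in targets) {
      cands <- setdiff(unique(unlist(term_index[gene_terms[[g]]],
                                     use.names = FALSE)), g)
      if (!length(cands)) next
      overlap <- vapply(cands, function(h) {
        length(intersect(gene_terms[[h]], gene_terms[[g]]))
      }, integer(1))
      homolog <- sort(cands[overlap == max(overlap)])[1]
      closed <- propagate_annotation_set(dag, gene_terms[[homolog]],
                                         lenient = TRUE)
      if (!length(closed)) next
      scores[[g]] <- stats::setNames(rep(1.0, length(closed)), closed)
    }
    return(prediction_set(scores, algorithm = algorithm))
  }

  # prevalence_mimic
  prev <- prevalence_predictor(propagate_annotations(corpus, dag),
                               dag, targets = targets)
  prediction_set(prev$scores, algorithm = algorithm)
}

#' Generate a complete benchmark world
#'
#' Ontology, prior annotation corpus (mixed evidence including IEA),
#' waiting-period gold-standard update, and a family of simulated
#' predictors, all derived deterministically from one integer seed. The
#' defaults are desk-scale stand-ins for a full assessment: 300 terms per
#' namespace, 2000 genes, 200 evaluation targets.
#'
#' @param seed master integer seed; fans out to per-component sub-seeds.
#' @param n_terms terms per namespace.
#' @param n_genes corpus genes.
#' @param n_targets evaluation targets receiving gold updates.
#' @param namespaces namespaces to generate.
#' @param max_parents,depth ontology shape knobs.
#' @param mf_dispersion,n_species,species_skew,iea_fraction corpus knobs.
#' @param confirmation_bias,mean_new_terms gold-update knobs.
#' @param predictors list of `list(family =, noise =)` specs; labels are
#'   `family` or `family_noise` when duplicated.
#' @return An object of class `benchmark_world` with elements `dag`,
#'   `corpus_before`, `gold_update`, `predictors`, `truth_params`, `seed`.
#' @export
generate_benchmark_world <- function(seed = 1L, n_terms = 300L,
                                     n_genes = 2000L, n_targets = 200L,
                                     namespaces = c("BP", "MF"),
                                     max_parents = 3L, depth = 6L,
                                     mf_dispersion = 4, n_species = 4L,
                                     species_skew = 0, iea_fraction = 0.8,
                                     confirmation_bias = 0.3,
                                     mean_new_terms = 2,
                                     predictors = default_predictor_specs()) {
  set.seed(seed)
  ss <- sample.int(2^31 - 2, 3 + length(predictors))
  dag <- generate_ontology(n_terms, max_parents, namespaces, depth,
                           seed = ss[1])
  corpus <- generate_corpus(dag, n_genes, mf_dispersion, n_species,
                            species_skew, iea_fraction, seed = ss[2])
  gold <- generate_gold_update(dag, corpus, n_targets, confirmation_bias,
                               mean_new_terms, seed = ss[3])
  labels <- vapply(predictors, function(p) p$family, character(1))
  dup <- labels %in% labels[duplicated(labels)]
  labels[dup] <- sprintf("%s_%g", labels[dup],
                         vapply(predictors[dup], function(p) p$noise %||% 0,
                                numeric(1)))
  preds <- vector("list", length(predictors))
  for (i in seq_along(predictors)) {
    p <- predictors[[i]]
    preds[[i]] <- simulate_predictor(dag, corpus, gold, family = p$family,
                                     noise = p$noise %||% 0,
                                     seed = ss[3 + i], algorithm = labels[i])
  }
  names(preds) <- labels
  structure(
    list(dag = dag, corpus_before = corpus, gold_update = gold,
         predictors = preds,
         truth_params = list(
           seed = seed, n_terms = n_terms, n_genes = n_genes,
           n_targets = n_targets, namespaces = namespaces,
           mf_dispersion = mf_dispersion, n_species = n_species,
           species_skew = species_skew, iea_fraction = iea_fraction,
           confirmation_bias = confirmation_bias,
           mean_new_terms = mean_new_terms,
           predictors = Map(function(p, l) {
             list(label = l, family = p$family, noise = p$noise %||% 0)
           }, predictors, labels)),
         seed = seed),
    class = "benchmark_world")
}

#' Default simulated predictor roster
#'
#' One representative of each family: two noisy oracles at different noise
#' levels, a homology copier, a prevalence mimic and a binary-score oracle.
#' @export
default_predictor_specs <- function() {
  list(list(family = "noisy_oracle", noise = 0.1),
       list(family = "noisy_oracle", noise = 0.4),
       list(family = "homology_copy", noise = 0),
       list(family = "prevalence_mimic", noise = 0),
       list(family = "binary_oracle", noise = 0.2))
}

#' @export
print.benchmark_world <- function(x, ...) {
  cat("benchmark_world (seed ", x$seed, "): ",
      sum(!x$dag$terms$obsolete), " terms, ",
      n_genes(x$corpus_before), " genes, ",
      n_genes(x$gold_update), " evaluation targets, ",
      length(x$predictors), " predictors [",
      paste(names(x$predictors), collapse = ", "), "]\n", sep = "")
  invisible(x)
}
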