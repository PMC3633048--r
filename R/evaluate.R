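#' Evaluate prediction sets against a gold standard
#'
#' Runs the full assessment for one namespace: the gene-centric
#' precision/recall score (average precision over the up-propagated
#' prediction/truth sets), the function-centric AUROC over terms with an
#' evaluable number of members, and the information-content informativeness
#' of each algorithm's top predictions against the prevalence-null
#' threshold tau.
#'
#' @param dag an [ontology_dag()].
#' @param gold the gold-standard [annotation_set()] restricted to the
#'   evaluation genes (raw or propagated; propagated internally).
#' @param predsets list of [prediction_set()]s to evaluate.
#' @param prior optional raw prior annotation corpus (with evidence
#'   records). Needed for information content, the prevalence null and the
#'   carry-forward baseline; without it the informativeness block is
#'   skipped.
#' @param namespace restrict evaluation to one namespace ("BP"/"MF"/"CC");
#'   `NULL` evaluates terms of all namespaces together.
#' @param top_n top-N submitted terms treated as proposed functions for the
#'   informativeness measure (default 10).
#' @param measure similarity measure for informativeness: "resnik"
#'   (default) or "lin".
#' @param ap_missing policy for genes without predictions: "zero"
#'   (contribute 0, default) or "exclude".
#' @param term_min,term_max member-count window for AUROC-evaluable terms
#'   (defaults 10 and 100).
#' @param include_baselines add the prevalence and IEA carry-forward
#'   baselines (requires `prior`).
#' @return An `evaluation_report`: list with `per_gene` (gene, algorithm,
#'   ap, info_score, informative), `per_term` (term, algorithm, n_pos,
#'   n_neg, auroc), `summary` (per-algorithm means), `tau`,
#'   `evaluable_terms`, `genes` and `multifunctionality`.
#' @export
evaluate_predictions <- function(dag, gold, predsets, prior = NULL,
                                 namespace = NULL, top_n = 10L,
                                 measure = c("resnik", "lin"),
                                 ap_missing = c("zero", "exclude"),
                                 term_min = 10L, term_max = 100L,
                                 include_baselines = TRUE) {
  measure <- match.arg(measure)
  ap_missing <- match.arg(ap_missing)
  stopifnot(inherits(dag, "ontology_dag"), inherits(gold, "annotation_set"))
  if (!is.list(predsets) || inherits(predsets, "prediction_set")) {
    predsets <- list(predsets)
  }

  if (!is.null(namespace)) {
    gold <- filter_namespace(gold, dag, namespace)
    if (!is.null(prior)) prior <- filter_namespace(prior, dag, namespace)
    predsets <- lapply(predsets, filter_predictions, dag = dag,
                       namespace = namespace)
    predsets <- predsets[vapply(predsets, function(p) length(p$scores) > 0,
                                logical(1))]
  }
  if (!isTRUE(gold$propagated)) gold <- propagate_annotations(gold, dag)
  eval_genes <- names(gold$assignments)
  if (!length(eval_genes)) stop("no evaluation genes in gold standard")

  ic <- NULL
  prevalence <- NULL
  prior_prop <- NULL
  if (!is.null(prior)) {
    prior_prop <- if (isTRUE(prior$propagated)) prior else {
      propagate_annotations(prior, dag)
    }
    ic <- information_content(dag, prior_prop)
    prevalence <- prevalence_predictor(prior_prop, dag, targets = eval_genes)
    if (include_baselines) {
      predsets <- c(predsets, list(prevalence))
      cf <- iea_carryforward_predictor(prior, dag, codes = "IEA",
                                       targets = eval_genes)
      if (length(cf$scores)) predsets <- c(predsets, list(cf))
    }
  }
  labels <- vapply(predsets, function(p) p$algorithm, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate algorithm labels: ", labels[duplicated(labels)][1])
  }

  truths <- gold$assignments

  # ---- gene-centric: AP per gene per algorithm -------------------------
  per_gene <- list()
  for (p in predsets) {
    ap <- info <- stats::setNames(rep(NA_real_, length(eval_genes)),
                                  eval_genes)
    ipt <- stats::setNames(rep(NA_character_, length(eval_genes)), eval_genes)
    for (g in eval_genes) {
      s <- p$scores[[g]]
      if (!is.null(s) && length(s)) {
        ap[[g]] <- average_precision(gene_pr_curve(dag, s, truths[[g]]))
      }
      if (!is.null(ic)) {
        r <- informativeness_score(dag, ic, s %||% numeric(0), truths[[g]],
                                   top_n = top_n, measure = measure)
        info[[g]] <- r$score
        ipt[[g]] <- r$pred_term
      }
    }
    per_gene[[p$algorithm]] <- data.frame(
      gene = eval_genes, algorithm = p$algorithm, ap = unname(ap),
      info_score = unname(info), info_pred_term = unname(ipt),
      stringsAsFactors = FALSE)
  }

  # ---- informativeness threshold ---------------------------------------
  tau <- NA_real_
  if (!is.null(ic)) {
    tau <- informativeness_threshold(dag, ic, prevalence, truths,
                                     top_n = top_n, measure = measure)
    for (a in names(per_gene)) {
      per_gene[[a]]$informative <- !is.na(per_gene[[a]]$info_score) &
        per_gene[[a]]$info_score > tau
    }
  }

  # ---- function-centric: AUROC per evaluable term ----------------------
  evaluable <- select_evaluable_terms(gold, term_min, term_max)
  per_term <- list()
  for (p in predsets) {
    prop <- lapply(p$scores[intersect(names(p$scores), eval_genes)],
                   function(s) {
                     propagate_prediction_scores(dag, s, lenient = TRUE)
                   })
    rows <- lapply(evaluable, function(t) {
      labelsv <- vapply(eval_genes, function(g) t %in% truths[[g]],
                        logical(1))
      names(labelsv) <- eval_genes
      sc <- vapply(names(prop), function(g) {
        v <- prop[[g]]
        if (t %in% names(v)) v[[t]] else NA_real_
      }, numeric(1))
      sc <- sc[!is.na(sc)]
      r <- term_auroc(sc, labelsv)
      data.frame(term = t, algorithm = p$algorithm, n_pos = r$n_pos,
                 n_neg = r$n_neg, auroc = r$auroc, stringsAsFactors = FALSE)
    })
    per_term[[p$algorithm]] <- do.call(rbind, rows)
  }

  # ---- summary ---------------------------------------------------------
  summary_rows <- lapply(predsets, function(p) {
    pg <- per_gene[[p$algorithm]]
    pt <- per_term[[p$algorithm]]
    ap_vec <- stats::setNames(pg$ap, pg$gene)
    data.frame(
      algorithm = p$algorithm,
      n_genes = length(eval_genes),
      mean_ap = cafa_score_summary(ap_vec, missing = ap_missing),
      mean_auroc = if (!is.null(pt) && any(!is.na(pt$auroc))) {
        mean(pt$auroc, na.rm = TRUE)
      } else NA_real_,
      informativeness_rate = if (!is.null(ic)) {
        informativeness_rate(ifelse(is.na(pg$info_score), 0, pg$info_score),
                             tau)
      } else NA_real_,
      tau = tau, stringsAsFactors = FALSE)
  })

  # ---- multifunctionality diagnostics ----------------------------------
  mf <- NULL
  if (!is.null(prior_prop) && length(evaluable)) {
    term_mf <- vapply(evaluable, function(t) {
      members <- eval_genes[vapply(eval_genes, function(g) t %in% truths[[g]],
                                   logical(1))]
      mean(vapply(members, function(g) {
        multifunctionality_score(prior_prop, g)
      }, numeric(1)))
    }, numeric(1))
    gains <- unlist(lapply(per_gene, function(pg) {
      pg$info_pred_term[!is.na(pg$informative) & pg$informative]
    }), use.names = FALSE)
    gain_tab <- table(gains[!is.na(gains)])
    gain_counts <- stats::setNames(as.numeric(gain_tab), names(gain_tab))
    corr <- NA_real_
    common <- intersect(names(term_mf), names(gain_counts))
    if (length(common) >= 3) {
      # zero-variance inputs (e.g. all gains equal) leave the rank
      # correlation undefined; report NA rather than warn
      corr <- suppressWarnings(
        multifunctionality_correlation(term_mf, gain_counts))
    }
    mf <- list(term_mf = term_mf, gain_counts = gain_counts,
               correlation = corr)
  }

  structure(
    list(per_gene = do.call(rbind, c(per_gene, make.row.names = FALSE)),
         per_term = do.call(rbind, c(per_term, make.row.names = FALSE)),
         summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)),
         tau = tau, evaluable_terms = evaluable, genes = eval_genes,
         multifunctionality = mf),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report: ", length(x$genes), " genes, ",
      length(x$evaluable_terms), " evaluable terms",
      if (!is.na(x$tau)) sprintf(", tau = %.3f", x$tau), "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Evaluate a synthetic benchmark world
#'
#' Convenience wrapper: runs [evaluate_predictions()] for one namespace of a
#' [generate_benchmark_world()] output, using the world's prior corpus for
#' information content and baselines and its gold update as truth.
#'
#' @param world a `benchmark_world`.
#' @param namespace namespace to evaluate (default "BP").
#' @param ... passed to [evaluate_predictions()].
#' @export
evaluate_world <- function(world, namespace = "BP", ...) {
  stopifnot(inherits(world, "benchmark_world"))
  evaluate_predictions(world$dag, world$gold_update,
                       unname(world$predictors),
                       prior = world$corpus_before,
                       namespace = namespace, ...)
}

#' Write an evaluation report as TSV tables
#'
#' Emits `per_gene.tsv`, `per_term.tsv` and `summary.tsv` under `dir`, plus
#' an optional `summary.json`.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @param json also write a JSON summary.
#' @export
write_report <- function(report, dir, json = TRUE) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(report$per_gene, "per_gene.tsv")
  if (!is.null(report$per_term)) tsv(report$per_term, "per_term.tsv")
  tsv(report$summary, "summary.tsv")
  if (json) {
    jsonlite::write_json(
      list(summary = report$summary, tau = report$tau,
           n_genes = length(report$genes),
           n_evaluable_terms = length(report$evaluable_terms)),
      file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(dir)
}
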