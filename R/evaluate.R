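# Evaluation machinery: confusion-based metrics, nested cross-validation,
# leave-one-feature-family-out ablation, inter-annotator agreement and
# retrieval comparison against reference PMID lists.

#' Per-node confusion counts
#'
#' Gold label sets are closed upward over the taxonomy before comparison
#' (a document annotated at a sub-node is gold-positive for every
#' ancestor). A document is a true positive if the node is in both the
#' predicted and gold set, a false positive if predicted only, a false
#' negative if gold only, and a true negative otherwise.
#'
#' @param pred a `prediction_set` (or named list pmid -> label sets).
#' @param gold an [annotation_set()] over the same pmids.
#' @param node node slug or display name.
#' @param taxonomy an `exposure_taxonomy`.
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(pred, gold, node, taxonomy) {
  node <- resolve_node(taxonomy, node)
  pp <- names(pred)
  gp <- names(gold$labels)
  if (!setequal(pp, gp)) {
    diff <- c(setdiff(pp, gp), setdiff(gp, pp))
    stop("prediction/gold pmid mismatch: ",
         paste(utils::head(diff, 10L), collapse = ", "), call. = FALSE)
  }
  in_pred <- vapply(pp, function(p) node %in% pred[[p]], TRUE)
  in_gold <- vapply(pp, function(p) {
    node %in% propagate_labels(taxonomy, gold$labels[[p]])
  }, TRUE)
  c(tp = sum(in_pred & in_gold), fp = sum(in_pred & !in_gold),
    fn = sum(!in_pred & in_gold), tn = sum(!in_pred & !in_gold))
}

#' Standard metrics from confusion counts
#'
#' precision = tp/(tp+fp), recall = tp/(tp+fn), accuracy = (tp+tn)/total,
#' F = 2PR/(P+R). A ratio with a zero denominator is reported as 0 and the
#' corresponding `defined` flag is cleared; rare nodes make this reachable.
#'
#' @param counts named vector with `tp`, `fp`, `fn`, `tn` (total > 0).
#' @return List of class `node_metrics`: `precision`, `recall`, `accuracy`,
#'   `f_score` (fractions in `[0, 1]`), plus logical `defined` flags per
#'   metric.
#' @export
node_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  total <- tp + fp + fn + tn
  check(total > 0, "all-zero confusion counts")
  check(all(c(tp, fp, fn, tn) >= 0), "negative confusion counts")
  p_def <- (tp + fp) > 0
  r_def <- (tp + fn) > 0
  precision <- if (p_def) tp / (tp + fp) else 0
  recall <- if (r_def) tp / (tp + fn) else 0
  f_def <- p_def && r_def && (precision + recall) > 0
  f <- if (f_def) 2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall,
                 accuracy = (tp + tn) / total, f_score = f,
                 defined = c(precision = p_def, recall = r_def,
                             accuracy = TRUE, f_score = f_def)),
            class = "node_metrics")
}

#' @export
print.node_metrics <- function(x, ...) {
  cat(sprintf("P=%.1f%% R=%.1f%% A=%.1f%% F=%.1f%%\n", 100 * x$precision,
              100 * x$recall, 100 * x$accuracy, 100 * x$f_score))
  invisible(x)
}

# Shared core: outer k-fold rotation over precomputed per-document feature
# sets. Vocabulary building, feature selection and hyperparameter tuning
# happen inside each training split only.
.cv_core <- function(feature_sets, annotations, taxonomy, k, seed, config) {
  pmids <- names(feature_sets)
  folds <- split_folds(pmids, k = k, seed = seed)$assignment
  nodes <- taxonomy_nodes(taxonomy, order = "traversal")
  counts <- matrix(0L, nrow = length(nodes), ncol = 4L,
                   dimnames = list(nodes, c("tp", "fp", "fn", "tn")))
  folds_trained <- stats::setNames(integer(length(nodes)), nodes)
  per_fold <- list()
  for (f in 0:(k - 1L)) {
    tr <- pmids[folds != f]
    te <- pmids[folds == f]
    fit <- suppressWarnings(
      .train_on_features(feature_sets[tr], annotations, taxonomy, config,
                         seed = seed))
    pred <- .predict_on_features(fit, feature_sets[te])
    gold_te <- annotation_set(annotations$labels[te], taxonomy,
                              annotator = annotations$annotator)
    fold_counts <- matrix(NA_integer_, nrow = length(nodes), ncol = 4L,
                          dimnames = dimnames(counts))
    for (nd in names(fit$nodes)) {
      cc <- confusion_counts(pred, gold_te, nd, taxonomy)
      counts[nd, ] <- counts[nd, ] + cc
      fold_counts[nd, ] <- cc
      folds_trained[nd] <- folds_trained[nd] + 1L
    }
    per_fold[[f + 1L]] <- fold_counts
  }
  list(counts = counts, folds_trained = folds_trained, per_fold = per_fold)
}

# exposure_classifier() on precomputed feature sets (skips NLP re-runs)
.train_on_features <- function(feature_sets, annotations, taxonomy, config,
                               seed) {
  feats <- .filter_families(feature_sets, config$families)
  nodes <- taxonomy_nodes(taxonomy, order = "traversal")
  fitted <- list()
  skipped <- character(0)
  for (nd in nodes) {
    ts <- assemble_training_set(feats, annotations, nd, taxonomy)
    npos <- sum(ts$y)
    if (npos == 0L || npos == length(ts$y)) {
      skipped <- c(skipped, nd)
      next
    }
    vocab <- build_vocabulary(feats, node = nd, thresholds = config$thresholds,
                              families = config$families)
    x <- encode_features(feats, vocab)
    hp <- if (length(config$cost_grid) * length(config$gamma_grid) > 1L) {
      tune_hyperparameters(x, ts$y, config$cost_grid, config$gamma_grid,
                           config$inner_k, seed = seed,
                           class_weights = config$class_weights)
    } else {
      list(cost = config$cost_grid[1L], gamma = config$gamma_grid[1L],
           mean_f = NA_real_)
    }
    model <- .fit_rbf_svm(x, ts$y, hp$cost, hp$gamma, config$class_weights)
    fitted[[nd]] <- list(node = nd, vocab = vocab, model = model,
                         n_pos = npos, n_neg = length(ts$y) - npos,
                         inner_f = hp$mean_f)
  }
  structure(list(taxonomy = taxonomy, nodes = fitted, skipped = skipped,
                 config = config,
                 manifest = list(seed = as.integer(seed),
                                 n_docs = length(feats),
                                 n_nodes = length(fitted))),
            class = "exposure_ensemble")
}

.predict_on_features <- function(ensemble, feature_sets) {
  feats <- .filter_families(feature_sets, ensemble$config$families)
  pmids <- names(feats)
  dec <- matrix(NA_real_, nrow = length(pmids), ncol = length(ensemble$nodes),
                dimnames = list(pmids, names(ensemble$nodes)))
  for (nd in names(ensemble$nodes)) {
    cl <- ensemble$nodes[[nd]]
    x <- encode_features(feats, cl$vocab)
    dec[, nd] <- .svm_decision(cl$model, x)
  }
  labels <- lapply(pmids, function(p) {
    lab <- colnames(dec)[dec[p, ] > 0]
    if (ensemble$config$force_hierarchy && length(lab)) {
      lab <- propagate_labels(ensemble$taxonomy, lab)
    }
    sort_c(lab)
  })
  names(labels) <- pmids
  structure(labels, decision = dec, class = "prediction_set")
}

#' Nested cross-validation evaluation
#'
#' Outer `k`-fold rotation (default 3 folds): the ensemble is trained on
#' k-1 folds -- per-node vocabulary building, feature selection and inner
#' `inner_k`-fold hyperparameter tuning all happen inside the training
#' split, so no information leaks from the test fold -- and evaluated on
#' the held-out fold. Per-node confusion counts are pooled across folds
#' before metrics are computed (per-fold averaging is available via
#' `aggregate = "per_fold"`).
#'
#' @param docs list of [document_record()]s or `annotated_document`s.
#' @param annotations an [annotation_set()].
#' @param taxonomy an `exposure_taxonomy`.
#' @param k outer fold count (default 3).
#' @param seed integer seed for all fold splits.
#' @param config a [classifier_config()] (its `inner_k` governs tuning).
#' @param aggregate `"pooled"` (counts summed over folds) or `"per_fold"`
#'   (metrics averaged over folds in which the node was trained).
#' @return Object of class `evaluation_report`: data frame `metrics` with
#'   one row per evaluated node (precision/recall/accuracy/F as fractions,
#'   pooled counts, `folds_trained`, `defined` flag) plus a manifest.
#' @export
cross_validate <- function(docs, annotations, taxonomy = exposure_taxonomy(),
                           k = 3L, seed = 1L, config = classifier_config(),
                           aggregate = c("pooled", "per_fold")) {
  aggregate <- match.arg(aggregate)
  check(k >= 2L, "k must be >= 2")
  feats <- .corpus_features(docs, config)
  if (config$drop_no_abstract && any(attr(feats, "no_abstract"))) {
    feats <- feats[!attr(feats, "no_abstract")]
  }
  res <- .cv_core(feats, annotations, taxonomy, k, seed, config)
  .build_report(res, taxonomy, k, seed, config, aggregate,
                n_docs = length(feats))
}

.build_report <- function(res, taxonomy, k, seed, config, aggregate, n_docs) {
  nodes <- rownames(res$counts)
  evaluated <- nodes[res$folds_trained > 0L]
  rows <- lapply(evaluated, function(nd) {
    if (aggregate == "pooled") {
      m <- node_metrics(res$counts[nd, ])
      def <- all(m$defined[c("precision", "recall", "f_score")])
    } else {
      ms <- lapply(res$per_fold, function(fc) {
        if (any(is.na(fc[nd, ]))) NULL else node_metrics(fc[nd, ])
      })
      ms <- ms[!vapply(ms, is.null, TRUE)]
      m <- list(precision = mean(vapply(ms, `[[`, 0, "precision")),
                recall = mean(vapply(ms, `[[`, 0, "recall")),
                accuracy = mean(vapply(ms, `[[`, 0, "accuracy")),
                f_score = mean(vapply(ms, `[[`, 0, "f_score")))
      def <- all(vapply(ms, function(x)
        all(x$defined[c("precision", "recall", "f_score")]), TRUE))
    }
    data.frame(node = nd,
               display = taxonomy$nodes$display[match(nd, taxonomy$nodes$name)],
               precision = m$precision, recall = m$recall,
               accuracy = m$accuracy, f_score = m$f_score,
               tp = res$counts[nd, "tp"], fp = res$counts[nd, "fp"],
               fn = res$counts[nd, "fn"], tn = res$counts[nd, "tn"],
               folds_trained = res$folds_trained[[nd]], defined = def,
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  structure(list(metrics = metrics,
                 manifest = list(k = as.integer(k), seed = as.integer(seed),
                                 inner_k = config$inner_k,
                                 families = config$families,
                                 aggregate = aggregate, n_docs = n_docs)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Cross-validation report: %d-fold outer, %d-fold inner tuning, seed %d, %d documents\n",
              x$manifest$k, x$manifest$inner_k, x$manifest$seed,
              x$manifest$n_docs))
  cat(sprintf("%-28s %9s %9s %9s %9s\n", "Node", "Precision", "Recall",
              "Accuracy", "F-score"))
  for (i in seq_len(nrow(m))) {
    cat(sprintf("%-28s %8.1f%% %8.1f%% %8.1f%% %8.1f%%%s\n", m$display[i],
                100 * m$precision[i], 100 * m$recall[i], 100 * m$accuracy[i],
                100 * m$f_score[i], if (m$defined[i]) "" else " *"))
  }
  cat(sprintf("%-28s %8.1f%% %8.1f%% %8.1f%% %8.1f%%\n", "Macro average",
              100 * mean(m$precision), 100 * mean(m$recall),
              100 * mean(m$accuracy), 100 * mean(m$f_score)))
  if (any(!m$defined)) cat("* metric with zero denominator reported as 0\n")
  invisible(x)
}

#' Macro-averaged F-score of a report
#'
#' @param report an `evaluation_report`.
#' @param nodes optional subset of node slugs to average over (default all
#'   evaluated nodes).
#' @return Mean F-score (fraction).
#' @export
macro_f <- function(report, nodes = NULL) {
  m <- report$metrics
  if (!is.null(nodes)) m <- m[m$node %in% nodes, , drop = FALSE]
  mean(m$f_score)
}

#' Export an evaluation report as TSV
#'
#' One row per node (precision, recall, accuracy, F as percentages with one
#' decimal), mirroring the package's printed report.
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  m <- report$metrics
  lines <- c("node\tprecision\trecall\taccuracy\tf_score\tdefined",
             sprintf("%s\t%.1f\t%.1f\t%.1f\t%.1f\t%d", m$node,
                     100 * m$precision, 100 * m$recall, 100 * m$accuracy,
                     100 * m$f_score, as.integer(m$defined)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- ablation ---------------------------------------------------------------

#' Leave-one-feature-family-out ablation
#'
#' Repeats the cross-validation once with all feature families (the
#' baseline) and once per family with that family removed from vocabulary
#' building and encoding, under identical seeds and fold splits. The
#' average delta of a family is the baseline mean F minus the mean F
#' without it; a family that never fires on the corpus reproduces the
#' baseline exactly.
#'
#' @inheritParams cross_validate
#' @param families families to ablate (default all seven).
#' @return Object of class `ablation_report`: matrix `f_scores` (node x
#'   ("all" + families), fractions), `avg_delta` per family, and the
#'   underlying reports.
#' @export
ablate_feature_families <- function(docs, annotations,
                                    taxonomy = exposure_taxonomy(),
                                    k = 3L, seed = 1L,
                                    config = classifier_config(),
                                    families = feature_families()) {
  bad <- setdiff(families, feature_families())
  check(length(bad) == 0L, "unknown feature family: %s",
        paste(bad, collapse = ", "))
  feats <- .corpus_features(docs, config)
  if (config$drop_no_abstract && any(attr(feats, "no_abstract"))) {
    feats <- feats[!attr(feats, "no_abstract")]
  }
  run <- function(fams) {
    cfg <- config
    cfg$families <- fams
    res <- .cv_core(feats, annotations, taxonomy, k, seed, cfg)
    .build_report(res, taxonomy, k, seed, cfg, "pooled", length(feats))
  }
  baseline <- run(config$families)
  ablated <- lapply(families, function(fam) {
    run(setdiff(config$families, fam))
  })
  names(ablated) <- families
  nodes <- baseline$metrics$node
  f_scores <- matrix(NA_real_, nrow = length(nodes),
                     ncol = length(families) + 1L,
                     dimnames = list(nodes, c("all", families)))
  f_scores[, "all"] <- baseline$metrics$f_score
  for (fam in families) {
    m <- ablated[[fam]]$metrics
    f_scores[m$node[m$node %in% nodes], fam] <-
      m$f_score[m$node %in% nodes]
  }
  avg_delta <- vapply(families, function(fam) {
    mean(f_scores[, "all"], na.rm = TRUE) -
      mean(f_scores[, fam], na.rm = TRUE)
  }, 0)
  structure(list(f_scores = f_scores, avg_delta = avg_delta,
                 baseline = baseline, ablated = ablated),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("Leave-one-family-out ablation (F-scores, %):\n")
  m <- round(100 * x$f_scores, 1)
  print(m)
  cat("\nAverage F drop when family removed (percentage points):\n")
  print(round(100 * x$avg_delta, 1))
  invisible(x)
}

#' Export an ablation report as TSV
#'
#' Node x family matrix of F-scores (percentages), with the all-families
#' baseline in the first column and the average row last.
#'
#' @param report an `ablation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ablation_report <- function(report, path) {
  m <- report$f_scores
  hdr <- paste(c("node", colnames(m)), collapse = "\t")
  rows <- vapply(rownames(m), function(nd) {
    paste(c(nd, sprintf("%.1f", 100 * m[nd, ])), collapse = "\t")
  }, "")
  avg <- paste(c("average", sprintf("%.1f", 100 * colMeans(m, na.rm = TRUE))),
               collapse = "\t")
  writeLines(c(hdr, rows, avg), path, useBytes = TRUE)
  invisible(path)
}

# ---- inter-annotator agreement ---------------------------------------------

#' Cohen's kappa between two annotation sets
#'
#' Per node, agreement on the binary membership labels of the two
#' annotators is chance-corrected: kappa = (po - pe) / (1 - pe) with pe
#' from the marginal products of the 2x2 table. Nodes where pe = 1 (both
#' annotators constant) have undefined kappa and are excluded from the
#' unweighted average. By default the annotations are compared as made;
#' `propagate = TRUE` closes both sets upward first.
#'
#' @param a,b [annotation_set()]s over identical pmids.
#' @param taxonomy an `exposure_taxonomy`.
#' @param propagate close label sets upward before comparing.
#' @return Object of class `agreement_report`: data frame `per_node`
#'   (node, kappa, po, pe), `average` kappa, `n` documents.
#' @export
cohen_kappa <- function(a, b, taxonomy = exposure_taxonomy(),
                        propagate = FALSE) {
  pa <- names(a$labels); pb <- names(b$labels)
  if (!setequal(pa, pb)) {
    diff <- c(setdiff(pa, pb), setdiff(pb, pa))
    stop("annotation sets cover different pmids: ",
         paste(utils::head(diff, 10L), collapse = ", "), call. = FALSE)
  }
  pmids <- pa
  n <- length(pmids)
  get_sets <- function(s) {
    lapply(stats::setNames(pmids, pmids), function(p) {
      if (propagate) propagate_labels(taxonomy, s$labels[[p]])
      else s$labels[[p]]
    })
  }
  sa <- get_sets(a); sb <- get_sets(b)
  nodes <- taxonomy_nodes(taxonomy, order = "traversal")
  rows <- lapply(nodes, function(nd) {
    xa <- vapply(pmids, function(p) nd %in% sa[[p]], TRUE)
    xb <- vapply(pmids, function(p) nd %in% sb[[p]], TRUE)
    po <- mean(xa == xb)
    pe <- mean(xa) * mean(xb) + (1 - mean(xa)) * (1 - mean(xb))
    kappa <- if (abs(1 - pe) < 1e-12) NA_real_ else (po - pe) / (1 - pe)
    data.frame(node = nd, kappa = kappa, po = po, pe = pe,
               stringsAsFactors = FALSE)
  })
  per_node <- do.call(rbind, rows)
  rownames(per_node) <- NULL
  structure(list(per_node = per_node,
                 average = mean(per_node$kappa, na.rm = TRUE), n = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Inter-annotator agreement over %d documents\n", x$n))
  cat(sprintf("Average Cohen's kappa: %.2f (%d nodes with defined kappa)\n",
              x$average, sum(!is.na(x$per_node$kappa))))
  invisible(x)
}

# ---- retrieval comparison ---------------------------------------------------

#' Compare predictions against a reference PMID list
#'
#' Reports how many of a manually collected reference list were also
#' predicted positive for the node (the classifier's recall on that list),
#' in found/total style.
#'
#' @param pred a `prediction_set`.
#' @param node node slug or display name.
#' @param reference_pmids character vector of reference PMIDs.
#' @param taxonomy an `exposure_taxonomy`.
#' @return List with `found`, `total`, `ratio` (e.g. `"14/15"`) and
#'   `missing` pmids.
#' @export
compare_retrieval <- function(pred, node, reference_pmids,
                              taxonomy = exposure_taxonomy()) {
  node <- resolve_node(taxonomy, node)
  reference_pmids <- as.character(reference_pmids)
  hit <- vapply(reference_pmids, function(p) {
    !is.null(pred[[p]]) && node %in% pred[[p]]
  }, TRUE)
  list(found = sum(hit), total = length(reference_pmids),
       ratio = sprintf("%d/%d", sum(hit), length(reference_pmids)),
       missing = reference_pmids[!hit])
}

#' Color-coded F-score summary (SVG)
#'
#' Writes a single-file SVG bar summary of per-node F-scores, color-coded
#' green (> 75 %), yellow (50--75 %) and red (< 50 %).
#'
#' @param report an `evaluation_report`.
#' @param path output `.svg` file.
#' @return `path`, invisibly.
#' @export
write_fscore_svg <- function(report, path) {
  m <- report$metrics
  row_h <- 22L
  width <- 640L
  height <- 40L + row_h * nrow(m)
  color <- ifelse(m$f_score > 0.75, "#2e7d32",
                  ifelse(m$f_score >= 0.50, "#f9a825", "#c62828"))
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="sans-serif" font-size="12">',
            width, height),
    '<text x="10" y="20" font-size="14">Per-node F-scores (%)</text>')
  for (i in seq_len(nrow(m))) {
    y <- 30L + row_h * (i - 1L)
    bar <- round(3 * 100 * m$f_score[i])
    lines <- c(lines,
      sprintf('<text x="10" y="%d">%s</text>', y + 14L, m$display[i]),
      sprintf('<rect x="230" y="%d" width="%d" height="14" fill="%s"/>',
              y + 3L, bar, color[i]),
      sprintf('<text x="%d" y="%d">%.1f</text>', 240L + bar, y + 14L,
              100 * m$f_score[i]))
  }
  writeLines(c(lines, "</svg>"), path, useBytes = TRUE)
  invisible(path)
}
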