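# The classifier ensemble: one independent binary RBF-SVM per taxonomy
# node, trained on that node's own selected feature space with hierarchical
# positive-label propagation (a sub-node annotation is a positive example
# for every ancestor node). Decisions are taken independently per node at
# decision-function threshold 0, giving mutually non-exclusive multi-label
# output.

#' Ensemble configuration
#'
#' @param families feature families used (default all seven).
#' @param thresholds a [df_thresholds()] for per-node feature selection.
#' @param cost_grid,gamma_grid hyperparameter candidates for the RBF kernel;
#'   the grid is searched by inner cross-validation maximizing mean
#'   inner-fold F-score, ties broken toward smaller cost then smaller gamma.
#' @param inner_k inner folds for hyperparameter tuning (default 5).
#' @param nlp an [nlp_config()].
#' @param vc_lexicon a [verb_cluster_lexicon()] (default built-in).
#' @param class_weights use inverse-frequency class weights (default
#'   `FALSE`: plain SVM objective).
#' @param force_hierarchy at prediction time, close predicted label sets
#'   upward over the taxonomy (default `FALSE`: nodes decide independently,
#'   so a child may fire without its parent).
#' @param drop_no_abstract exclude records with an empty abstract from
#'   training (default `TRUE`; such records can still be classified from
#'   their metadata features at prediction time).
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(families = feature_families(),
                              thresholds = df_thresholds(),
                              cost_grid = c(0.1, 1, 10, 100),
                              gamma_grid = c(0.001, 0.01, 0.1, 1),
                              inner_k = 5L,
                              nlp = nlp_config(),
                              vc_lexicon = NULL,
                              class_weights = FALSE,
                              force_hierarchy = FALSE,
                              drop_no_abstract = TRUE) {
  bad <- setdiff(families, feature_families())
  check(length(bad) == 0L, "unknown feature family: %s", paste(bad, collapse = ", "))
  check(inner_k >= 2L, "inner_k must be >= 2")
  structure(list(families = families, thresholds = thresholds,
                 cost_grid = sort(cost_grid), gamma_grid = sort(gamma_grid),
                 inner_k = as.integer(inner_k), nlp = nlp,
                 vc_lexicon = vc_lexicon,
                 class_weights = isTRUE(class_weights),
                 force_hierarchy = isTRUE(force_hierarchy),
                 drop_no_abstract = isTRUE(drop_no_abstract)),
            class = "classifier_config")
}

# Per-document feature sets for a corpus; accepts raw records or
# already-annotated documents, annotating as needed.
.corpus_features <- function(docs, config) {
  if (length(docs) && inherits(docs[[1L]], "document_record")) {
    docs <- annotate_corpus(docs, config$nlp)
  }
  check(all(vapply(docs, inherits, TRUE, "annotated_document")),
        "docs must be document_records or annotated_documents")
  lex <- config$vc_lexicon %||% verb_cluster_lexicon()
  feats <- lapply(docs, extract_features, families = feature_families(),
                  vc_lexicon = lex)
  names(feats) <- vapply(docs, function(d) d$record$pmid, "")
  attr(feats, "no_abstract") <- vapply(docs, function(d) d$record$no_abstract,
                                       TRUE)
  feats
}

.filter_families <- function(feature_sets, families) {
  out <- lapply(feature_sets, function(ks) ks[feature_family_of(ks) %in% families])
  attributes(out) <- attributes(feature_sets)
  out
}

#' Assemble a node's training set
#'
#' A document is positive for `node` iff the upward closure of its
#' annotation contains the node (sub-node labels propagate to ancestors);
#' every other reviewed document -- including reviewed-but-irrelevant ones
#' with an empty label set -- is a negative.
#'
#' @param feature_sets named (by pmid) list of per-document feature sets.
#' @param annotations an [annotation_set()] covering those pmids.
#' @param node node slug or display name.
#' @param taxonomy an `exposure_taxonomy`.
#' @return List with `x` (the feature sets), `y` (logical positives) and
#'   `node`.
#' @export
assemble_training_set <- function(feature_sets, annotations, node, taxonomy) {
  node <- resolve_node(taxonomy, node)
  pmids <- names(feature_sets)
  miss <- setdiff(pmids, names(annotations$labels))
  check(length(miss) == 0L, "documents without annotation row: %s",
        paste(utils::head(miss, 5L), collapse = ", "))
  y <- vapply(pmids, function(p) {
    node %in% propagate_labels(taxonomy, annotations$labels[[p]])
  }, TRUE)
  list(x = feature_sets, y = y, node = node)
}

# ---- SVM core ---------------------------------------------------------------

# Portable binary RBF-SVM: stores support vectors and dual coefficients so
# the decision function can be evaluated without the fitting object and
# serialized exactly. decision > 0 <=> positive.
.fit_rbf_svm <- function(x, y, cost, gamma, class_weights = FALSE) {
  stopifnot(is.matrix(x), is.logical(y), length(y) == nrow(x))
  if (ncol(x) == 0L || length(unique(y)) < 2L) {
    return(structure(list(type = "constant",
                          decision = if (mean(y) > 0.5) 1 else -1,
                          cost = cost, gamma = gamma),
                     class = "rbf_node_svm"))
  }
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  cw <- if (class_weights) {
    n <- table(yf); stats::setNames(as.numeric(sum(n) / (2 * n)), names(n))
  } else NULL
  m <- e1071::svm(x = x, y = yf, kernel = "radial", cost = cost,
                  gamma = gamma, scale = FALSE, class.weights = cw)
  coefs <- as.numeric(m$coefs)
  rho <- as.numeric(m$rho)
  # libsvm decision > 0 corresponds to the first internal label
  if (m$levels[m$labels[1L]] != "pos") {
    coefs <- -coefs
    rho <- -rho
  }
  structure(list(type = "svm", sv = unname(as.matrix(m$SV)), coefs = coefs,
                 rho = rho, cost = cost, gamma = gamma),
            class = "rbf_node_svm")
}

.svm_decision <- function(model, x) {
  if (model$type == "constant") return(rep(model$decision, nrow(x)))
  # ||sv - x||^2 via cross products; all features binary so this is exact
  sv <- model$sv
  d2 <- outer(rowSums(sv^2), rowSums(x^2), "+") - 2 * tcrossprod(sv, x)
  d2[d2 < 0] <- 0
  k <- exp(-model$gamma * d2)
  drop(crossprod(k, model$coefs)) - model$rho
}

#' Tune RBF hyperparameters by inner cross-validation
#'
#' Evaluates every `(cost, gamma)` grid point with seeded `inner_k`-fold
#' cross-validation and returns the point maximizing the mean inner-fold
#' F-score; ties break toward smaller cost, then smaller gamma. Folds with
#' an undefined F-score contribute 0.
#'
#' @param x binary feature matrix.
#' @param y logical labels (both classes present).
#' @param cost_grid,gamma_grid candidate values.
#' @param inner_k inner fold count.
#' @param seed integer seed for the fold split.
#' @param class_weights see [classifier_config()].
#' @return List with `cost`, `gamma` and `mean_f`.
#' @export
tune_hyperparameters <- function(x, y, cost_grid = c(0.1, 1, 10, 100),
                                 gamma_grid = c(0.001, 0.01, 0.1, 1),
                                 inner_k = 5L, seed = 1L,
                                 class_weights = FALSE) {
  check(length(unique(y)) == 2L,
        "degenerate training set: both classes required for tuning")
  grid <- expand.grid(gamma = sort(gamma_grid), cost = sort(cost_grid))
  grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
  if (nrow(grid) == 1L) {
    return(list(cost = grid$cost[1L], gamma = grid$gamma[1L], mean_f = NA_real_))
  }
  ids <- as.character(seq_len(nrow(x)))
  inner_k <- min(inner_k, nrow(x))
  folds <- split_folds(ids, k = inner_k, seed = seed)$assignment
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    fs <- vapply(0:(inner_k - 1L), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) return(0)
      m <- .fit_rbf_svm(x[tr, , drop = FALSE], y[tr], grid$cost[g],
                        grid$gamma[g], class_weights)
      pred <- .svm_decision(m, x[!tr, , drop = FALSE]) > 0
      tp <- sum(pred & y[!tr]); fp <- sum(pred & !y[!tr])
      fn <- sum(!pred & y[!tr])
      if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, 0)
    mf <- mean(fs)
    if (is.null(best) || mf > best$mean_f + 1e-12) {
      best <- list(cost = grid$cost[g], gamma = grid$gamma[g], mean_f = mf)
    }
  }
  best
}

# ---- ensemble fit -----------------------------------------------------------

#' Train the node-classifier ensemble
#'
#' The main fitting function: builds, for every taxonomy node with at least
#' one positive and one negative training document, a per-node feature
#' vocabulary (document-frequency selection over the training corpus only),
#' tunes the RBF kernel by inner cross-validation, and fits an independent
#' binary SVM. Nodes failing the eligibility check are skipped with a
#' warning.
#'
#' @param docs list of [document_record()]s or `annotated_document`s.
#' @param annotations an [annotation_set()] covering the documents (empty
#'   label sets mark reviewed-but-irrelevant documents, used as negatives
#'   for every node).
#' @param taxonomy an `exposure_taxonomy` (default built-in, 32 nodes).
#' @param config a [classifier_config()].
#' @param seed integer seed governing fold splits in tuning.
#' @return Object of class `exposure_ensemble` with `print`, `summary` and
#'   `predict` methods.
#' @examples
#' \donttest{
#' spec <- synthetic_corpus_spec(docs_per_leaf = 25, irrelevant_docs = 50,
#'                               seed = 7)
#' corpus <- generate_corpus(spec)
#' fit <- exposure_classifier(corpus$records, corpus$annotations,
#'                            config = classifier_config(
#'                              cost_grid = 1, gamma_grid = 0.01))
#' pred <- predict(fit, corpus$records[1:5])
#' }
#' @export
exposure_classifier <- function(docs, annotations,
                                taxonomy = exposure_taxonomy(),
                                config = classifier_config(), seed = 1L) {
  check(length(docs) > 0L, "empty corpus")
  feats <- .corpus_features(docs, config)
  if (config$drop_no_abstract && any(attr(feats, "no_abstract"))) {
    feats <- feats[!attr(feats, "no_abstract")]
  }
  fit <- .train_on_features(feats, annotations, taxonomy, config, seed)
  if (length(fit$skipped)) {
    warning("nodes skipped (need >=1 positive and >=1 negative): ",
            paste(fit$skipped, collapse = ", "), call. = FALSE)
  }
  fit
}

#' @export
print.exposure_ensemble <- function(x, ...) {
  cat(sprintf("Exposure classifier ensemble: %d node classifiers (of %d taxonomy nodes)\n",
              length(x$nodes), nrow(x$taxonomy$nodes)))
  cat(sprintf("  trained on %d documents, seed %d\n", x$manifest$n_docs,
              x$manifest$seed))
  if (length(x$skipped))
    cat("  skipped nodes:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.exposure_ensemble <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$nodes, function(n) {
    data.frame(node = n$node, n_pos = n$n_pos, n_neg = n$n_neg,
               n_features = length(n$vocab$features), cost = n$model$cost,
               gamma = n$model$gamma, inner_f = n$inner_f,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, skipped = object$skipped),
            class = "summary.exposure_ensemble")
}

#' @export
print.summary.exposure_ensemble <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 3)
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Predict taxonomy labels for new documents
#'
#' Every node classifier decides independently at decision threshold 0; the
#' output label sets are mutually non-exclusive, and (unless
#' `force_hierarchy` was configured) a child node may fire without its
#' parent.
#'
#' @param object an `exposure_ensemble`.
#' @param newdata list of [document_record()]s or `annotated_document`s.
#' @param ... unused.
#' @return Object of class `prediction_set`: named list pmid -> character
#'   vector of node slugs, with the dense decision-value matrix in
#'   `attr(, "decision")`.
#' @export
predict.exposure_ensemble <- function(object, newdata, ...) {
  feats <- .corpus_features(newdata, object$config)
  .predict_on_features(object, feats)
}

#' @export
print.prediction_set <- function(x, ...) {
  n <- length(x)
  cat(sprintf("Prediction set: %d documents, %d with >=1 label\n", n,
              sum(lengths(x) > 0L)))
  invisible(x)
}

#' Write predictions as TSV
#'
#' Wide form: `pmid<TAB>semicolon-joined node slugs`. Long form (with
#' `long = TRUE`): one row per (pmid, node) with the decision value.
#'
#' @param pred a `prediction_set`.
#' @param path output file.
#' @param long write the long decision-value form.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path, long = FALSE) {
  pmids <- sort_c(names(pred))
  if (!long) {
    writeLines(vapply(pmids, function(p) {
      paste0(p, "\t", paste(pred[[p]], collapse = ";"))
    }, ""), path, useBytes = TRUE)
  } else {
    dec <- attr(pred, "decision")
    lines <- c("pmid\tnode\tdecision")
    for (p in pmids) for (nd in colnames(dec)) {
      lines <- c(lines, sprintf("%s\t%s\t%.10g", p, nd, dec[p, nd]))
    }
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

# ---- model bundle -----------------------------------------------------------

#' Write a model bundle
#'
#' Serializes an ensemble to a directory of plain-text files: a manifest, a
#' taxonomy description, and per node a vocabulary JSON plus learned
#' parameters (support vectors, dual coefficients, offset, kernel
#' settings). The canonical serialization is byte-stable under write ->
#' read -> write.
#'
#' @param ensemble an `exposure_ensemble`.
#' @param dir bundle directory.
#' @return `dir`, invisibly.
#' @export
write_model_bundle <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_taxonomy(ensemble$taxonomy, file.path(dir, "taxonomy.json"))
  cfg <- ensemble$config
  write_canonical_json(list(
    format = "expotax-model-bundle", version = 1L,
    seed = ensemble$manifest$seed, n_docs = ensemble$manifest$n_docs,
    families = cfg$families,
    thresholds = list(min_df = cfg$thresholds$min_df,
                      max_df = cfg$thresholds$max_df,
                      max_df_frac = cfg$thresholds$max_df_frac),
    cost_grid = cfg$cost_grid, gamma_grid = cfg$gamma_grid,
    inner_k = cfg$inner_k, class_weights = cfg$class_weights,
    force_hierarchy = cfg$force_hierarchy,
    include_title = cfg$nlp$include_title,
    nodes = names(ensemble$nodes), skipped = ensemble$skipped
  ), file.path(dir, "manifest.json"))
  for (nd in names(ensemble$nodes)) {
    cl <- ensemble$nodes[[nd]]
    write_vocabulary(cl$vocab, file.path(dir, paste0(nd, ".vocab.json")))
    m <- cl$model
    params <- list(node = nd, type = m$type, cost = m$cost, gamma = m$gamma,
                   n_pos = cl$n_pos, n_neg = cl$n_neg)
    if (m$type == "svm") {
      # doubles as %.17g strings: exact value round trip, byte-stable text
      params$rho <- sprintf("%.17g", m$rho)
      params$coefs <- sprintf("%.17g", m$coefs)
      params$sv <- apply(m$sv, 1L, function(r) as.integer(r),
                         simplify = FALSE)
    } else {
      params$decision <- m$decision
    }
    write_canonical_json(params, file.path(dir, paste0(nd, ".params.json")))
  }
  invisible(dir)
}

#' Read a model bundle
#'
#' @param dir directory written by [write_model_bundle()].
#' @return An `exposure_ensemble` whose predictions are identical to those
#'   of the ensemble that was written.
#' @export
read_model_bundle <- function(dir) {
  check(dir.exists(dir), "model bundle directory not found: %s", dir)
  man <- read_json_file(file.path(dir, "manifest.json"))
  taxonomy <- load_taxonomy(file.path(dir, "taxonomy.json"))
  thr <- df_thresholds(min_df = man$thresholds$min_df,
                       max_df = man$thresholds$max_df,
                       max_df_frac = man$thresholds$max_df_frac %||% 0.3)
  config <- classifier_config(
    families = as.character(unlist(man$families)), thresholds = thr,
    cost_grid = as.numeric(unlist(man$cost_grid)),
    gamma_grid = as.numeric(unlist(man$gamma_grid)),
    inner_k = man$inner_k,
    nlp = nlp_config(include_title = isTRUE(man$include_title)),
    class_weights = isTRUE(man$class_weights),
    force_hierarchy = isTRUE(man$force_hierarchy))
  nodes <- list()
  for (nd in as.character(unlist(man$nodes))) {
    vocab <- read_vocabulary(file.path(dir, paste0(nd, ".vocab.json")))
    p <- read_json_file(file.path(dir, paste0(nd, ".params.json")))
    model <- if (p$type == "svm") {
      sv <- do.call(rbind, lapply(p$sv, function(r) as.numeric(unlist(r))))
      structure(list(type = "svm", sv = sv,
                     coefs = as.numeric(unlist(p$coefs)),
                     rho = as.numeric(p$rho), cost = as.numeric(p$cost),
                     gamma = as.numeric(p$gamma)),
                class = "rbf_node_svm")
    } else {
      structure(list(type = "constant", decision = p$decision,
                     cost = p$cost, gamma = p$gamma),
                class = "rbf_node_svm")
    }
    nodes[[nd]] <- list(node = nd, vocab = vocab, model = model,
                        n_pos = p$n_pos, n_neg = p$n_neg, inner_f = NA_real_)
  }
  structure(list(taxonomy = taxonomy, nodes = nodes,
                 skipped = as.character(unlist(man$skipped)),
                 config = config,
                 manifest = list(seed = as.integer(man$seed),
                                 n_docs = as.integer(man$n_docs),
                                 n_nodes = length(nodes))),
            class = "exposure_ensemble")
}
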