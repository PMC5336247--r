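test_that("training sets use hierarchical closure and irrelevant negatives", {
  tax <- exposure_taxonomy()
  feats <- list(a = "LBOW:x", b = "LBOW:y", c = "LBOW:z")
  ann <- annotation_set(list(a = "Blood", b = character(0), c = "Food"), tax)
  for (nd in c("blood", "exposure_biomarker", "biomonitoring")) {
    ts <- assemble_training_set(feats, ann, nd, tax)
    expect_equal(unname(ts$y), c(TRUE, FALSE, FALSE), label = nd)
  }
  ts <- assemble_training_set(feats, ann, "urine", tax)
  expect_equal(unname(ts$y), c(FALSE, FALSE, FALSE))
  expect_error(assemble_training_set(feats, ann, "plasma", tax),
               "unknown taxonomy node")
})

test_that("closure counting matches a brute-force oracle on random sets", {
  tax <- exposure_taxonomy()
  nodes <- taxonomy_nodes(tax)
  set.seed(13)
  pm <- sprintf("p%02d", 1:40)
  labels <- lapply(pm, function(p) sample(nodes, sample(0:3, 1)))
  names(labels) <- pm
  ann <- annotation_set(labels, tax)
  feats <- stats::setNames(as.list(paste0("LBOW:", pm)), pm)
  for (nd in sample(nodes, 8)) {
    ts <- assemble_training_set(feats, ann, nd, tax)
    oracle <- vapply(pm, function(p)
      nd %in% oracle_closure(tax, ann$labels[[p]]), TRUE)
    expect_equal(ts$y, oracle, label = nd)
  }
  # parent positives contain the union of descendant positives
  for (nd in c("exposure_biomarker", "inhalation", "molecule")) {
    par_y <- assemble_training_set(feats, ann, nd, tax)$y
    for (ch in taxonomy_descendants(tax, nd)) {
      ch_y <- assemble_training_set(feats, ann, ch, tax)$y
      expect_true(all(which(ch_y) %in% which(par_y)),
                  label = paste(nd, "<-", ch))
    }
  }
})

test_that("portable decision function reproduces e1071 predictions", {
  set.seed(2)
  x <- matrix(rbinom(600, 1, 0.3), 60)
  y <- rowSums(x[, 1:3]) >= 2
  xnew <- matrix(rbinom(300, 1, 0.3), 30)
  m <- expotax:::.fit_rbf_svm(x, y, cost = 10, gamma = 0.05)
  # independent route: e1071's own predict with decision values
  ref <- e1071::svm(x, factor(ifelse(y, "pos", "neg"),
                              levels = c("neg", "pos")),
                    kernel = "radial", cost = 10, gamma = 0.05,
                    scale = FALSE)
  for (xx in list(x, xnew)) {
    ours <- expotax:::.svm_decision(m, xx)
    refp <- predict(ref, xx, decision.values = TRUE)
    refd <- drop(attr(refp, "decision.values"))
    flip <- if (colnames(attr(refp, "decision.values")) == "pos/neg") 1 else -1
    expect_equal(unname(ours), unname(flip * refd), tolerance = 1e-10)
    expect_equal(unname(ours > 0), unname(refp == "pos"))
  }
})

test_that("hyperparameter tuning is deterministic with lexicographic ties", {
  set.seed(4)
  x <- rbind(matrix(rbinom(300, 1, 0.9), 30), matrix(rbinom(300, 1, 0.1), 30))
  y <- rep(c(TRUE, FALSE), each = 30)
  one <- tune_hyperparameters(x, y, cost_grid = 7, gamma_grid = 0.02,
                              inner_k = 3, seed = 1)
  expect_equal(one$cost, 7)
  expect_equal(one$gamma, 0.02)
  # clearly separable blob: the chosen point attains inner F = 1
  best <- tune_hyperparameters(x, y, cost_grid = c(1, 10),
                               gamma_grid = c(0.01, 0.1), inner_k = 3,
                               seed = 1)
  expect_equal(best$mean_f, 1.0)
  # all grid points tie at F = 1 -> smallest cost, then smallest gamma
  expect_equal(best$cost, 1)
  expect_equal(best$gamma, 0.01)
  expect_error(tune_hyperparameters(x, rep(TRUE, 60), 1, 1, 3, 1),
               "degenerate")
})

test_that("ensemble covers all 32 nodes when every node has positives", {
  tax <- exposure_taxonomy()
  leaves <- setdiff(taxonomy_nodes(tax),
                    unique(stats::na.omit(tax$nodes$parent)))
  leaves <- leaves[vapply(leaves, function(nd)
    length(taxonomy_descendants(tax, nd)) == 0L, TRUE)]
  corpus <- generate_corpus(synthetic_corpus_spec(
    leaves = leaves, docs_per_leaf = 6L, irrelevant_docs = 20L,
    keywords_per_leaf = 4L, seed = 31))
  cfg <- classifier_config(cost_grid = 10, gamma_grid = 0.01,
                           thresholds = df_thresholds(min_df = 2))
  fit <- exposure_classifier(corpus$records, corpus$annotations, tax,
                             config = cfg, seed = 2)
  expect_length(fit$nodes, 32L)
  expect_length(fit$skipped, 0L)
})

test_that("nodes without positives are skipped with a warning", {
  corpus <- tiny_corpus(seed = 5, docs_per_leaf = 10L, irrelevant_docs = 20L)
  cfg <- classifier_config(cost_grid = 10, gamma_grid = 0.01)
  expect_warning(
    fit <- exposure_classifier(corpus$records, corpus$annotations,
                               config = cfg, seed = 1),
    "skipped")
  expect_true("soil" %in% fit$skipped)
  expect_false("soil" %in% names(fit$nodes))
  expect_true(all(c("blood", "urine", "food") %in% names(fit$nodes)))
})

test_that("training and prediction are deterministic given seeds", {
  corpus <- tiny_corpus(seed = 6, docs_per_leaf = 12L, irrelevant_docs = 16L)
  cfg <- tiny_config()
  ann <- annotate_corpus(corpus$records, cfg$nlp)
  f1 <- suppressWarnings(exposure_classifier(ann, corpus$annotations,
                                             config = cfg, seed = 3))
  f2 <- suppressWarnings(exposure_classifier(ann, corpus$annotations,
                                             config = cfg, seed = 3))
  expect_identical(f1$nodes, f2$nodes)
  p1 <- predict(f1, ann[1:10])
  p2 <- predict(f2, ann[1:10])
  expect_identical(p1, p2)
})

test_that("node classifiers decide independently", {
  corpus <- tiny_corpus(seed = 7, docs_per_leaf = 12L, irrelevant_docs = 16L)
  cfg <- classifier_config(cost_grid = 10, gamma_grid = 0.01)
  ann <- annotate_corpus(corpus$records, cfg$nlp)
  fit <- suppressWarnings(exposure_classifier(ann, corpus$annotations,
                                              config = cfg, seed = 1))
  pred_full <- predict(fit, ann[1:8])
  # drop one node's classifier: other nodes' decisions are unchanged
  fit2 <- fit
  fit2$nodes[["blood"]] <- NULL
  pred_drop <- predict(fit2, ann[1:8])
  for (p in names(pred_full)) {
    expect_equal(setdiff(pred_full[[p]], "blood"), pred_drop[[p]])
  }
  # strongly positive training document is recovered
  tax <- exposure_taxonomy()
  strong <- names(which(vapply(corpus$annotations$labels,
                               function(l) identical(l, "urine"), TRUE)))[1]
  expect_true("urine" %in% predict(fit, ann[strong])[[strong]])
})

test_that("documents with empty abstracts classify from metadata alone", {
  corpus <- tiny_corpus(seed = 8, docs_per_leaf = 12L, irrelevant_docs = 16L)
  cfg <- classifier_config(cost_grid = 10, gamma_grid = 0.01)
  fit <- suppressWarnings(exposure_classifier(corpus$records,
                                              corpus$annotations,
                                              config = cfg, seed = 1))
  bare <- document_record("EMPTY1", title = "t", abstract = "",
                          mesh_terms = c("Humans", "mesh-blood"),
                          chemicals = "chem-blood")
  p <- predict(fit, list(bare))
  expect_type(p[["EMPTY1"]], "character")   # possibly empty, never an error
})

test_that("model bundles round trip with identical predictions and bytes", {
  corpus <- tiny_corpus(seed = 9, docs_per_leaf = 10L, irrelevant_docs = 12L)
  cfg <- classifier_config(cost_grid = c(1, 10), gamma_grid = 0.01,
                           inner_k = 2)
  ann <- annotate_corpus(corpus$records, cfg$nlp)
  fit <- suppressWarnings(exposure_classifier(ann, corpus$annotations,
                                              config = cfg, seed = 4))
  d1 <- file.path(tempdir(), "model1")
  d2 <- file.path(tempdir(), "model2")
  write_model_bundle(fit, d1)
  fit2 <- read_model_bundle(d1)
  expect_identical(predict(fit2, ann[1:6]), predict(fit, ann[1:6]))
  write_model_bundle(fit2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), label = f)
  }
})

test_that("prediction TSV exports cover wide and long forms", {
  corpus <- tiny_corpus(seed = 10, docs_per_leaf = 10L, irrelevant_docs = 10L)
  cfg <- classifier_config(cost_grid = 10, gamma_grid = 0.01)
  ann <- annotate_corpus(corpus$records, cfg$nlp)
  fit <- suppressWarnings(exposure_classifier(ann, corpus$annotations,
                                              config = cfg, seed = 1))
  pred <- predict(fit, ann[1:4])
  wide <- file.path(tempdir(), "pred.tsv")
  long <- file.path(tempdir(), "pred_long.tsv")
  write_predictions(pred, wide)
  write_predictions(pred, long, long = TRUE)
  wl <- readLines(wide)
  expect_length(wl, 4L)
  expect_true(all(grepl("^SYN[0-9]+\t", wl)))
  ll <- read.delim(long)
  expect_equal(nrow(ll), 4L * length(fit$nodes))
  expect_true(is.numeric(ll$decision))
})
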