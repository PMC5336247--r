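test_that("confusion counting handles identity, misses and mismatches", {
  tax <- exposure_taxonomy()
  pm <- sprintf("p%02d", 1:10)
  gold <- annotation_set(stats::setNames(
    c(lapply(1:3, function(i) "blood"), lapply(4:10, function(i) character(0))),
    pm), tax)
  pred_eq <- stats::setNames(lapply(pm, function(p)
    propagate_labels(tax, gold$labels[[p]])), pm)
  cc <- confusion_counts(pred_eq, gold, "blood", tax)
  expect_equal(unname(cc[c("fp", "fn")]), c(0L, 0L))
  pred_none <- stats::setNames(rep(list(character(0)), 10), pm)
  cc2 <- confusion_counts(pred_none, gold, "blood", tax)
  expect_equal(unname(cc2), c(0L, 0L, 3L, 7L))
  # gold is closed upward before comparison
  cc3 <- confusion_counts(pred_none, gold, "biomonitoring", tax)
  expect_equal(cc3[["fn"]], 3L)
  expect_error(confusion_counts(pred_none[1:5], gold, "blood", tax),
               "mismatch")
})

test_that("metrics follow the closed forms and zero-denominator convention", {
  m <- node_metrics(c(tp = 1, fp = 1, fn = 0, tn = 8))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 1.0)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$f_score, 2 / 3, tolerance = 1e-12)
  z <- node_metrics(c(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_equal(z$precision, 0)
  expect_equal(z$recall, 0)
  expect_equal(z$f_score, 0)
  expect_false(z$defined[["precision"]])
  expect_error(node_metrics(c(tp = 0, fp = 0, fn = 0, tn = 0)), "all-zero")
  # independent formula oracle over random count tuples
  set.seed(17)
  for (i in 1:500) {
    ct <- stats::setNames(sample(0:30, 4, replace = TRUE),
                          c("tp", "fp", "fn", "tn"))
    if (sum(ct) == 0) ct["tn"] <- 1L
    m <- node_metrics(ct)
    p <- if (ct["tp"] + ct["fp"] > 0) ct[["tp"]] / (ct[["tp"]] + ct[["fp"]]) else 0
    r <- if (ct["tp"] + ct["fn"] > 0) ct[["tp"]] / (ct[["tp"]] + ct[["fn"]]) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    expect_equal(m$precision, p, tolerance = 1e-12)
    expect_equal(m$recall, r, tolerance = 1e-12)
    expect_equal(m$f_score, f, tolerance = 1e-12)
    expect_equal(m$accuracy, (ct[["tp"]] + ct[["tn"]]) / sum(ct),
                 tolerance = 1e-12)
  }
})

test_that("perfectly separable corpus yields F = 1 and pooled counts partition", {
  corpus <- generate_corpus(synthetic_corpus_spec(
    leaves = c("blood", "food"), docs_per_leaf = 24L, irrelevant_docs = 24L,
    signal_prob = 1, multilabel_rate = 0, seed = 23))
  cfg <- classifier_config(cost_grid = c(1, 10), gamma_grid = c(0.001, 0.01),
                           inner_k = 3)
  rep <- cross_validate(corpus$records, corpus$annotations, k = 3, seed = 2,
                        config = cfg)
  expect_true(all(rep$metrics$f_score == 1))
  # pooled confusion counts cover every document for every node
  totals <- rowSums(as.matrix(rep$metrics[, c("tp", "fp", "fn", "tn")]))
  expect_true(all(totals == length(corpus$records)))
  # metrics on identical pred/gold are all 1 by construction above
  expect_true(all(rep$metrics$precision == 1 & rep$metrics$recall == 1))
})

test_that("cross-validation is reproducible under a fixed seed", {
  corpus <- tiny_corpus(seed = 24, docs_per_leaf = 12L, irrelevant_docs = 16L)
  cfg <- classifier_config(cost_grid = 10, gamma_grid = 0.01)
  ann <- annotate_corpus(corpus$records, cfg$nlp)
  r1 <- cross_validate(ann, corpus$annotations, k = 3, seed = 6, config = cfg)
  r2 <- cross_validate(ann, corpus$annotations, k = 3, seed = 6, config = cfg)
  expect_identical(r1, r2)
  r3 <- cross_validate(ann, corpus$annotations, k = 3, seed = 7, config = cfg)
  expect_false(identical(r1$metrics, r3$metrics))
  # per-fold aggregation is available and reports the same nodes
  r4 <- cross_validate(ann, corpus$annotations, k = 3, seed = 6, config = cfg,
                       aggregate = "per_fold")
  expect_equal(r4$metrics$node, r1$metrics$node)
})

test_that("ablating an inert family reproduces the baseline bit for bit", {
  corpus <- generate_corpus(synthetic_corpus_spec(
    leaves = c("blood", "food"), docs_per_leaf = 12L, irrelevant_docs = 12L,
    mode = "lbow_only", seed = 25))
  cfg <- classifier_config(cost_grid = 10, gamma_grid = 0.01)
  ann <- annotate_corpus(corpus$records, cfg$nlp)
  ab <- ablate_feature_families(ann, corpus$annotations, k = 3, seed = 3,
                                config = cfg,
                                families = c("LBOW", "GR", "NE"))
  # GR and NE never fire in lbow_only mode: ablated reports identical
  expect_identical(ab$ablated[["GR"]]$metrics, ab$baseline$metrics)
  expect_identical(ab$ablated[["NE"]]$metrics, ab$baseline$metrics)
  expect_equal(ab$avg_delta[["GR"]], 0)
  # LBOW carries all signal: removing it must hurt
  expect_gt(ab$avg_delta[["LBOW"]], 0.2)
  expect_error(ablate_feature_families(ann, corpus$annotations, k = 3,
                                       seed = 3, config = cfg,
                                       families = "NOSUCH"),
               "unknown feature family")
})

test_that("Cohen's kappa matches hand computations and is symmetric", {
  tax <- exposure_taxonomy()
  pm <- sprintf("d%03d", 1:100)
  # hand 2x2 table per the closed form: (45, 5 / 5, 45) -> kappa = 0.8
  a_lab <- stats::setNames(c(rep(list("blood"), 50),
                             rep(list(character(0)), 50)), pm)
  b_lab <- stats::setNames(c(rep(list("blood"), 45),
                             rep(list(character(0)), 5),
                             rep(list("blood"), 5),
                             rep(list(character(0)), 45)), pm)
  a <- annotation_set(a_lab, tax, "a")
  b <- annotation_set(b_lab, tax, "b")
  ab <- cohen_kappa(a, b, tax)
  expect_equal(ab$per_node$kappa[ab$per_node$node == "blood"], 0.8,
               tolerance = 1e-12)
  ba <- cohen_kappa(b, a, tax)
  expect_equal(ab$per_node$kappa, ba$per_node$kappa, tolerance = 1e-12)
  # identical sets give kappa 1 wherever defined
  aa <- cohen_kappa(a, a, tax)
  expect_equal(aa$per_node$kappa[aa$per_node$node == "blood"], 1.0)
  expect_error(cohen_kappa(a, annotation_set(b_lab[1:10], tax), tax),
               "different pmids")
  # pmid-order invariance
  b_shuf <- annotation_set(b_lab[rev(pm)], tax, "b")
  expect_equal(cohen_kappa(a, b_shuf, tax)$per_node$kappa,
               ab$per_node$kappa, tolerance = 1e-12)
})

test_that("retrieval comparison reports found/total with missing pmids", {
  pred <- stats::setNames(rep(list("blood"), 30), sprintf("r%02d", 1:30))
  ref_in <- sprintf("r%02d", 1:10)
  r <- compare_retrieval(pred, "blood", ref_in)
  expect_equal(r$ratio, "10/10")
  expect_length(r$missing, 0L)
  r2 <- compare_retrieval(pred, "blood", c(sprintf("r%02d", 4:30), "x1"))
  expect_equal(r2$ratio, "27/28")
  expect_equal(r2$missing, "x1")
  r3 <- compare_retrieval(pred, "urine", ref_in)
  expect_equal(r3$found, 0L)
  expect_equal(r3$missing, ref_in)
})

test_that("report exports write the tabular layouts", {
  corpus <- tiny_corpus(seed = 26, docs_per_leaf = 10L, irrelevant_docs = 10L)
  cfg <- classifier_config(cost_grid = 10, gamma_grid = 0.01)
  rep <- cross_validate(corpus$records, corpus$annotations, k = 3, seed = 2,
                        config = cfg)
  path <- file.path(tempdir(), "report.tsv")
  write_evaluation_report(rep, path)
  tab <- read.delim(path)
  expect_equal(tab$node, rep$metrics$node)
  expect_true(all(tab$f_score >= 0 & tab$f_score <= 100))
})

test_that("the SVG summary color-codes F-score bands", {
  corpus <- tiny_corpus(seed = 27, docs_per_leaf = 10L, irrelevant_docs = 10L)
  cfg <- classifier_config(cost_grid = 10, gamma_grid = 0.01)
  rep <- cross_validate(corpus$records, corpus$annotations, k = 3, seed = 2,
                        config = cfg)
  path <- file.path(tempdir(), "fscores.svg")
  write_fscore_svg(rep, path)
  svg <- readLines(path)
  expect_true(grepl("<svg", svg[1]))
  expect_equal(sum(grepl("<rect", svg)), nrow(rep$metrics))
  # bands: force known scores through a modified report
  rep$metrics$f_score <- c(0.9, 0.6, 0.2,
                           rep(0.8, nrow(rep$metrics) - 3))
  write_fscore_svg(rep, path)
  svg <- paste(readLines(path), collapse = "")
  expect_true(grepl("#2e7d32", svg))   # green > 75
  expect_true(grepl("#f9a825", svg))   # yellow 50-75
  expect_true(grepl("#c62828", svg))   # red < 50
})
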