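test_that("LBOW merges inflectional variants into one lemma feature", {
  d <- quick_doc("Lead was measured. The measures rose.")
  f <- extract_lbow(d)
  expect_true("LBOW:measure" %in% f)
  expect_equal(sum(grepl("^LBOW:measure", f)), 1L)
  # empty abstract -> no features
  expect_length(extract_lbow(quick_doc("")), 0L)
  # brute-force oracle: the distinct lemma set
  lemmas <- unique(unlist(lapply(d$sentences, function(s)
    s$lemma[grepl("[A-Za-z0-9]", s$surface)])))
  expect_setequal(f, paste0("LBOW:", tolower(lemmas)))
})

test_that("noun bigrams are surface forms, case-folded, never lemmatized", {
  d <- quick_doc("The breast milk was analyzed .")
  expect_true("NBIGRAM:breast milk" %in% extract_noun_bigrams(d))
  # plural surfaces preserved: blood samples, not blood sample
  d2 <- quick_doc("The blood samples were analyzed .")
  f2 <- extract_noun_bigrams(d2)
  expect_true("NBIGRAM:blood samples" %in% f2)
  expect_false("NBIGRAM:blood sample" %in% f2)
  # no adjacent nouns -> empty
  expect_length(extract_noun_bigrams(quick_doc("Lead was measured .")), 0L)
})

test_that("GR features emit the lexicalized triple plus two wildcards", {
  d <- quick_doc("Lead affects hemoglobin .")
  f <- extract_gr_patterns(d)
  expect_setequal(f, c("GR:subject|affects|lead", "GR:subject|affects|*",
                       "GR:subject|*|lead", "GR:object|affects|hemoglobin",
                       "GR:object|affects|*", "GR:object|*|hemoglobin"))
  expect_length(extract_gr_patterns(quick_doc("Blood of children .")), 0L)
  # enumeration oracle on a multi-arc fixture: 3 patterns per arc, de-duplicated
  d3 <- quick_doc(paste("Lead raises pressure .", "Cadmium raises pressure .",
                        "Lead lowers weight ."))
  f3 <- extract_gr_patterns(d3)
  oracle <- unique(unlist(lapply(seq_len(nrow(d3$arcs)), function(i) {
    a <- d3$arcs[i, ]
    paste0("GR:", c(paste(a$relation, a$head, a$dependent, sep = "|"),
                    paste(a$relation, a$head, "*", sep = "|"),
                    paste(a$relation, "*", a$dependent, sep = "|")))
  })))
  expect_setequal(f3, oracle)
})

test_that("NE features are (type, span) pairs with set semantics", {
  d <- quick_doc("Hemoglobin binds. Hemoglobin rose.")
  f <- extract_ne_features(d)
  expect_equal(f, "NE:protein|Hemoglobin")
  expect_length(extract_ne_features(quick_doc("Lead was measured .")), 0L)
})

test_that("verb clusters activate one bit per hierarchy level", {
  lex <- verb_cluster_lexicon()
  d <- quick_doc("Lead stimulates growth .")
  f <- extract_verb_cluster_bits(d, lex)
  expect_length(f, 3L)
  expect_setequal(substr(f, 1, 6), c("VC:L1|", "VC:L2|", "VC:L3|"))
  # verbs sharing a cluster path activate the same three features
  f2 <- extract_verb_cluster_bits(quick_doc("Lead activates growth ."), lex)
  expect_setequal(f, f2)
  # verbs on different paths do not
  f3 <- extract_verb_cluster_bits(quick_doc("Lead inhibits growth ."), lex)
  expect_false(setequal(f, f3))
  expect_length(extract_verb_cluster_bits(quick_doc("Blood of children ."),
                                          lex), 0L)
})

test_that("metadata features map MeSH and chemicals verbatim, case-folded", {
  rec <- document_record("9", abstract = "x",
                         mesh_terms = c("Humans", "Lead"),
                         chemicals = character(0))
  f <- extract_metadata_features(rec)
  expect_setequal(f, c("MESH:humans", "MESH:lead"))
  rec2 <- document_record("10", abstract = "x",
                          mesh_terms = "Humans", chemicals = "Lead")
  expect_setequal(extract_metadata_features(rec2),
                  c("MESH:humans", "CHEM:lead"))
})

test_that("document-frequency selection matches a brute-force filter", {
  set.seed(3)
  pool <- paste0("LBOW:w", 1:40)
  sets <- lapply(1:30, function(i) sample(pool, sample(3:12, 1)))
  names(sets) <- paste0("d", 1:30)
  df_oracle <- table(unlist(lapply(sets, unique)))

  v5 <- build_vocabulary(sets, thresholds = df_thresholds(min_df = 5,
                                                          max_df = 1000))
  expect_setequal(v5$features, names(df_oracle)[df_oracle >= 5])
  # a feature present in exactly 4 documents is excluded at min_df = 5
  four <- names(df_oracle)[df_oracle == 4][1]
  if (!is.na(four)) expect_false(four %in% v5$features)
  # min_df = 1, unbounded max keeps everything observed
  v1 <- build_vocabulary(sets, thresholds = df_thresholds(min_df = 1,
                                                          max_df = 10000))
  expect_setequal(v1$features, names(df_oracle))
  # monotone: raising min_df shrinks (or keeps) the retained set
  prev <- v1$features
  for (m in c(2, 5, 8, 12)) {
    vm <- build_vocabulary(sets, thresholds = df_thresholds(min_df = m,
                                                            max_df = 1000))
    expect_true(all(vm$features %in% prev))
    expect_setequal(vm$features, names(df_oracle)[df_oracle >= m])
    prev <- vm$features
  }
  # max_df cap removes too-common features
  vcap <- build_vocabulary(sets, thresholds = df_thresholds(min_df = 1,
                                                            max_df = 10))
  expect_setequal(vcap$features,
                  names(df_oracle)[df_oracle >= 1 & df_oracle <= 10])
  expect_error(df_thresholds(min_df = 5, max_df = 2), "min_df")
})

test_that("per-node vocabularies are independent", {
  corpus <- tiny_corpus(seed = 21, docs_per_leaf = 8L, irrelevant_docs = 8L)
  cfg <- tiny_config()
  feats <- expotax:::.corpus_features(
    annotate_corpus(corpus$records, cfg$nlp), cfg)
  vb <- build_vocabulary(feats, "blood", df_thresholds(min_df = 2))
  vu1 <- build_vocabulary(feats, "urine", df_thresholds(min_df = 2))
  # changing node A's thresholds leaves node B's vocabulary untouched
  vb2 <- build_vocabulary(feats, "blood", df_thresholds(min_df = 6))
  vu2 <- build_vocabulary(feats, "urine", df_thresholds(min_df = 2))
  expect_identical(vu1$features, vu2$features)
  expect_false(identical(vb$features, vb2$features))
})

test_that("encoding is binary membership against the vocabulary", {
  set.seed(8)
  pool <- paste0("LBOW:w", 1:25)
  sets <- lapply(1:20, function(i) sample(pool, sample(2:10, 1)))
  names(sets) <- paste0("d", 1:20)
  v <- build_vocabulary(sets, thresholds = df_thresholds(min_df = 1,
                                                         max_df = 100))
  m <- encode_features(sets, v)
  expect_true(all(m %in% c(0, 1)))
  # brute-force membership oracle
  for (i in seq_along(sets)) {
    expect_equal(unname(m[i, ]),
                 as.numeric(v$features %in% sets[[i]]), label = names(sets)[i])
  }
  # out-of-vocabulary features are ignored; empty overlap -> zero row
  idx <- encode_features(c("LBOW:nosuch", sets[[1]][1]), v)
  expect_equal(v$features[idx], sets[[1]][1])
  expect_length(encode_features("LBOW:nosuch", v), 0L)
  # repeated occurrences change nothing
  expect_equal(encode_features(rep(sets[[1]], 3), v),
               encode_features(sets[[1]], v))
})

test_that("vocabulary JSON and MTX exports round trip", {
  set.seed(5)
  sets <- lapply(1:12, function(i) sample(paste0("LBOW:w", 1:15), 5))
  names(sets) <- paste0("d", 1:12)
  v <- build_vocabulary(sets, node = "blood",
                        thresholds = df_thresholds(min_df = 2, max_df = 10))
  p1 <- file.path(tempdir(), "v1.json")
  p2 <- file.path(tempdir(), "v2.json")
  write_vocabulary(v, p1)
  v2 <- read_vocabulary(p1)
  expect_equal(v2$features, v$features)
  expect_equal(v2$df, v$df)
  write_vocabulary(v2, p2)
  expect_identical(readLines(p1), readLines(p2))

  m <- encode_features(sets, v)
  stem <- file.path(tempdir(), "mat")
  write_feature_matrix(m, stem)
  mm <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  expect_equal(unname(m), unname(mm))
  expect_equal(readLines(paste0(stem, ".features")), v$features)
})
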