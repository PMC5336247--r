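# Seven families of sparse binary document features. A feature key is a
# string "<FAMILY>:<value>"; composite values join their slots with "|"
# (e.g. "GR:subject|affects|*", "VC:L2|11"). Everything is case-folded
# except named-entity spans, which keep the verbatim surface.

#' The seven feature families
#'
#' `LBOW` lemmatized bag of words, `NBIGRAM` noun compound bigrams, `GR`
#' lexicalized grammatical relations, `NE` named entities, `VC` verb
#' clusters, `MESH` MeSH descriptors, `CHEM` chemical-list substances.
#'
#' @return Character vector of family codes.
#' @export
feature_families <- function() {
  c("LBOW", "NBIGRAM", "GR", "NE", "VC", "MESH", "CHEM")
}

# elementwise: value slots must already be "|"-joined
feature_key <- function(family, value) {
  paste0(family, ":", value)
}

#' Family of a feature key
#' @param keys character vector of feature keys.
#' @return Character vector of family codes.
#' @export
feature_family_of <- function(keys) sub(":.*$", "", keys)

#' Verb cluster lexicon
#'
#' Maps verb lemmas to a three-level semantic cluster path (one class id
#' per abstraction level); verbs sharing a path are semantically grouped
#' (e.g. *stimulate*/*activate*). The built-in lexicon is a small baseline;
#' a larger reference lexicon (such as a 399-verb hierarchical
#' classification of biomedical verbs) can be loaded from a TSV with
#' columns `verb`, `L1`, `L2`, `L3`.
#'
#' @param path optional TSV path; default built-in lexicon.
#' @return Object of class `verb_cluster_lexicon` with element `entries`:
#'   named list verb -> character vector of three class ids.
#' @export
verb_cluster_lexicon <- function(path = NULL) {
  x <- if (is.null(path)) .resource("verb_clusters.tsv", .read_tsv2)
       else .read_tsv2(path)
  check(ncol(x) >= 4L, "verb cluster lexicon needs columns verb, L1, L2, L3")
  entries <- lapply(seq_len(nrow(x)), function(i) {
    as.character(unlist(x[i, 2:4]))
  })
  names(entries) <- tolower(x[[1L]])
  check(!anyDuplicated(names(entries)), "duplicate verb in cluster lexicon")
  structure(list(entries = entries), class = "verb_cluster_lexicon")
}

#' @export
print.verb_cluster_lexicon <- function(x, ...) {
  cat(sprintf("Verb cluster lexicon: %d verbs, 3 abstraction levels\n",
              length(x$entries)))
  invisible(x)
}

# ---- per-family extraction --------------------------------------------------

.content_token <- function(surface) grepl("[A-Za-z0-9]", surface)

#' Lemmatized bag-of-words features
#' @param doc an `annotated_document` (lemmatized).
#' @return Character set of `LBOW:` feature keys, one per distinct lemma.
#' @export
extract_lbow <- function(doc) {
  lemmas <- unlist(lapply(doc$sentences, function(s) {
    s$lemma[.content_token(s$surface)]
  }))
  if (length(lemmas) == 0L) return(character(0))
  sort_c(unique(feature_key("LBOW", tolower(lemmas))))
}

#' Noun compound bigram features
#'
#' Adjacent token pairs both noun-tagged; surfaces are kept un-lemmatized
#' (so *drinking water* is never reduced to *drink water*), case-folded.
#'
#' @param doc an `annotated_document` (POS-tagged).
#' @return Character set of `NBIGRAM:` feature keys.
#' @export
extract_noun_bigrams <- function(doc) {
  out <- unlist(lapply(doc$sentences, function(s) {
    if (nrow(s) < 2L) return(character(0))
    i <- which(.is_noun(s$pos[-nrow(s)]) & .is_noun(s$pos[-1L]))
    if (length(i) == 0L) return(character(0))
    paste(tolower(s$surface[i]), tolower(s$surface[i + 1L]))
  }))
  if (length(out) == 0L) return(character(0))
  sort_c(unique(feature_key("NBIGRAM", out)))
}

#' Lexicalized grammatical-relation features
#'
#' Each dependency arc yields three patterns: the fully lexicalized triple
#' `(relation, head, dependent)` and the two single-wildcard variants
#' `(relation, head, *)` and `(relation, *, dependent)`.
#'
#' @param doc an `annotated_document` (parsed).
#' @return Character set of `GR:` feature keys.
#' @export
extract_gr_patterns <- function(doc) {
  a <- doc$arcs
  if (is.null(a) || nrow(a) == 0L) return(character(0))
  rel <- tolower(a$relation); h <- tolower(a$head); d <- tolower(a$dependent)
  keys <- c(feature_key("GR", paste(rel, h, d, sep = "|")),
            feature_key("GR", paste(rel, h, "*", sep = "|")),
            feature_key("GR", paste(rel, "*", d, sep = "|")))
  sort_c(unique(keys))
}

#' Named-entity features
#'
#' One feature per distinct (entity type, span) pair; spans keep their
#' verbatim surface.
#'
#' @param doc an `annotated_document` (NER-annotated).
#' @return Character set of `NE:` feature keys.
#' @export
extract_ne_features <- function(doc) {
  e <- doc$entities
  if (is.null(e) || nrow(e) == 0L) return(character(0))
  sort_c(unique(feature_key("NE", paste(e$entity_type, e$span_text,
                                        sep = "|"))))
}

#' Verb cluster features
#'
#' Every verb lemma found in the cluster lexicon activates the three
#' `(level, class id)` features of its cluster path; one in-lexicon verb
#' therefore contributes exactly three features, and verbs sharing a
#' cluster path contribute the same three.
#'
#' @param doc an `annotated_document` (lemmatized).
#' @param lexicon a [verb_cluster_lexicon()].
#' @return Character set of `VC:` feature keys.
#' @export
extract_verb_cluster_bits <- function(doc, lexicon = verb_cluster_lexicon()) {
  lemmas <- unique(unlist(lapply(doc$sentences, `[[`, "lemma")))
  verbs <- intersect(lemmas, names(lexicon$entries))
  if (length(verbs) == 0L) return(character(0))
  keys <- unlist(lapply(verbs, function(v) {
    path <- lexicon$entries[[v]]
    feature_key("VC", paste(c("L1", "L2", "L3"), path, sep = "|"))
  }))
  sort_c(unique(keys))
}

#' Metadata features (MeSH descriptors and chemical lists)
#'
#' @param record a [document_record()].
#' @return Character set of `MESH:` and `CHEM:` feature keys, case-folded.
#' @export
extract_metadata_features <- function(record) {
  keys <- c(if (length(record$mesh_terms))
              feature_key("MESH", tolower(record$mesh_terms)),
            if (length(record$chemicals))
              feature_key("CHEM", tolower(record$chemicals)))
  if (length(keys) == 0L) return(character(0))
  sort_c(unique(keys))
}

#' Extract all feature families from an annotated document
#'
#' @param doc an `annotated_document`.
#' @param families subset of [feature_families()] to extract.
#' @param vc_lexicon a [verb_cluster_lexicon()].
#' @return Character set of feature keys (union over families).
#' @export
extract_features <- function(doc, families = feature_families(),
                             vc_lexicon = verb_cluster_lexicon()) {
  bad <- setdiff(families, feature_families())
  check(length(bad) == 0L, "unknown feature family: %s",
        paste(bad, collapse = ", "))
  keys <- c(
    if ("LBOW" %in% families) extract_lbow(doc),
    if ("NBIGRAM" %in% families) extract_noun_bigrams(doc),
    if ("GR" %in% families) extract_gr_patterns(doc),
    if ("NE" %in% families) extract_ne_features(doc),
    if ("VC" %in% families) extract_verb_cluster_bits(doc, vc_lexicon),
    if ("MESH" %in% families || "CHEM" %in% families) {
      m <- extract_metadata_features(doc$record)
      m[feature_family_of(m) %in% families]
    })
  sort_c(unique(keys))
}

# ---- feature selection and encoding ----------------------------------------

#' Per-family document-frequency thresholds
#'
#' Features are kept only when their document frequency lies in
#' `[min_df, max_df]`; too-rare and too-common features are removed before
#' training. `max_df` may be given as an absolute count or as a fraction of
#' the corpus (`max_df_frac`); per-family overrides win over the defaults.
#'
#' @param min_df minimum document frequency (default 5).
#' @param max_df absolute maximum document frequency, or `NULL` to use
#'   `max_df_frac`.
#' @param max_df_frac maximum document frequency as a fraction of corpus
#'   size (default 0.3).
#' @param per_family named list of per-family overrides, each a list with
#'   any of `min_df`, `max_df`, `max_df_frac`.
#' @return List of class `df_thresholds`.
#' @export
df_thresholds <- function(min_df = 5L, max_df = NULL, max_df_frac = 0.3,
                          per_family = list()) {
  check(min_df >= 1L, "min_df must be >= 1")
  if (!is.null(max_df)) check(min_df <= max_df, "min_df must be <= max_df")
  bad <- setdiff(names(per_family), feature_families())
  check(length(bad) == 0L, "unknown feature family in thresholds: %s",
        paste(bad, collapse = ", "))
  structure(list(min_df = as.integer(min_df), max_df = max_df,
                 max_df_frac = max_df_frac, per_family = per_family),
            class = "df_thresholds")
}

.family_bounds <- function(thresholds, family, n_docs) {
  o <- thresholds$per_family[[family]] %||% list()
  min_df <- as.integer(o$min_df %||% thresholds$min_df)
  max_df <- o$max_df %||%
    (if (!is.null(o$max_df_frac)) ceiling(o$max_df_frac * n_docs) else NULL) %||%
    thresholds$max_df %||% ceiling(thresholds$max_df_frac * n_docs)
  check(min_df >= 1L && min_df <= max_df,
        "invalid thresholds for family %s: min_df=%d max_df=%s", family,
        min_df, format(max_df))
  c(min_df = min_df, max_df = as.integer(max_df))
}

#' Build a per-node feature vocabulary
#'
#' Counts document frequency (number of documents containing a feature) over
#' the training corpus and keeps features within the per-family `[min_df,
#' max_df]` band. Vocabularies are built independently per taxonomy node, so
#' every node classifier sees its own selected feature space. Ordering is
#' deterministic: family, then value (radix sort).
#'
#' @param feature_sets list of per-document feature-key sets (see
#'   [extract_features()]).
#' @param node taxonomy node slug the vocabulary belongs to.
#' @param thresholds a [df_thresholds()].
#' @param families families to admit (default all seven).
#' @return Object of class `feature_vocabulary`: `node`, `features` (ordered
#'   keys), `df` (named counts), `n_docs`, `bounds` (per-family matrix).
#' @export
build_vocabulary <- function(feature_sets, node = "all",
                             thresholds = df_thresholds(),
                             families = feature_families()) {
  check(length(feature_sets) > 0L, "empty corpus")
  n_docs <- length(feature_sets)
  keys <- unlist(lapply(feature_sets, unique), use.names = FALSE)
  keys <- keys[feature_family_of(keys) %in% families]
  df <- table(keys)
  fam <- feature_family_of(names(df))
  bounds <- vapply(feature_families(), .family_bounds, c(min_df = 0L, max_df = 0L),
                   thresholds = thresholds, n_docs = n_docs)
  keep <- df >= bounds["min_df", fam] & df <= bounds["max_df", fam]
  feats <- sort_c(names(df)[keep])
  structure(list(node = node, features = feats,
                 df = stats::setNames(as.integer(df[feats]), feats),
                 n_docs = n_docs, bounds = bounds),
            class = "feature_vocabulary")
}

#' @export
print.feature_vocabulary <- function(x, ...) {
  cat(sprintf("Feature vocabulary for node '%s': %d features over %d documents\n",
              x$node, length(x$features), x$n_docs))
  tab <- table(feature_family_of(x$features))
  for (f in names(tab)) cat(sprintf("  %-8s %d\n", f, tab[[f]]))
  invisible(x)
}

#' Encode documents against a vocabulary
#'
#' Sparse binary semantics: a cell is 1 iff the document contains the
#' feature; out-of-vocabulary features are ignored; repeated occurrences
#' change nothing.
#'
#' @param feature_sets list of per-document feature-key sets, or a single
#'   set (character vector).
#' @param vocab a [feature_vocabulary()].
#' @return For a list input, a dense 0/1 matrix (documents x features) with
#'   vocabulary keys as column names; for a single set, an integer vector of
#'   active (sorted) vocabulary indices.
#' @export
encode_features <- function(feature_sets, vocab) {
  if (is.character(feature_sets)) {
    return(sort(which(vocab$features %in% feature_sets)))
  }
  m <- matrix(0, nrow = length(feature_sets), ncol = length(vocab$features),
              dimnames = list(names(feature_sets), vocab$features))
  for (i in seq_along(feature_sets)) {
    m[i, vocab$features %in% feature_sets[[i]]] <- 1
  }
  m
}

#' Write / read a vocabulary as JSON
#'
#' Canonical serialization (byte-stable under write -> read -> write).
#'
#' @param vocab a [feature_vocabulary()].
#' @param path JSON file path.
#' @return `path` (write) / a `feature_vocabulary` (read).
#' @export
write_vocabulary <- function(vocab, path) {
  write_canonical_json(list(
    node = vocab$node, n_docs = vocab$n_docs,
    bounds = apply(vocab$bounds, 2L, as.list),
    features = vocab$features,
    df = as.list(vocab$df)), path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- read_json_file(path)
  feats <- as.character(unlist(x$features))
  bounds <- vapply(feature_families(), function(f) {
    c(min_df = as.integer(x$bounds[[f]]$min_df),
      max_df = as.integer(x$bounds[[f]]$max_df))
  }, c(min_df = 0L, max_df = 0L))
  structure(list(node = x$node, features = feats,
                 df = stats::setNames(as.integer(unlist(x$df)), names(x$df)),
                 n_docs = as.integer(x$n_docs), bounds = bounds),
            class = "feature_vocabulary")
}

#' Export an encoded matrix in MatrixMarket form
#'
#' Writes the binary document-feature matrix as MatrixMarket coordinate
#' text plus two index files (`<stem>.docs`, `<stem>.features`).
#'
#' @param m matrix from [encode_features()].
#' @param stem output path stem; files `<stem>.mtx`, `<stem>.docs`,
#'   `<stem>.features` are written.
#' @return `stem`, invisibly.
#' @export
write_feature_matrix <- function(m, stem) {
  nz <- which(m != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 2L], nz[, 1L]), , drop = FALSE]
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             sprintf("%d %d %d", nrow(m), ncol(m), nrow(nz)),
             sprintf("%d %d 1", nz[, 1L], nz[, 2L]))
  writeLines(lines, paste0(stem, ".mtx"), useBytes = TRUE)
  writeLines(rownames(m) %||% as.character(seq_len(nrow(m))),
             paste0(stem, ".docs"), useBytes = TRUE)
  writeLines(colnames(m), paste0(stem, ".features"), useBytes = TRUE)
  invisible(stem)
}
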