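# Seeded synthetic corpus generator. Generates abstracts whose token
# distributions, MeSH descriptors and chemical lists correlate with chosen
# taxonomy leaves, plus a pool of reviewed-but-irrelevant documents, so the
# whole pipeline is testable end to end without downloads. Two sentence
# modes: "svo" emits subject-verb-object templates the baseline tagger and
# finite-state parser handle, exercising all seven feature families;
# "lbow_only" emits verb-less token streams with function-word separators,
# so the planted signal reaches the lemmatized bag of words alone.

#' Specification for a synthetic corpus
#'
#' @param taxonomy an `exposure_taxonomy` the labels come from.
#' @param leaves leaf slugs that receive planted keyword signal (default:
#'   six well-separated leaves of the built-in taxonomy).
#' @param docs_per_leaf positive documents generated per leaf.
#' @param irrelevant_docs reviewed-but-irrelevant documents (empty label
#'   sets, background vocabulary only).
#' @param keywords_per_leaf size of each leaf's keyword vocabulary; the
#'   vocabularies are pairwise disjoint.
#' @param signal_prob per content-token probability that a positive
#'   document emits one of its leaf's keywords rather than a background
#'   word.
#' @param background_vocab_size number of distinct background words.
#' @param sentences_per_doc integer range `c(min, max)`.
#' @param content_tokens_per_sentence integer range `c(min, max)` of
#'   content tokens per sentence in `"lbow_only"` mode.
#' @param mode `"svo"` (templated subject-verb-object sentences; signal
#'   reaches all feature families) or `"lbow_only"` (verb-less streams;
#'   signal reaches only unigram features).
#' @param metadata_rate probability that a positive document carries a
#'   leaf-correlated MeSH descriptor / chemical name (`"svo"` mode only).
#' @param entity_rate probability per sentence of inserting a gazetteer
#'   entity phrase (`"svo"` mode only).
#' @param multilabel_rate probability that a positive document receives a
#'   second leaf label (its sentences then mix both keyword pools).
#' @param seed integer seed; the same spec and seed reproduce a
#'   byte-identical corpus.
#' @return List of class `synthetic_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(taxonomy = exposure_taxonomy(),
                                  leaves = c("blood", "urine", "hair_nail",
                                             "food", "dust", "outdoor_air"),
                                  docs_per_leaf = 150L,
                                  irrelevant_docs = 300L,
                                  keywords_per_leaf = 8L,
                                  signal_prob = 0.8,
                                  background_vocab_size = 500L,
                                  sentences_per_doc = c(4L, 8L),
                                  content_tokens_per_sentence = c(3L, 6L),
                                  mode = c("svo", "lbow_only"),
                                  metadata_rate = 0.5,
                                  entity_rate = 0.15,
                                  multilabel_rate = 0.1,
                                  seed = 1L) {
  mode <- match.arg(mode)
  leaves <- resolve_node(taxonomy, leaves)
  check(!anyDuplicated(leaves), "duplicate leaves in spec")
  for (p in c(signal_prob, metadata_rate, entity_rate, multilabel_rate)) {
    check(p >= 0 && p <= 1, "probabilities must lie in [0, 1]")
  }
  check(docs_per_leaf >= 1L && irrelevant_docs >= 0L && keywords_per_leaf >= 1L,
        "invalid corpus sizes")
  check(length(sentences_per_doc) == 2L &&
          sentences_per_doc[1L] <= sentences_per_doc[2L],
        "sentences_per_doc must be an increasing range")
  structure(list(taxonomy = taxonomy, leaves = leaves,
                 docs_per_leaf = as.integer(docs_per_leaf),
                 irrelevant_docs = as.integer(irrelevant_docs),
                 keywords_per_leaf = as.integer(keywords_per_leaf),
                 signal_prob = signal_prob,
                 background_vocab_size = as.integer(background_vocab_size),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 content_tokens_per_sentence =
                   as.integer(content_tokens_per_sentence),
                 mode = mode, metadata_rate = metadata_rate,
                 entity_rate = entity_rate,
                 multilabel_rate = multilabel_rate,
                 seed = as.integer(seed)),
            class = "synthetic_corpus_spec")
}

#' Keyword vocabulary of a synthetic leaf
#'
#' @param spec a [synthetic_corpus_spec()].
#' @param leaf leaf slug from `spec$leaves`.
#' @return Character vector of that leaf's planted keywords.
#' @export
leaf_keywords <- function(spec, leaf) {
  check(leaf %in% spec$leaves, "leaf %s not in spec", leaf)
  base <- gsub("_", "", leaf)
  sprintf("%skw%d", base, seq_len(spec$keywords_per_leaf))
}

.verb_s <- function(v) {
  if (grepl("(s|x|z|ch|sh)$", v)) paste0(v, "es")
  else if (grepl("[b-df-hj-np-tv-z]y$", v)) sub("y$", "ies", v)
  else paste0(v, "s")
}

.entity_phrases <- c("hemoglobin", "albumin", "glutathione", "lymphocytes",
                     "erythrocytes", "dna")

# uniform integer in [lo, hi]; safe when lo == hi (unlike sample(lo:hi, 1))
.rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

#' Generate a synthetic corpus
#'
#' Positive documents for a leaf embed its keywords (with per-token
#' probability `signal_prob`) into sentence templates; leaf-correlated MeSH
#' and chemical strings are attached at `metadata_rate`; irrelevant
#' documents draw only background vocabulary and get explicit empty label
#' sets. Gold annotations carry leaf labels; hierarchical closure is
#' applied downstream when training.
#'
#' @param spec a [synthetic_corpus_spec()].
#' @return List with `records` (list of [document_record()]s, pmids
#'   `SYN000001`...) and `annotations` (an [annotation_set()]).
#' @export
generate_corpus <- function(spec) {
  check(inherits(spec, "synthetic_corpus_spec"), "spec must be a synthetic_corpus_spec")
  tax <- spec$taxonomy
  kw <- lapply(stats::setNames(spec$leaves, spec$leaves), leaf_keywords,
               spec = spec)
  bg <- sprintf("bg%04d", seq_len(spec$background_vocab_size))
  verbs <- names(verb_cluster_lexicon()$entries)
  with_seed(spec$seed, {
    pick_word <- function(leaf_pool) {
      if (!is.null(leaf_pool) && stats::runif(1) < spec$signal_prob) {
        sample(leaf_pool, 1L)
      } else sample(bg, 1L)
    }
    svo_sentence <- function(leaf_pool) {
      n_subj <- .rint(1L, 2L)
      n_obj <- .rint(1L, 2L)
      subj <- vapply(seq_len(n_subj), function(i) pick_word(leaf_pool), "")
      obj <- vapply(seq_len(n_obj), function(i) pick_word(leaf_pool), "")
      verb <- .verb_s(sample(verbs, 1L))
      s <- c("The", subj, verb, "the", obj)
      if (stats::runif(1) < spec$entity_rate) {
        s <- c(s, "in", sample(.entity_phrases, 1L))
      }
      paste(c(s, "."), collapse = " ")
    }
    lbow_sentence <- function(leaf_pool) {
      m <- .rint(spec$content_tokens_per_sentence[1L],
                 spec$content_tokens_per_sentence[2L])
      words <- vapply(seq_len(m), function(i) pick_word(leaf_pool), "")
      fillers <- sample(c("of", "in", "for", "with"), m, replace = TRUE)
      toks <- as.vector(rbind(words, fillers))
      toks <- toks[-length(toks)]        # drop trailing filler
      toks[1L] <- paste0(toupper(substr(toks[1L], 1L, 1L)),
                         substr(toks[1L], 2L, nchar(toks[1L])))
      paste(c(toks, "."), collapse = " ")
    }
    make_doc <- function(pmid, labels) {
      pools <- if (length(labels)) kw[labels] else list(NULL)
      n_sent <- .rint(spec$sentences_per_doc[1L], spec$sentences_per_doc[2L])
      sents <- vapply(seq_len(n_sent), function(i) {
        pool <- pools[[1L + (i - 1L) %% length(pools)]]
        if (spec$mode == "svo") svo_sentence(pool) else lbow_sentence(pool)
      }, "")
      mesh <- "Humans"
      chem <- character(0)
      if (spec$mode == "svo" && length(labels)) {
        for (lf in labels) {
          if (stats::runif(1) < spec$metadata_rate) {
            mesh <- c(mesh, sprintf("mesh-%s", lf))
          }
          if (stats::runif(1) < spec$metadata_rate) {
            chem <- c(chem, sprintf("chem-%s", lf))
          }
        }
      }
      if (length(labels) == 0L && stats::runif(1) < 0.3) {
        mesh <- c(mesh, sample(c("Adult", "Female", "Male"), 1L))
      }
      title <- if (length(labels)) {
        sprintf("Synthetic study of %s", paste(labels, collapse = " and "))
      } else "Synthetic study with no exposure content"
      document_record(pmid = pmid, title = title,
                      abstract = paste(sents, collapse = " "),
                      mesh_terms = mesh, chemicals = chem,
                      journal = "Synthetic Journal of Exposure Science",
                      year = .rint(1993L, 2013L))
    }
    n_total <- length(spec$leaves) * spec$docs_per_leaf + spec$irrelevant_docs
    pmids <- sprintf("SYN%06d", seq_len(n_total))
    records <- vector("list", n_total)
    labels <- vector("list", n_total)
    i <- 0L
    for (leaf in spec$leaves) {
      for (d in seq_len(spec$docs_per_leaf)) {
        i <- i + 1L
        labs <- leaf
        if (length(spec$leaves) > 1L &&
            stats::runif(1) < spec$multilabel_rate) {
          labs <- c(labs, sample(setdiff(spec$leaves, leaf), 1L))
        }
        records[[i]] <- make_doc(pmids[i], labs)
        labels[[i]] <- labs
      }
    }
    for (d in seq_len(spec$irrelevant_docs)) {
      i <- i + 1L
      records[[i]] <- make_doc(pmids[i], character(0))
      labels[[i]] <- character(0)
    }
    names(labels) <- pmids
    list(records = records,
         annotations = annotation_set(labels, tax, annotator = "synthetic"))
  })
}

#' Generate a second, noisier annotator
#'
#' Returns an annotation set in which every (document, node) membership is
#' independently flipped with probability `disagreement_rate`, emulating a
#' second human annotator for inter-annotator agreement analysis. With
#' rate 0 the sets are identical (kappa 1 per node); the expected kappa for
#' a node of prevalence p follows in closed form from the flip rate.
#'
#' @param annotations an [annotation_set()].
#' @param taxonomy the `exposure_taxonomy` the labels live in.
#' @param disagreement_rate flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A new [annotation_set()] (annotator suffixed `-b`).
#' @export
generate_annotator_pair <- function(annotations,
                                    taxonomy = exposure_taxonomy(),
                                    disagreement_rate = 0.05, seed = 1L) {
  check(disagreement_rate >= 0 && disagreement_rate <= 1,
        "disagreement_rate must lie in [0, 1]")
  nodes <- taxonomy_nodes(taxonomy)
  pmids <- names(annotations$labels)
  new_labels <- with_seed(seed, {
    lapply(stats::setNames(pmids, pmids), function(p) {
      cur <- annotations$labels[[p]]
      flips <- stats::runif(length(nodes)) < disagreement_rate
      member <- nodes %in% cur
      nodes[xor(member, flips)]
    })
  })
  annotation_set(new_labels, taxonomy,
                 annotator = paste0(annotations$annotator, "-b"))
}
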