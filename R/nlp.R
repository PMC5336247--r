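# Deterministic NLP pipeline: text cleaning, tokenization/sentence
# splitting, Penn-Treebank POS tagging, POS-aware lemmatization, gazetteer
# named-entity recognition, and a finite-state dependency baseline emitting
# subject/object arcs. Every stage is an adapter slot: the rule-based
# baselines shipped here can be replaced per stage through the adapter
# registry, so richer external tools plug in without touching the feature
# or classifier code.

.pkg_cache <- new.env(parent = emptyenv())

.resource <- function(file, loader) {
  key <- paste0("res_", file)
  if (!exists(key, envir = .pkg_cache)) {
    path <- system.file("extdata", file, package = "expotax")
    check(nzchar(path), "missing package resource: %s", file)
    assign(key, loader(path), envir = .pkg_cache)
  }
  get(key, envir = .pkg_cache)
}

.read_tsv2 <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  quote = "", comment.char = "")
  x
}

.pos_lexicon <- function() {
  x <- .resource("pos_lexicon.tsv", .read_tsv2)
  stats::setNames(x[[2L]], x[[1L]])
}

.lemma_exceptions <- function() {
  x <- .resource("lemma_exceptions.tsv", .read_tsv2)
  stats::setNames(x[[2L]], x[[1L]])
}

.verb_stems <- function() {
  c(names(verb_cluster_lexicon()$entries), "be", "have")
}

#' Default named-entity gazetteer
#'
#' The baseline recognizer matches phrases from a gazetteer over the five
#' biomedical entity types `DNA`, `RNA`, `protein`, `cell_line` and
#' `cell_type`. The built-in gazetteer is a small plain-text resource; users
#' can supply their own via the same two-column (type, phrase) layout.
#'
#' @param path optional path to a custom gazetteer TSV.
#' @return data frame with columns `type` and `phrase`.
#' @export
ner_gazetteer <- function(path = NULL) {
  x <- if (is.null(path)) .resource("gazetteer.tsv", .read_tsv2)
       else .read_tsv2(path)
  g <- data.frame(type = x[[1L]], phrase = x[[2L]], stringsAsFactors = FALSE)
  bad <- setdiff(g$type, entity_types())
  check(length(bad) == 0L, "unknown entity type in gazetteer: %s",
        paste(unique(bad), collapse = ", "))
  g
}

#' The closed set of named-entity types
#' @return Character vector of the five entity types.
#' @export
entity_types <- function() c("DNA", "RNA", "protein", "cell_line", "cell_type")

# ---- adapter registry -------------------------------------------------------

.nlp_stages <- c("tokenize", "pos", "lemma", "ner", "parse")

.adapter_registry <- function() {
  if (!exists("adapters", envir = .pkg_cache)) {
    reg <- new.env(parent = emptyenv())
    assign("adapters", reg, envir = .pkg_cache)
    register_nlp_adapter("tokenize", "baseline", segment_text)
    register_nlp_adapter("pos", "baseline", pos_tag)
    register_nlp_adapter("lemma", "baseline", lemmatize_tokens)
    register_nlp_adapter("ner", "baseline", recognize_entities)
    register_nlp_adapter("parse", "baseline", parse_dependencies)
  }
  get("adapters", envir = .pkg_cache)
}

#' Register an NLP adapter
#'
#' Installs a replacement implementation for one pipeline stage. The
#' function must accept and return the same shapes as the corresponding
#' baseline ([segment_text()], [pos_tag()], [lemmatize_tokens()],
#' [recognize_entities()], [parse_dependencies()]).
#'
#' @param stage one of `"tokenize"`, `"pos"`, `"lemma"`, `"ner"`, `"parse"`.
#' @param name adapter name selected through [nlp_config()].
#' @param fn the adapter function.
#' @export
register_nlp_adapter <- function(stage, name, fn) {
  stage <- match.arg(stage, .nlp_stages)
  check(is.function(fn), "adapter must be a function")
  reg <- if (exists("adapters", envir = .pkg_cache))
    get("adapters", envir = .pkg_cache) else .adapter_registry()
  assign(paste(stage, name, sep = "."), fn, envir = reg)
  invisible(NULL)
}

nlp_adapter <- function(stage, name = "baseline") {
  reg <- .adapter_registry()
  key <- paste(stage, name, sep = ".")
  check(exists(key, envir = reg), "no adapter '%s' registered for stage %s",
        name, stage)
  get(key, envir = reg)
}

#' NLP pipeline configuration
#'
#' @param include_title prepend the record title to the classified text
#'   (default `FALSE`: the abstract alone is classified).
#' @param adapters named character vector selecting an adapter per stage
#'   (defaults to the rule-based baselines).
#' @param gazetteer gazetteer data frame for the NER baseline.
#' @return List of class `nlp_config`.
#' @export
nlp_config <- function(include_title = FALSE, adapters = character(0),
                       gazetteer = NULL) {
  sel <- stats::setNames(rep("baseline", length(.nlp_stages)), .nlp_stages)
  if (length(adapters)) {
    bad <- setdiff(names(adapters), .nlp_stages)
    check(length(bad) == 0L, "unknown NLP stage: %s", paste(bad, collapse = ", "))
    sel[names(adapters)] <- adapters
  }
  structure(list(include_title = isTRUE(include_title), adapters = sel,
                 gazetteer = gazetteer),
            class = "nlp_config")
}

# ---- stage baselines --------------------------------------------------------

#' Clean raw abstract text
#'
#' Removes control characters, normalizes unicode spaces to ASCII space,
#' and collapses whitespace runs. Total and idempotent.
#'
#' @param raw character vector.
#' @return Cleaned character vector of the same length.
#' @export
clean_text <- function(raw) {
  x <- as.character(raw)
  x[is.na(x)] <- ""
  # unicode spaces -> ASCII space; zero-width and control characters removed
  x <- gsub("(*UTF)[\\x{00A0}\\x{2000}-\\x{200A}\\x{202F}\\x{205F}\\x{3000}]", " ", x, perl = TRUE)
  x <- gsub("(*UTF)[\\x{200B}-\\x{200D}\\x{FEFF}\\x{0001}-\\x{0008}\\x{000B}\\x{000C}\\x{000E}-\\x{001F}\\x{007F}]", "", x, perl = TRUE)
  x <- gsub("[\t\r\n]", " ", x)
  x <- gsub(" {2,}", " ", x)
  trimws(x)
}

# Abbreviations whose trailing period never ends a sentence.
.abbreviations <- c("e.g", "i.e", "et al", "al", "etc", "vs", "ca", "approx",
                    "fig", "figs", "no", "dr", "prof", "resp", "cf")

# word token: alphanumeric runs glued by internal - ' . / , (keeps
# hyphenated chemical names like 2,4-D and decimal numbers intact);
# otherwise single characters
.token_regex <- "[A-Za-z0-9]+(?:[-'./,][A-Za-z0-9]+)*|[^A-Za-z0-9 ]"

.tokenize_one <- function(sentence) {
  m <- gregexpr(.token_regex, sentence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(character(0))
  regmatches(sentence, list(m))[[1L]]
}

.split_sentences <- function(text) {
  if (!nzchar(text)) return(character(0))
  n <- nchar(text)
  ends <- integer(0)
  hits <- gregexpr("[.!?]", text)[[1L]]
  if (hits[1L] != -1L) {
    for (i in hits) {
      ch <- substr(text, i, i)
      nxt <- if (i < n) substr(text, i + 1L, i + 1L) else ""
      if (nzchar(nxt) && nxt != " ") next
      if (ch == ".") {
        # preceding word (letters/digits/periods run)
        j <- i - 1L
        while (j >= 1L && grepl("[A-Za-z0-9.]", substr(text, j, j))) j <- j - 1L
        prev <- substr(text, j + 1L, i - 1L)
        prev_clean <- tolower(gsub("\\.+$", "", prev))
        if (prev_clean %in% .abbreviations) next
        if (grepl("^[A-Z]$", prev)) next      # single-letter initial
        # require following sentence to open with capital or digit
        rest <- sub("^ +", "", substr(text, i + 1L, n))
        if (nzchar(rest) && !grepl("^[A-Z0-9(\"']", rest)) next
      }
      ends <- c(ends, i)
    }
  }
  ends <- unique(c(ends, n))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- vapply(seq_along(ends), function(s) {
    trimws(substr(text, starts[s], ends[s]))
  }, "")
  out[nzchar(out)]
}

#' Tokenize and sentence-split cleaned text
#'
#' Baseline rules: sentences end at `.`, `!` or `?` followed by whitespace,
#' unless the period closes a listed abbreviation or a single-letter
#' initial, and (for periods) only when the next sentence opens with a
#' capital, digit, bracket or quote. Word tokens are alphanumeric runs;
#' internal `-`, `'`, `.` and `/` are kept so hyphenated chemical names and
#' decimal numbers stay single tokens.
#'
#' @param text a cleaned string (see [clean_text()]).
#' @return List of sentences; each sentence is a data frame with columns
#'   `surface`, `pos`, `lemma` (the latter two `NA` until tagged), rows in
#'   token position order.
#' @export
segment_text <- function(text) {
  sents <- .split_sentences(text)
  lapply(sents, function(s) {
    toks <- .tokenize_one(s)
    data.frame(surface = toks, pos = NA_character_, lemma = NA_character_,
               stringsAsFactors = FALSE)
  })
}

# vectorized over a sentence's tokens; rule order: punctuation/number ->
# closed-class lexicon -> verb morphology against the verb lexicon ->
# suffix heuristics -> default NN
.tag_tokens <- function(surface) {
  n <- length(surface)
  lower <- tolower(surface)
  lex <- .pos_lexicon()
  stems <- .verb_stems()
  stemy <- function(x) x %in% stems
  tag <- rep(NA_character_, n)
  set <- function(tag_now, cond, value) {
    cond <- is.na(tag_now) & cond
    tag_now[cond] <- value[cond]
    tag_now
  }
  punct <- c("." = ".", "!" = ".", "?" = ".", "," = ",", "(" = "(",
             "[" = "(", ")" = ")", "]" = ")", ";" = ":", ":" = ":",
             "\"" = ":", "'" = ":", "%" = ":")
  tag <- set(tag, surface %in% names(punct), unname(punct[surface]))
  tag <- set(tag, grepl("^[0-9]+([./,-][0-9]+)*$", surface), rep("CD", n))
  tag <- set(tag, !is.na(lex[lower]), unname(lex[lower]))
  tag <- set(tag, stemy(lower), rep("VB", n))
  tag <- set(tag, stemy(sub("s$", "", lower)) | stemy(sub("es$", "", lower)),
             rep("VBZ", n))
  has_ed <- grepl("ed$", lower)
  tag <- set(tag, has_ed & (stemy(sub("ed$", "", lower)) |
                              stemy(sub("d$", "", lower))), rep("VBD", n))
  has_ing <- grepl("ing$", lower)
  tag <- set(tag, has_ing & (stemy(sub("ing$", "", lower)) |
                               stemy(paste0(sub("ing$", "", lower), "e"))),
             rep("VBG", n))
  tag <- set(tag, has_ed & nchar(lower) > 3L, rep("VBD", n))
  tag <- set(tag, has_ing & nchar(lower) > 4L, rep("VBG", n))
  tag <- set(tag, grepl("ly$", lower) & nchar(lower) > 3L, rep("RB", n))
  tag <- set(tag, grepl("(ous|ive|ic|ical|ary)$", lower) & nchar(lower) > 4L,
             rep("JJ", n))
  tag <- set(tag, grepl("[a-z]s$", lower) & !grepl("(ss|us|is)$", lower),
             rep("NNS", n))
  tag <- set(tag, c(FALSE, rep(TRUE, max(0L, n - 1L))) &
               grepl("^[A-Z]", surface), rep("NNP", n))
  tag[is.na(tag)] <- "NN"
  tag
}

#' Part-of-speech tagging (baseline)
#'
#' Lexicon lookup for closed-class words, verb morphology against the verb
#' lexicon, then suffix heuristics with default `NN`. Tags follow the Penn
#' Treebank set.
#'
#' @param sentences output of [segment_text()].
#' @return The sentences with the `pos` column filled.
#' @export
pos_tag <- function(sentences) {
  lapply(sentences, function(s) {
    if (nrow(s) == 0L) return(s)
    s$pos <- .tag_tokens(s$surface)
    s
  })
}

# one token; kept scalar for clarity, hot path cached below
.lemma_one <- function(lower, pos, exc, stems) {
  if (!is.na(exc[lower])) return(unname(exc[lower]))
  if (startsWith(pos, "V")) {
    if (pos %in% c("VBD", "VBN")) {
      if (grepl("ied$", lower)) return(sub("ied$", "y", lower))
      if (grepl("ed$", lower)) {
        s1 <- sub("ed$", "", lower)           # wanted -> want
        s2 <- sub("d$", "", lower)            # measured -> measure
        if (s1 %in% stems) return(s1)
        if (s2 %in% stems) return(s2)
        if (grepl("([b-df-hj-np-tv-z])\\1$", s1))
          return(sub(".$", "", s1))           # stopped -> stop
        return(s1)
      }
    }
    if (pos == "VBZ") {
      if (grepl("ies$", lower)) return(sub("ies$", "y", lower))
      s1 <- sub("es$", "", lower)
      if (s1 %in% stems) return(s1)
      s2 <- sub("s$", "", lower)
      if (s2 %in% stems || grepl("s$", lower)) return(s2)
    }
    if (pos == "VBG" && grepl("ing$", lower)) {
      s1 <- sub("ing$", "", lower)
      if (s1 %in% stems) return(s1)
      if (paste0(s1, "e") %in% stems) return(paste0(s1, "e"))
      if (grepl("([b-df-hj-np-tv-z])\\1$", s1)) return(sub(".$", "", s1))
      return(s1)
    }
    return(lower)
  }
  if (pos == "NNS") {
    if (grepl("ies$", lower)) return(sub("ies$", "y", lower))
    if (grepl("(xes|ches|shes|sses|zes)$", lower)) return(sub("es$", "", lower))
    if (grepl("s$", lower) && !grepl("ss$", lower)) return(sub("s$", "", lower))
  }
  lower
}

# memoized (surface, pos) -> lemma map; corpora reuse a small vocabulary so
# the cache hit rate is high
.lemma_cached <- function(lower, pos) {
  if (!exists("lemma_memo", envir = .pkg_cache)) {
    assign("lemma_memo", new.env(parent = emptyenv(), hash = TRUE),
           envir = .pkg_cache)
  }
  memo <- get("lemma_memo", envir = .pkg_cache)
  exc <- .lemma_exceptions()
  stems <- .verb_stems()
  vapply(seq_along(lower), function(i) {
    key <- paste0(pos[i], "\r", lower[i])
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- .lemma_one(lower[i], pos[i], exc, stems)
    memo[[key]] <- val
    val
  }, "")
}

#' Lemmatization (baseline)
#'
#' Exception lexicon first (irregular plurals and the like), then POS-aware
#' suffix rules; output is lowercased.
#'
#' @param sentences POS-tagged sentences (see [pos_tag()]).
#' @return The sentences with the `lemma` column filled.
#' @export
lemmatize_tokens <- function(sentences) {
  lapply(sentences, function(s) {
    if (nrow(s) == 0L) return(s)
    s$lemma <- .lemma_cached(tolower(s$surface), s$pos)
    s
  })
}

#' Named-entity recognition (baseline)
#'
#' Gazetteer matcher over token sequences: case-insensitive, longest match
#' wins, matches never overlap, scanning left to right within each
#' sentence. Spans are reported with their original (verbatim) surface.
#'
#' @param sentences segmented sentences.
#' @param gazetteer data frame (`type`, `phrase`); default built-in.
#' @return data frame with columns `entity_type`, `span_text`,
#'   `sentence_index`, `start`, `end` (token positions).
#' @export
recognize_entities <- function(sentences, gazetteer = NULL) {
  if (is.null(gazetteer)) gazetteer <- ner_gazetteer()
  empty <- data.frame(entity_type = character(0), span_text = character(0),
                      sentence_index = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (nrow(gazetteer) == 0L || length(sentences) == 0L) return(empty)
  phrase_toks <- strsplit(tolower(gazetteer$phrase), " ", fixed = TRUE)
  maxlen <- max(lengths(phrase_toks))
  key <- vapply(phrase_toks, paste, "", collapse = "")
  type_of <- stats::setNames(gazetteer$type, key)
  out <- empty
  for (si in seq_along(sentences)) {
    toks <- sentences[[si]]$surface
    low <- tolower(toks)
    i <- 1L
    while (i <= length(toks)) {
      hit_len <- 0L
      for (L in seq_len(min(maxlen, length(toks) - i + 1L))) {
        cand <- paste(low[i:(i + L - 1L)], collapse = "")
        if (!is.na(type_of[cand])) hit_len <- L
      }
      if (hit_len > 0L) {
        cand <- paste(low[i:(i + hit_len - 1L)], collapse = "")
        out <- rbind(out, data.frame(
          entity_type = unname(type_of[cand]),
          span_text = paste(toks[i:(i + hit_len - 1L)], collapse = " "),
          sentence_index = si, start = i, end = i + hit_len - 1L,
          stringsAsFactors = FALSE))
        i <- i + hit_len
      } else i <- i + 1L
    }
  }
  out
}

.is_noun <- function(pos) pos %in% c("NN", "NNS", "NNP", "NNPS")

#' Dependency parsing (finite-state baseline)
#'
#' Emits subject and object arcs from the pattern *noun group -- verb
#' (group) -- noun group*: the head noun (last noun) of the preceding group
#' is the subject of the main verb (last verb of a verb group), the head
#' noun of the following group its object. Sentences without the pattern
#' yield no arcs. External parsers may replace this stage through the
#' adapter registry and emit richer relation inventories.
#'
#' @param sentences POS-tagged sentences.
#' @return data frame with columns `relation`, `head`, `dependent`,
#'   `sentence_index`; words are case-folded.
#' @export
parse_dependencies <- function(sentences) {
  out <- data.frame(relation = character(0), head = character(0),
                    dependent = character(0), sentence_index = integer(0),
                    stringsAsFactors = FALSE)
  rows <- list()
  for (si in seq_along(sentences)) {
    s <- sentences[[si]]
    if (nrow(s) == 0L) next
    pos <- s$pos
    n <- nrow(s)
    i <- 1L
    pending_subject <- NA_character_
    pending_verb <- NA_character_
    while (i <= n) {
      if (.is_noun(pos[i])) {
        # maximal noun group: JJ/JJR/CD/NN* run; head = last noun in the run
        j <- i
        last_noun <- i
        while (j + 1L <= n && (pos[j + 1L] %in% c("JJ", "JJR", "CD") ||
                               .is_noun(pos[j + 1L]))) {
          j <- j + 1L
          if (.is_noun(pos[j])) last_noun <- j
        }
        h <- tolower(s$surface[last_noun])
        if (!is.na(pending_verb)) {
          rows[[length(rows) + 1L]] <- list("object", pending_verb, h, si)
          pending_verb <- NA_character_
        }
        pending_subject <- h
        i <- j + 1L
      } else if (startsWith(pos[i], "VB")) {
        # verb group (VB*/RB/MD run): the final VB* token is the main verb
        j <- i
        while (j + 1L <= n && (startsWith(pos[j + 1L], "VB") ||
                               pos[j + 1L] %in% c("RB", "MD"))) j <- j + 1L
        main <- max(which(startsWith(pos[i:j], "VB"))) + i - 1L
        v <- tolower(s$surface[main])
        if (!is.na(pending_subject)) {
          rows[[length(rows) + 1L]] <- list("subject", v, pending_subject, si)
          pending_verb <- v
          pending_subject <- NA_character_
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(rows)) {
    out <- data.frame(
      relation = vapply(rows, `[[`, "", 1L),
      head = vapply(rows, `[[`, "", 2L),
      dependent = vapply(rows, `[[`, "", 3L),
      sentence_index = vapply(rows, function(r) as.integer(r[[4L]]), 0L),
      stringsAsFactors = FALSE)
  }
  out
}

# ---- full pipeline ----------------------------------------------------------

#' Annotate a document record
#'
#' Runs the full pipeline (clean, segment, POS-tag, lemmatize, NER, parse)
#' over the record's abstract (optionally title + abstract) using the
#' adapters selected in `config`.
#'
#' @param record a [document_record()].
#' @param config an [nlp_config()].
#' @return Object of class `annotated_document`: list with `record`,
#'   `sentences`, `arcs`, `entities`.
#' @export
annotate_document <- function(record, config = nlp_config()) {
  check(inherits(record, "document_record"), "record must be a document_record")
  text <- if (config$include_title)
    paste(record$title, record$abstract) else record$abstract
  text <- clean_text(text)
  tokenize <- nlp_adapter("tokenize", config$adapters[["tokenize"]])
  tag      <- nlp_adapter("pos", config$adapters[["pos"]])
  lemma    <- nlp_adapter("lemma", config$adapters[["lemma"]])
  ner      <- nlp_adapter("ner", config$adapters[["ner"]])
  parse    <- nlp_adapter("parse", config$adapters[["parse"]])
  sents <- lemma(tag(tokenize(text)))
  ents <- if (identical(config$adapters[["ner"]], "baseline"))
    ner(sents, gazetteer = config$gazetteer) else ner(sents)
  arcs <- tryCatch(parse(sents), error = function(e) {
    warning("dependency adapter failed; empty arc list: ",
            conditionMessage(e), call. = FALSE)
    parse_dependencies(list())
  })
  structure(list(record = record, sentences = sents, arcs = arcs,
                 entities = ents),
            class = "annotated_document")
}

#' Annotate a list of records
#'
#' @param records list of [document_record()]s.
#' @param config an [nlp_config()].
#' @return Named list (by pmid) of `annotated_document`s.
#' @export
annotate_corpus <- function(records, config = nlp_config()) {
  out <- lapply(records, annotate_document, config = config)
  names(out) <- vapply(records, `[[`, "", "pmid")
  out
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("Annotated document <%s>: %d sentence(s), %d arc(s), %d entity mention(s)\n",
              x$record$pmid, length(x$sentences), nrow(x$arcs),
              nrow(x$entities)))
  invisible(x)
}
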