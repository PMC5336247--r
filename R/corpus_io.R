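# Reading and writing abstract records, annotation sets and fold
# assignments. Two record dialects are supported: PubMed XML
# (PubmedArticleSet) and tagged MEDLINE text. The package's canonical
# serialization is the MEDLINE dialect written by write_medline(), which is
# byte-stable under read -> write.

#' Construct a document record
#'
#' One PubMed-style abstract record: identifier, title, abstract text and
#' metadata (MeSH descriptors, chemical substance names, journal, year).
#'
#' @param pmid nonempty identifier string.
#' @param title,abstract text; `abstract` may be empty (the record is kept
#'   and flagged via `no_abstract`).
#' @param mesh_terms,chemicals character vectors (possibly empty).
#' @param journal journal name.
#' @param year publication year (integer or `NA`).
#' @return A list of class `document_record`.
#' @export
document_record <- function(pmid, title = "", abstract = "",
                            mesh_terms = character(0),
                            chemicals = character(0),
                            journal = "", year = NA_integer_) {
  pmid <- as.character(pmid)
  check(length(pmid) == 1L && nzchar(pmid), "pmid must be a nonempty string")
  structure(list(pmid = pmid,
                 title = as.character(title),
                 abstract = as.character(abstract),
                 mesh_terms = as.character(mesh_terms),
                 chemicals = as.character(chemicals),
                 journal = as.character(journal),
                 year = as.integer(year),
                 no_abstract = !nzchar(as.character(abstract))),
            class = "document_record")
}

#' @export
print.document_record <- function(x, ...) {
  cat(sprintf("<%s> %s (%s, %s)\n", x$pmid, x$title, x$journal, x$year))
  cat(sprintf("  abstract: %d chars; MeSH: %d; chemicals: %d\n",
              nchar(x$abstract), length(x$mesh_terms), length(x$chemicals)))
  invisible(x)
}

.dedupe_records <- function(records) {
  pmids <- vapply(records, `[[`, "", "pmid")
  if (anyDuplicated(pmids)) {
    warning("duplicate PMIDs in input; last record wins: ",
            paste(unique(pmids[duplicated(pmids)]), collapse = ", "),
            call. = FALSE)
    records <- records[!duplicated(pmids, fromLast = TRUE)]
  }
  records
}

#' Read records from tagged MEDLINE text
#'
#' Parses the plain MEDLINE dialect (`PMID- `, `TI  - `, `AB  - `, `JT  - `,
#' `DP  - `, `MH  - `, `RN  - ` tags; continuation lines indented six
#' spaces; records separated by blank lines). `RN` values of the registry
#' form `number (Name)` yield the parenthesised substance name; other values
#' are taken verbatim.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return List of [document_record()]s.
#' @export
read_medline <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else {
    check(!is.null(path) && file.exists(path), "MEDLINE file not found: %s",
          path %||% "<missing>")
    readLines(path, warn = FALSE)
  }
  records <- list()
  fields <- list()
  tag <- NULL
  flush_field <- NULL
  cur_tag <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_tag)) {
      fields[[length(fields) + 1L]] <<- list(tag = cur_tag, value = cur_val)
    }
    cur_tag <<- NULL
    cur_val <<- NULL
  }
  end_record <- function() {
    flush()
    if (length(fields) == 0L) return()
    tags <- vapply(fields, `[[`, "", "tag")
    vals <- vapply(fields, `[[`, "", "value")
    get1 <- function(tg) {
      i <- which(tags == tg)
      if (length(i) == 0L) "" else vals[i[1L]]
    }
    pmid <- get1("PMID")
    check(nzchar(pmid), "MEDLINE record without PMID (record %d)",
          length(records) + 1L)
    rn <- vals[tags == "RN"]
    paren <- regmatches(rn, regexec("^[^ ()]+ \\((.+)\\)$", rn))
    chem <- vapply(seq_along(rn), function(i) {
      if (length(paren[[i]]) == 2L) paren[[i]][2L] else rn[i]
    }, "")
    dp <- get1("DP")
    year <- suppressWarnings(as.integer(substr(dp, 1L, 4L)))
    records[[length(records) + 1L]] <<- document_record(
      pmid = pmid, title = get1("TI"), abstract = get1("AB"),
      mesh_terms = vals[tags == "MH"], chemicals = chem,
      journal = get1("JT"), year = year)
    fields <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { end_record(); next }
    if (grepl("^[A-Z0-9]{1,4} *- ", ln)) {
      flush()
      m <- regmatches(ln, regexec("^([A-Z0-9]{1,4}) *- (.*)$", ln))[[1L]]
      cur_tag <- m[2L]
      cur_val <- m[3L]
    } else if (grepl("^      ", ln) && !is.null(cur_tag)) {
      cur_val <- paste(cur_val, trimws(ln))
    } else {
      stop(sprintf("malformed MEDLINE line %d: %s", i, ln), call. = FALSE)
    }
  }
  end_record()
  .dedupe_records(records)
}

#' Write records as canonical MEDLINE text
#'
#' Fields are emitted in fixed order (PMID, TI, AB, JT, DP, MH..., RN...)
#' with no line wrapping, so write -> read -> write is byte identical.
#'
#' @param records list of [document_record()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_medline <- function(records, path) {
  fmt <- function(tag, value) sprintf("%-4s- %s", tag, value)
  out <- unlist(lapply(records, function(r) {
    lines <- c(fmt("PMID", r$pmid))
    if (nzchar(r$title))    lines <- c(lines, fmt("TI", r$title))
    if (nzchar(r$abstract)) lines <- c(lines, fmt("AB", r$abstract))
    if (nzchar(r$journal))  lines <- c(lines, fmt("JT", r$journal))
    if (!is.na(r$year))     lines <- c(lines, fmt("DP", r$year))
    c(lines, vapply(r$mesh_terms, function(m) fmt("MH", m), ""),
      vapply(r$chemicals, function(ch) fmt("RN", ch), ""), "")
  }))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read records from PubMed XML
#'
#' Parses a `PubmedArticleSet` document: PMID, article title, abstract text
#' (multiple `AbstractText` sections are joined with a space), MeSH
#' descriptor names, chemical substance names, journal title and publication
#' year.
#'
#' @param path path to a PubMed XML file.
#' @return List of [document_record()]s.
#' @export
read_pubmed_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  check(length(arts) > 0L, "no PubmedArticle elements found in %s", path)
  records <- lapply(arts, function(a) {
    txt <- function(xp) {
      n <- xml2::xml_find_first(a, xp)
      if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
    }
    all_txt <- function(xp) xml2::xml_text(xml2::xml_find_all(a, xp))
    abstract <- paste(all_txt(".//Abstract/AbstractText"), collapse = " ")
    year <- suppressWarnings(as.integer(
      txt(".//Journal//PubDate/Year")))
    document_record(
      pmid = txt(".//MedlineCitation/PMID"),
      title = txt(".//ArticleTitle"),
      abstract = trimws(abstract),
      mesh_terms = all_txt(".//MeshHeadingList/MeshHeading/DescriptorName"),
      chemicals = all_txt(".//ChemicalList/Chemical/NameOfSubstance"),
      journal = txt(".//Journal/Title"),
      year = year)
  })
  .dedupe_records(records)
}

#' Construct an annotation set
#'
#' Maps PMIDs to sets of taxonomy node labels. An explicit empty set means
#' the document was reviewed but judged irrelevant for the whole taxonomy;
#' such documents serve as negative examples for every node.
#'
#' @param labels named list: pmid -> character vector of node slugs/display
#'   names (possibly empty).
#' @param taxonomy an `exposure_taxonomy` used to validate labels.
#' @param annotator annotator identifier.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(labels, taxonomy, annotator = "annotator") {
  check(!is.null(names(labels)) && all(nzchar(names(labels))),
        "labels must be a named list keyed by pmid")
  check(!anyDuplicated(names(labels)), "duplicate pmid in annotation set: %s",
        paste(unique(names(labels)[duplicated(names(labels))]), collapse = ", "))
  labels <- lapply(stats::setNames(names(labels), names(labels)), function(p) {
    lb <- labels[[p]]
    if (length(lb) == 0L) return(character(0))
    tryCatch(sort_c(unique(resolve_node(taxonomy, lb))),
             error = function(e) stop(sprintf("pmid %s: %s", p,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  structure(list(labels = labels, annotator = as.character(annotator)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  n <- length(x$labels)
  nrel <- sum(vapply(x$labels, length, 0L) > 0L)
  cat(sprintf("Annotation set (%s): %d documents, %d annotated, %d irrelevant\n",
              x$annotator, n, nrel, n - nrel))
  invisible(x)
}

#' Read annotations from TSV or JSON
#'
#' TSV dialect: one row per document, `pmid<TAB>semicolon-joined node
#' labels`; an empty label field marks a reviewed-but-irrelevant document.
#' JSON dialect: object mapping pmid to an array of labels.
#'
#' @param path annotation file (`.tsv`/`.txt` or `.json`).
#' @param taxonomy an `exposure_taxonomy`.
#' @param annotator annotator identifier recorded in the set.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, taxonomy, annotator = "annotator") {
  check(file.exists(path), "annotation file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- read_json_file(path)
    labels <- lapply(raw, function(v) as.character(unlist(v)))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    pmids <- vapply(parts, `[[`, "", 1L)
    check(!anyDuplicated(pmids), "duplicate pmid rows in %s: %s", path,
          paste(unique(pmids[duplicated(pmids)]), collapse = ", "))
    labels <- lapply(parts, function(p) {
      if (length(p) < 2L || !nzchar(p[2L])) character(0)
      else strsplit(p[2L], ";", fixed = TRUE)[[1L]]
    })
    names(labels) <- pmids
  }
  annotation_set(labels, taxonomy, annotator = annotator)
}

#' Write annotations as canonical TSV
#'
#' Rows ordered by pmid (radix sort); labels are slugs joined with `;`.
#' Write -> read -> write is byte identical.
#'
#' @param annotations an [annotation_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  pmids <- sort_c(names(annotations$labels))
  out <- vapply(pmids, function(p) {
    paste0(p, "\t", paste(annotations$labels[[p]], collapse = ";"))
  }, "")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Deterministic cross-validation folds
#'
#' Seeded uniform shuffle followed by round-robin assignment, so fold sizes
#' differ by at most one and the same `(pmids, k, seed)` always reproduces
#' the identical assignment.
#'
#' @param pmids character vector of document identifiers.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return Object of class `fold_assignment`: list with `k`, `seed` and
#'   `assignment`, a named integer vector mapping pmid to fold index in
#'   `[0, k)`.
#' @export
split_folds <- function(pmids, k, seed = 1L) {
  pmids <- as.character(pmids)
  check(k >= 2L, "k must be >= 2")
  check(length(pmids) >= k, "more folds (%d) than documents (%d)", k,
        length(pmids))
  check(!anyDuplicated(pmids), "duplicate pmids in fold split")
  shuffled <- with_seed(seed, sample(pmids))
  assignment <- stats::setNames((seq_along(shuffled) - 1L) %% as.integer(k),
                                shuffled)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignment = assignment[pmids]),
            class = "fold_assignment")
}

#' Write a corpus bundle
#'
#' A bundle directory holds `records.medline` (canonical MEDLINE),
#' `annotations.tsv` (canonical TSV) and `manifest.json` (record and
#' annotation counts). The canonical serialization is byte-stable under
#' write -> read -> write.
#'
#' @param records list of [document_record()]s.
#' @param annotations an [annotation_set()].
#' @param dir bundle directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_corpus_bundle <- function(records, annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_medline(records, file.path(dir, "records.medline"))
  write_annotations(annotations, file.path(dir, "annotations.tsv"))
  nlab <- vapply(annotations$labels, length, 0L)
  write_canonical_json(list(
    format = "expotax-corpus-bundle",
    version = 1L,
    n_records = length(records),
    n_reviewed = length(annotations$labels),
    n_annotated = sum(nlab > 0L),
    n_irrelevant = sum(nlab == 0L),
    annotator = annotations$annotator
  ), file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a corpus bundle
#'
#' @param dir bundle directory written by [write_corpus_bundle()].
#' @param taxonomy an `exposure_taxonomy` used to validate annotation labels.
#' @return List with `records`, `annotations` and `manifest`.
#' @export
read_corpus_bundle <- function(dir, taxonomy) {
  check(dir.exists(dir), "corpus bundle directory not found: %s", dir)
  manifest <- read_json_file(file.path(dir, "manifest.json"))
  annotator <- manifest$annotator %||% "annotator"
  list(records = read_medline(file.path(dir, "records.medline")),
       annotations = read_annotations(file.path(dir, "annotations.tsv"),
                                      taxonomy, annotator = annotator),
       manifest = manifest)
}

#' Best-effort importer for a released corpus directory
#'
#' Scans a directory for record files (PubMed XML `*.xml`, MEDLINE
#' `*.medline`/`*.txt`) and annotation files (`*.tsv`, `*.json`) and
#' assembles a corpus. This is a convenience entry point for externally
#' distributed corpus archives whose exact layout varies; the canonical,
#' fully specified format remains the corpus bundle of
#' [write_corpus_bundle()].
#'
#' @param dir directory to scan.
#' @param taxonomy an `exposure_taxonomy` used to validate labels.
#' @return List with `records` and `annotations` (may have `NULL`
#'   annotations when no annotation file is found).
#' @export
read_corpus_dir <- function(dir, taxonomy) {
  check(dir.exists(dir), "corpus directory not found: %s", dir)
  files <- list.files(dir, full.names = TRUE)
  records <- list()
  for (f in files[grepl("\\.xml$", files, ignore.case = TRUE)]) {
    records <- c(records, read_pubmed_xml(f))
  }
  for (f in files[grepl("\\.(medline|txt)$", files, ignore.case = TRUE)]) {
    recs <- tryCatch(read_medline(f), error = function(e) {
      warning("skipping unparseable record file ", f, ": ",
              conditionMessage(e), call. = FALSE)
      list()
    })
    records <- c(records, recs)
  }
  check(length(records) > 0L, "no record files found under %s", dir)
  records <- .dedupe_records(records)
  ann_files <- files[grepl("\\.(tsv|json)$", files, ignore.case = TRUE)]
  ann_files <- ann_files[!grepl("manifest\\.json$", ann_files)]
  annotations <- NULL
  if (length(ann_files)) {
    annotations <- read_annotations(ann_files[[1L]], taxonomy)
    if (length(ann_files) > 1L) {
      warning("multiple annotation files found; using ", ann_files[[1L]],
              call. = FALSE)
    }
  }
  list(records = records, annotations = annotations)
}
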