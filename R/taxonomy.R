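# Exposure-information taxonomy: a forest of two trees (BIOMONITORING and
# EXPOSURE ROUTES) whose nodes are the classification targets. Nodes are
# addressed by canonical slugs; display names are kept for reporting.

.builtin_taxonomy_table <- function() {
  # display name, parent display name (NA = branch root); order is the
  # canonical depth-first traversal used in all reports
  def <- matrix(c(
    "BIOMONITORING",           NA,
    "Exposure biomarker",      "BIOMONITORING",
    "Adipose tissue",          "Exposure biomarker",
    "Blood",                   "Exposure biomarker",
    "Hair/nail",               "Exposure biomarker",
    "Mother's milk",           "Exposure biomarker",
    "Other tissue",            "Exposure biomarker",
    "Placenta",                "Exposure biomarker",
    "Urine",                   "Exposure biomarker",
    "Effect biomarker",        "BIOMONITORING",
    "Biomarker",               "Effect biomarker",
    "Gene",                    "Biomarker",
    "Molecule",                "Biomarker",
    "Lipid",                   "Molecule",
    "Other molecule",          "Molecule",
    "Protein",                 "Molecule",
    "Other effect biomarker",  "Biomarker",
    "Oxidative stress marker", "Biomarker",
    "Physiological parameter", "Effect biomarker",
    "EXPOSURE ROUTES",         NA,
    "Combined",                "EXPOSURE ROUTES",
    "Dermal exposure",         "EXPOSURE ROUTES",
    "Inhalation",              "EXPOSURE ROUTES",
    "Outdoor air",             "Inhalation",
    "Indoor air",              "Inhalation",
    "Personal air",            "Inhalation",
    "Oral intake",             "EXPOSURE ROUTES",
    "Drinking water",          "Oral intake",
    "Dust",                    "Oral intake",
    "Food",                    "Oral intake",
    "Products",                "Oral intake",
    "Soil",                    "Oral intake"
  ), ncol = 2L, byrow = TRUE)
  data.frame(display = def[, 1L], parent_display = def[, 2L],
             stringsAsFactors = FALSE)
}

#' The built-in exposure taxonomy
#'
#' Returns the default 32-node taxonomy of human chemical-exposure
#' information: two branches, *biomonitoring* (exposure biomarkers by
#' biological matrix; effect biomarkers by marker character) and *exposure
#' routes* (oral intake, inhalation, dermal and combined exposure, with
#' source-specific sub-nodes).
#'
#' @return An object of class `exposure_taxonomy`.
#' @seealso [load_taxonomy()] for user-defined taxonomies.
#' @examples
#' tax <- exposure_taxonomy()
#' tax
#' taxonomy_ancestors(tax, "food")
#' @export
exposure_taxonomy <- function() {
  tab <- .builtin_taxonomy_table()
  load_taxonomy(data.frame(name = tab$display, parent = tab$parent_display,
                           stringsAsFactors = FALSE))
}

#' Load and validate a taxonomy
#'
#' Builds an `exposure_taxonomy` from a node/parent description. Accepted
#' sources: a data frame with columns `name` and `parent` (`NA` or `""`
#' parent marks a branch root), the path of a JSON or YAML file holding a
#' list of `{name, parent}` records, or the marker string `"builtin"`.
#' Node names may be given as display names or slugs; all lookups elsewhere
#' in the package accept either.
#'
#' @param source data frame, file path, or `"builtin"`.
#' @return An `exposure_taxonomy`: list with elements `nodes` (data frame of
#'   `name` (slug), `display`, `parent` (slug or `NA`)), `children` (named
#'   list of child slugs in declaration order), and `roots`.
#' @export
load_taxonomy <- function(source = "builtin") {
  if (is.character(source) && length(source) == 1L) {
    if (identical(source, "builtin")) return(exposure_taxonomy())
    check(file.exists(source), "taxonomy file not found: %s", source)
    recs <- if (grepl("\\.ya?ml$", source, ignore.case = TRUE)) {
      yaml::read_yaml(source)
    } else {
      read_json_file(source)
    }
    source <- data.frame(
      name = vapply(recs, function(r) as.character(r$name), ""),
      parent = vapply(recs, function(r) {
        p <- r$parent
        if (is.null(p) || is.na(p) || !nzchar(p)) NA_character_ else as.character(p)
      }, ""),
      stringsAsFactors = FALSE)
  }
  check(is.data.frame(source) && all(c("name", "parent") %in% names(source)),
        "taxonomy source must be a data frame with columns 'name' and 'parent'")
  display <- as.character(source$name)
  parent_raw <- as.character(source$parent)
  parent_raw[!is.na(parent_raw) & !nzchar(parent_raw)] <- NA_character_
  name <- slugify(display)
  dup <- name[duplicated(name)]
  check(length(dup) == 0L, "duplicate taxonomy node name: %s", paste(dup, collapse = ", "))
  parent <- ifelse(is.na(parent_raw), NA_character_, slugify(parent_raw))
  missing <- setdiff(parent[!is.na(parent)], name)
  check(length(missing) == 0L, "parent of a taxonomy node does not exist: %s",
        paste(missing, collapse = ", "))
  nodes <- data.frame(name = name, display = display, parent = parent,
                      stringsAsFactors = FALSE)
  # cycle check: walk parents from each node, at most n steps
  pmap <- stats::setNames(nodes$parent, nodes$name)
  for (nd in nodes$name) {
    seen <- character(0)
    cur <- nd
    while (!is.na(pmap[[cur]])) {
      check(!(pmap[[cur]] %in% c(seen, nd)),
            "taxonomy cycle detected at node: %s", nd)
      seen <- c(seen, cur)
      cur <- pmap[[cur]]
    }
  }
  children <- lapply(stats::setNames(nodes$name, nodes$name), function(nd) {
    nodes$name[!is.na(nodes$parent) & nodes$parent == nd]
  })
  structure(list(nodes = nodes, children = children,
                 roots = nodes$name[is.na(nodes$parent)]),
            class = "exposure_taxonomy")
}

#' @export
print.exposure_taxonomy <- function(x, ...) {
  cat(sprintf("Exposure taxonomy: %d nodes, %d branch root(s) [%s]\n",
              nrow(x$nodes), length(x$roots),
              paste(x$nodes$display[match(x$roots, x$nodes$name)],
                    collapse = ", ")))
  depth <- vapply(x$nodes$name, function(nd) length(taxonomy_ancestors(x, nd)),
                  0L)
  for (i in .taxonomy_traversal_order(x)) {
    cat(strrep("  ", depth[i]), x$nodes$display[i], "\n", sep = "")
  }
  invisible(x)
}

# depth-first order following declaration order of roots/children
.taxonomy_traversal_order <- function(taxonomy) {
  idx <- stats::setNames(seq_len(nrow(taxonomy$nodes)), taxonomy$nodes$name)
  out <- integer(0)
  visit <- function(nd) {
    out <<- c(out, idx[[nd]])
    for (ch in taxonomy$children[[nd]]) visit(ch)
  }
  for (r in taxonomy$roots) visit(r)
  out
}

#' Node names of a taxonomy
#'
#' @param taxonomy an `exposure_taxonomy`.
#' @param order `"declared"` (declaration order) or `"traversal"`
#'   (depth-first, the order used in reports).
#' @return Character vector of node slugs.
#' @export
taxonomy_nodes <- function(taxonomy, order = c("declared", "traversal")) {
  order <- match.arg(order)
  if (order == "declared") taxonomy$nodes$name
  else taxonomy$nodes$name[.taxonomy_traversal_order(taxonomy)]
}

# Resolve a user-supplied node reference (slug or display name) to a slug.
resolve_node <- function(taxonomy, node) {
  s <- slugify(as.character(node))
  bad <- setdiff(s, taxonomy$nodes$name)
  check(length(bad) == 0L, "unknown taxonomy node: %s",
        paste(unique(bad), collapse = ", "))
  s
}

#' Strict ancestors of a node
#'
#' @param taxonomy an `exposure_taxonomy`.
#' @param node node slug or display name.
#' @return Slugs ordered from parent up to the branch root; empty for roots.
#' @examples
#' taxonomy_ancestors(exposure_taxonomy(), "Blood")
#' @export
taxonomy_ancestors <- function(taxonomy, node) {
  node <- resolve_node(taxonomy, node)
  pmap <- stats::setNames(taxonomy$nodes$parent, taxonomy$nodes$name)
  out <- character(0)
  cur <- pmap[[node]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- pmap[[cur]]
  }
  out
}

#' Strict descendants of a node
#'
#' @inheritParams taxonomy_ancestors
#' @return Slugs of all nodes below `node`, depth-first.
#' @export
taxonomy_descendants <- function(taxonomy, node) {
  node <- resolve_node(taxonomy, node)
  out <- character(0)
  visit <- function(nd) {
    for (ch in taxonomy$children[[nd]]) {
      out <<- c(out, ch)
      visit(ch)
    }
  }
  visit(node)
  out
}

#' Hierarchical label closure
#'
#' Propagates a set of node labels upward: every label's ancestors are added,
#' so an abstract annotated at a sub-node counts as a positive example for
#' each parent node. The operation is idempotent and monotone.
#'
#' @param taxonomy an `exposure_taxonomy`.
#' @param labels character vector of node slugs or display names (may be
#'   empty).
#' @return Sorted character vector of slugs: the upward closure of `labels`.
#' @examples
#' propagate_labels(exposure_taxonomy(), "Food")
#' @export
propagate_labels <- function(taxonomy, labels) {
  if (length(labels) == 0L) return(character(0))
  labels <- resolve_node(taxonomy, labels)
  out <- unique(c(labels, unlist(lapply(labels, taxonomy_ancestors,
                                        taxonomy = taxonomy))))
  sort_c(out)
}

#' Export a taxonomy description
#'
#' Writes the `{name, parent}` record list consumed by [load_taxonomy()].
#'
#' @param taxonomy an `exposure_taxonomy`.
#' @param path output file; format chosen by extension (`.json`, `.yaml`/
#'   `.yml`).
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  recs <- lapply(seq_len(nrow(taxonomy$nodes)), function(i) {
    list(name = taxonomy$nodes$display[i],
         parent = if (is.na(taxonomy$nodes$parent[i])) NULL else
           taxonomy$nodes$display[match(taxonomy$nodes$parent[i],
                                        taxonomy$nodes$name)])
  })
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(recs, path)
  } else {
    write_canonical_json(recs, path)
  }
  invisible(path)
}
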