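# Chemical-specific publication profiles: per-taxonomy-node distributions
# of classified abstracts, used to overview published exposure information
# and spot data gaps when comparing chemicals.

#' Publication profile from a prediction set
#'
#' A document counts as relevant when it was predicted positive for at
#' least one taxonomy node; node percentages are taken against that
#' relevant total, so they need not sum to 100 (the labeling is
#' multi-label) and a document counts once per node it fires.
#'
#' @param pred a `prediction_set` over the chemical's documents.
#' @param taxonomy an `exposure_taxonomy`.
#' @param label chemical name the profile describes.
#' @return Object of class `publication_profile`: data frame `per_node`
#'   (`node`, `display`, `count`, `percent`) in taxonomy traversal order,
#'   `total_relevant`, `label`, and flag `undefined_percent` when no
#'   document was relevant (all percents reported as 0).
#' @export
publication_profile <- function(pred, taxonomy = exposure_taxonomy(),
                                label = "chemical") {
  nodes <- taxonomy_nodes(taxonomy, order = "traversal")
  total <- sum(lengths(pred) > 0L)
  count <- vapply(nodes, function(nd) {
    sum(vapply(pred, function(lb) nd %in% lb, TRUE))
  }, 0L)
  percent <- if (total > 0L) 100 * count / total else rep(0, length(nodes))
  per_node <- data.frame(
    node = nodes,
    display = taxonomy$nodes$display[match(nodes, taxonomy$nodes$name)],
    count = count, percent = percent, stringsAsFactors = FALSE)
  rownames(per_node) <- NULL
  structure(list(per_node = per_node, total_relevant = total, label = label,
                 undefined_percent = total == 0L, taxonomy = taxonomy),
            class = "publication_profile")
}

#' @export
print.publication_profile <- function(x, ...) {
  cat(sprintf("Publication profile for %s: %d relevant documents\n", x$label,
              x$total_relevant))
  if (x$undefined_percent) cat("  (no relevant documents; percents are 0 by convention)\n")
  m <- x$per_node[x$per_node$count > 0L, , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-28s %5d  %5.1f%%\n", m$display[i], m$count[i],
                m$percent[i]))
  }
  invisible(x)
}

#' @export
plot.publication_profile <- function(x, ...) {
  m <- x$per_node
  op <- graphics::par(mar = c(9, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(m$percent, names.arg = m$display, las = 2,
                    cex.names = 0.65, ylab = "% of relevant abstracts",
                    main = sprintf("%s (n = %d)", x$label, x$total_relevant),
                    ...)
  invisible(x)
}

#' Compare publication profiles across chemicals
#'
#' Stacks profiles over the same taxonomy into node x chemical matrices of
#' counts and percents, with a data-gap flag for node/chemical cells with
#' zero classified documents.
#'
#' @param profiles list of [publication_profile()]s (>= 2) over the same
#'   taxonomy.
#' @return Object of class `profile_matrix`: `counts`, `percents`, logical
#'   `gaps`, `totals` per chemical.
#' @export
compare_profiles <- function(profiles) {
  check(length(profiles) >= 2L, "need at least two profiles to compare")
  check(all(vapply(profiles, inherits, TRUE, "publication_profile")),
        "inputs must be publication_profiles")
  ref_nodes <- profiles[[1L]]$per_node$node
  for (p in profiles[-1L]) {
    check(identical(p$per_node$node, ref_nodes),
          "profiles computed over different taxonomies")
  }
  labels <- vapply(profiles, `[[`, "", "label")
  counts <- vapply(profiles, function(p) p$per_node$count,
                   integer(length(ref_nodes)))
  percents <- vapply(profiles, function(p) p$per_node$percent,
                     numeric(length(ref_nodes)))
  dimnames(counts) <- dimnames(percents) <- list(ref_nodes, labels)
  structure(list(counts = counts, percents = percents, gaps = counts == 0L,
                 totals = stats::setNames(
                   vapply(profiles, `[[`, 0L, "total_relevant"), labels),
                 display = profiles[[1L]]$per_node$display),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("Profile comparison: %d nodes x %d chemicals (totals: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", colnames(x$counts), x$totals),
                    collapse = ", ")))
  m <- round(x$percents, 1)
  rownames(m) <- x$display
  print(m)
  ngap <- sum(x$gaps)
  cat(sprintf("%d data-gap cells (zero classified documents)\n", ngap))
  invisible(x)
}

#' Export a profile comparison as TSV
#'
#' One row per node: counts and percents per chemical plus the gap flags.
#'
#' @param pm a `profile_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(pm, path) {
  labs <- colnames(pm$counts)
  hdr <- paste(c("node", paste0(labs, "_count"), paste0(labs, "_percent"),
                 paste0(labs, "_gap")), collapse = "\t")
  rows <- vapply(seq_len(nrow(pm$counts)), function(i) {
    paste(c(rownames(pm$counts)[i], pm$counts[i, ],
            sprintf("%.1f", pm$percents[i, ]),
            as.integer(pm$gaps[i, ])), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}
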