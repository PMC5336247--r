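# Shared fixtures and independent brute-force oracles. Oracles are kept
# deliberately naive (per-document loops, parent-walk fixpoints) so they
# stay independent of the implementation paths they check.

tiny_config <- function(...) {
  classifier_config(cost_grid = c(1, 10), gamma_grid = c(0.001, 0.01),
                    inner_k = 3, ...)
}

tiny_corpus <- function(seed = 11, leaves = c("blood", "urine", "food"),
                        docs_per_leaf = 20L, irrelevant_docs = 40L, ...) {
  generate_corpus(synthetic_corpus_spec(
    leaves = leaves, docs_per_leaf = docs_per_leaf,
    irrelevant_docs = irrelevant_docs, seed = seed, ...))
}

# random forest-shaped taxonomy description (for property tests)
random_taxonomy <- function(n_nodes, seed) {
  withr_seed <- function(expr) expr
  set.seed(seed)
  name <- sprintf("node%02d", seq_len(n_nodes))
  parent <- c(NA_character_, vapply(2:n_nodes, function(i) {
    if (stats::runif(1) < 0.15) NA_character_ else name[sample(i - 1L, 1L)]
  }, ""))
  load_taxonomy(data.frame(name = name, parent = parent,
                           stringsAsFactors = FALSE))
}

# oracle: ancestors by repeated parent lookup on the node table
oracle_ancestors <- function(taxonomy, node) {
  pmap <- stats::setNames(taxonomy$nodes$parent, taxonomy$nodes$name)
  out <- character(0)
  cur <- pmap[[node]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- pmap[[cur]]
  }
  out
}

# oracle: upward closure as a fixpoint of adding parents
oracle_closure <- function(taxonomy, labels) {
  pmap <- stats::setNames(taxonomy$nodes$parent, taxonomy$nodes$name)
  out <- labels
  repeat {
    parents <- stats::na.omit(unname(pmap[out]))
    new <- union(out, parents)
    if (setequal(new, out)) break
    out <- new
  }
  sort(out, method = "radix")
}

# oracle: per-document confusion counting
oracle_confusion <- function(pred, gold_closed, node) {
  tp <- fp <- fn <- tn <- 0L
  for (p in names(pred)) {
    inp <- node %in% pred[[p]]
    ing <- node %in% gold_closed[[p]]
    if (inp && ing) tp <- tp + 1L
    else if (inp) fp <- fp + 1L
    else if (ing) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# hand-written MEDLINE fixture: five records exercising every field
medline_fixture_lines <- function() {
  c("PMID- 1001",
    "TI  - Lead exposure in children",
    "AB  - Blood lead was measured. Levels rose.",
    "JT  - J Expo Sci",
    "DP  - 2004 Jan",
    "MH  - Humans",
    "MH  - Lead",
    "RN  - 7439-92-1 (Lead)",
    "",
    "PMID- 1002",
    "TI  - Cadmium in urine",
    "AB  - Urinary cadmium reflects exposure.",
    "JT  - Environ Res",
    "DP  - 2010",
    "MH  - Humans",
    "RN  - Cadmium",
    "",
    "PMID- 1003",
    "TI  - No abstract record",
    "JT  - Toxicology",
    "DP  - 1999",
    "MH  - Animals",
    "",
    "PMID- 1004",
    "TI  - Continuation line record",
    "AB  - First part of the abstract",
    "      continued on a second line.",
    "DP  - 2013",
    "",
    "PMID- 1005",
    "TI  - Minimal record",
    "AB  - Short.",
    "")
}

pubmed_xml_fixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0"?>',
    "<PubmedArticleSet>",
    "  <PubmedArticle><MedlineCitation>",
    "    <PMID>2001</PMID>",
    "    <Article>",
    "      <Journal><Title>J Expo Sci</Title>",
    "        <JournalIssue><PubDate><Year>2008</Year></PubDate></JournalIssue>",
    "      </Journal>",
    "      <ArticleTitle>Mercury in hair</ArticleTitle>",
    "      <Abstract><AbstractText>Hair mercury was measured.</AbstractText>",
    "      <AbstractText>Levels were high.</AbstractText></Abstract>",
    "    </Article>",
    "    <MeshHeadingList>",
    "      <MeshHeading><DescriptorName>Humans</DescriptorName></MeshHeading>",
    "      <MeshHeading><DescriptorName>Mercury</DescriptorName></MeshHeading>",
    "    </MeshHeadingList>",
    "    <ChemicalList>",
    "      <Chemical><NameOfSubstance>Mercury</NameOfSubstance></Chemical>",
    "    </ChemicalList>",
    "  </MedlineCitation></PubmedArticle>",
    "  <PubmedArticle><MedlineCitation>",
    "    <PMID>2002</PMID>",
    "    <Article>",
    "      <ArticleTitle>Record without abstract</ArticleTitle>",
    "    </Article>",
    "  </MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"), path)
  path
}

# quick annotated document from raw text + metadata
quick_doc <- function(text, pmid = "X1", mesh = character(0),
                      chem = character(0)) {
  annotate_document(document_record(pmid = pmid, title = "t", abstract = text,
                                    mesh_terms = mesh, chemicals = chem))
}
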