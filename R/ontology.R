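# Ontology parsing, representation and closure queries.
#
# The graph is stored child -> parent with typed edges (is_a / part_of).
# Obsolete terms stay in the term table, carry no edges, and are excluded
# from closure queries; version comparisons rely on them being retained.

#' Construct an OntologyGraph
#'
#' @param version single character version label.
#' @param terms data.frame with at least `term_id`; missing columns
#'   (`name`, `namespace`, `obsolete`, `replaced_by`, `alt_ids`) are
#'   filled with defaults.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @return a validated [OntologyGraph-class] object.
#' @export
OntologyGraph <- function(version, terms, edges = NULL) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  # [[ ]] on purpose: $ would partial-match "name" to "namespace"
  if (is.null(terms[["name"]])) terms$name <- NA_character_
  if (is.null(terms[["namespace"]])) terms$namespace <- "other"
  if (is.null(terms[["obsolete"]])) terms$obsolete <- FALSE
  if (is.null(terms[["replaced_by"]])) terms$replaced_by <- NA_character_
  if (is.null(terms[["alt_ids"]])) terms$alt_ids <- NA_character_
  terms <- terms[, c("term_id", "name", "namespace", "obsolete",
                     "replaced_by", "alt_ids")]
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges <- unique(edges[, c("child", "parent", "relation")])
  }
  rownames(terms) <- rownames(edges) <- NULL
  new("OntologyGraph", version = as.character(version), terms = terms,
      edges = edges)
}

#' Parse an OBO 1.2/1.4 document into an OntologyGraph
#'
#' Reads `[Term]` stanzas, keeping `is_a` and `relationship: part_of`
#' edges.  Obsolete terms are retained (flagged, `replaced_by` recorded)
#' but carry no edges.  Parent ids referenced by an edge but never defined
#' by a stanza are added as stub terms so the edge set stays closed.
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @param version version label for the graph; defaults to the header
#'   `data-version` if present, else `"unversioned"`.
#' @return an [OntologyGraph-class].
#' @export
parseOBO <- function(x, version = NULL) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE)
           else x
  lines <- sub("\\s+$", "", lines)
  if (is.null(version)) {
    dv <- grep("^data-version:", lines, value = TRUE)
    version <- if (length(dv)) sub("^data-version:\\s*", "", dv[1])
               else "unversioned"
  }
  stanza_at <- grep("^\\[", lines)
  terms <- list()
  edges <- list()
  for (i in seq_along(stanza_at)) {
    start <- stanza_at[i]
    if (lines[start] != "[Term]") next
    end <- if (i < length(stanza_at)) stanza_at[i + 1] - 1L
           else length(lines)
    body <- lines[(start + 1L):end]
    body_ln <- (start + 1L):end
    keep <- nzchar(body) & !grepl("^!", body)
    body <- body[keep]; body_ln <- body_ln[keep]
    bad <- !grepl("^[A-Za-z_]+:", body)
    if (any(bad))
      stop("malformed OBO stanza at line ", body_ln[which(bad)[1]], ": '",
           body[which(bad)[1]], "'")
    tag <- sub(":.*$", "", body)
    val <- sub("\\s*(!.*)?$", "", sub("^[A-Za-z_]+:\\s*", "", body))
    if (!any(tag == "id"))
      stop("malformed OBO stanza at line ", start, ": [Term] without id")
    id <- val[tag == "id"][1]
    obsolete <- any(tag == "is_obsolete" & val == "true")
    rel <- val[tag == "relationship"]
    rel_parts <- strsplit(rel, "\\s+")
    part_of <- vapply(rel_parts,
                      function(p) if (length(p) >= 2 && p[1] == "part_of")
                        p[2] else NA_character_, character(1))
    part_of <- part_of[!is.na(part_of)]
    terms[[id]] <- data.frame(
      term_id = id,
      name = if (any(tag == "name")) val[tag == "name"][1] else NA,
      namespace = if (any(tag == "namespace")) val[tag == "namespace"][1]
                  else "other",
      obsolete = obsolete,
      replaced_by = if (any(tag == "replaced_by"))
        val[tag == "replaced_by"][1] else NA,
      alt_ids = if (any(tag == "alt_id"))
        paste(val[tag == "alt_id"], collapse = ",") else NA,
      stringsAsFactors = FALSE)
    if (!obsolete) {
      isa <- val[tag == "is_a"]
      if (length(isa) || length(part_of))
        edges[[id]] <- data.frame(
          child = id,
          parent = c(isa, part_of),
          relation = rep(c("is_a", "part_of"),
                         c(length(isa), length(part_of))),
          stringsAsFactors = FALSE)
    }
  }
  terms <- do.call(rbind, terms)
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(child = character(), parent = character(),
                           relation = character())
  # stub terms for referenced-but-undefined parents
  miss <- setdiff(edges$parent, terms$term_id)
  if (length(miss))
    terms <- rbind(terms, data.frame(term_id = miss, name = NA,
                                     namespace = "other", obsolete = FALSE,
                                     replaced_by = NA, alt_ids = NA))
  # drop edges onto obsolete parents (the active graph excludes them)
  obs <- terms$term_id[terms$obsolete]
  edges <- edges[!(edges$parent %in% obs), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE)
  if (nrow(edges) && !igraph::is_dag(g))
    stop("ontology integrity error, cycle: ",
         paste(.find_cycle(edges), collapse = " -> "))
  OntologyGraph(version, terms, edges)
}

#' Serialize an OntologyGraph back to OBO text
#'
#' Writes the minimal tag subset `parseOBO()` reads, so a
#' parse-serialize-parse round trip preserves the term and edge multisets.
#'
#' @param graph an [OntologyGraph-class].
#' @param path optional output file; if `NULL` the lines are returned.
#' @export
writeOBO <- function(graph, path = NULL) {
  tr <- graph@terms
  ed <- graph@edges
  out <- c("format-version: 1.2",
           paste0("data-version: ", graph@version), "")
  for (i in seq_len(nrow(tr))) {
    out <- c(out, "[Term]", paste0("id: ", tr$term_id[i]))
    if (!is.na(tr$name[i])) out <- c(out, paste0("name: ", tr$name[i]))
    if (tr$namespace[i] != "other")
      out <- c(out, paste0("namespace: ", tr$namespace[i]))
    if (!is.na(tr$alt_ids[i]))
      out <- c(out, paste0("alt_id: ",
                           strsplit(tr$alt_ids[i], ",")[[1]]))
    if (tr$obsolete[i]) {
      out <- c(out, "is_obsolete: true")
      if (!is.na(tr$replaced_by[i]))
        out <- c(out, paste0("replaced_by: ", tr$replaced_by[i]))
    } else {
      e <- ed[ed$child == tr$term_id[i], , drop = FALSE]
      if (nrow(e)) {
        isa <- e$parent[e$relation == "is_a"]
        po <- e$parent[e$relation == "part_of"]
        if (length(isa)) out <- c(out, paste0("is_a: ", isa))
        if (length(po))
          out <- c(out, paste0("relationship: part_of ", po))
      }
    }
    out <- c(out, "")
  }
  if (is.null(path)) out else writeLines(out, path)
}

.check_term <- function(graph, term, allow_obsolete = FALSE) {
  i <- match(term, graph@terms$term_id)
  if (is.na(i)) stop("unknown term: ", term)
  if (!allow_obsolete && graph@terms$obsolete[i])
    stop("term ", term, " is obsolete in version ", graph@version,
         "; closure queries are defined on active terms only")
  invisible(i)
}

#' Descendant closure of a term
#'
#' All terms reachable against the child-to-parent edge direction from
#' `root` via the given relation types; `root` itself is excluded.
#'
#' @param graph an [OntologyGraph-class].
#' @param root a term id present and non-obsolete in `graph`.
#' @param relations edge types to traverse (default both).
#' @return character vector of descendant term ids.
#' @export
descendants <- function(graph, root, relations = c("is_a", "part_of")) {
  .check_term(graph, root)
  g <- ontoIgraph(graph, relations)
  out <- names(igraph::subcomponent(g, root, mode = "in"))
  setdiff(out, root)
}

# Ancestor closure (term excluded), same traversal semantics.
ancestors <- function(graph, term, relations = c("is_a", "part_of")) {
  .check_term(graph, term)
  g <- ontoIgraph(graph, relations)
  setdiff(names(igraph::subcomponent(g, term, mode = "out")), term)
}

#' Construct an AnnotationTable from direct gene-term pairs
#'
#' @param pairs data.frame with columns `gene_id`, `term_id` (direct
#'   annotations only).
#' @param graph optional companion [OntologyGraph-class]; annotated terms
#'   absent from it are reported with a warning (kept, flagged unknown).
#' @param graphVersion version label; defaults to `graph`'s.
#' @return an [AnnotationTable-class].
#' @export
AnnotationTable <- function(pairs, graph = NULL,
                            graphVersion = if (!is.null(graph))
                              graph@version else "unversioned") {
  pairs <- unique(as.data.frame(pairs, stringsAsFactors = FALSE))
  stopifnot(all(c("gene_id", "term_id") %in% names(pairs)))
  if (any(!nzchar(pairs$gene_id)) || anyNA(pairs$gene_id))
    stop("gene ids must be non-empty strings")
  if (!is.null(graph)) {
    unk <- setdiff(unique(pairs$term_id), graph@terms$term_id)
    if (length(unk))
      warning(length(unk), " annotated term(s) unknown to graph version ",
              graph@version, ": ",
              paste(head(unk, 5), collapse = ", "))
  }
  entries <- lapply(split(pairs$term_id, pairs$gene_id), unique)
  new("AnnotationTable", entries = entries,
      graphVersion = as.character(graphVersion))
}

#' Read direct annotations from a two-column TSV (gene_id, term_id)
#'
#' @inheritParams AnnotationTable
#' @param path TSV file with columns `gene_id` and `term_id` (header
#'   optional; detected from the first line).
#' @export
readAnnotationsTSV <- function(path, graph = NULL, ...) {
  first <- readLines(path, n = 1)
  header <- grepl("gene_id", first)
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!header) names(df)[1:2] <- c("gene_id", "term_id")
  AnnotationTable(df[, c("gene_id", "term_id")], graph = graph, ...)
}

#' Read annotations from a GAF-style file (columns 2 and 5)
#'
#' Lines starting with `!` are skipped; column 2 is the gene/product id,
#' column 5 the term accession, as in GO annotation files.
#'
#' @inheritParams readAnnotationsTSV
#' @export
readGAF <- function(path, graph = NULL, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 5
  if (!all(ok)) warning(sum(!ok), " GAF line(s) with <5 columns skipped")
  parts <- parts[ok]
  df <- data.frame(gene_id = vapply(parts, `[`, "", 2),
                   term_id = vapply(parts, `[`, "", 5),
                   stringsAsFactors = FALSE)
  AnnotationTable(df, graph = graph, ...)
}

#' Genes annotated to a term or any of its descendants
#'
#' Applies the true-path rule at query time: a gene directly annotated to
#' any descendant of `term` is annotated to `term`.
#'
#' @param graph an [OntologyGraph-class].
#' @param annotations an [AnnotationTable-class] of direct annotations.
#' @param term a term id present in `graph`.
#' @param relations edge types used for the descendant closure.
#' @return character vector of gene ids.
#' @export
annotatedGenes <- function(graph, annotations, term,
                           relations = c("is_a", "part_of")) {
  .check_term(graph, term, allow_obsolete = TRUE)
  fam <- c(term, descendants(graph, term, relations))
  hits <- vapply(annotations@entries,
                 function(ts) any(ts %in% fam), logical(1))
  names(annotations@entries)[hits]
}

# Map each term of the graph to its direct gene set (reverse index);
# internal, used by enrichment and drift counting.
termGeneIndex <- function(annotations) {
  e <- annotations@entries
  if (!length(e)) return(list())
  df <- data.frame(gene = rep(names(e), lengths(e)),
                   term = unlist(e, use.names = FALSE))
  lapply(split(df$gene, df$term), unique)
}

#' Subgraph induced by seed terms and their first neighbours
#'
#' Nodes are the seeds plus their direct parents and children in the
#' active graph; edges are all typed edges between retained nodes.
#' Unknown seeds are reported with a warning, not an error.
#'
#' @param graph an [OntologyGraph-class].
#' @param seeds character vector of term ids.
#' @return an [OntologyGraph-class] restricted to the neighbourhood.
#' @export
firstNeighborSubgraph <- function(graph, seeds) {
  seeds <- unique(seeds)
  unk <- setdiff(seeds, graph@terms$term_id)
  if (length(unk))
    warning(length(unk), " seed term(s) not in graph version ",
            graph@version, ": ", paste(head(unk, 5), collapse = ", "))
  seeds <- setdiff(seeds, unk)
  if (!length(seeds)) {
    warning("empty seed set; returning empty subgraph")
    return(OntologyGraph(graph@version,
                         graph@terms[0, , drop = FALSE]))
  }
  ed <- graph@edges
  nb <- c(ed$parent[ed$child %in% seeds], ed$child[ed$parent %in% seeds])
  nodes <- unique(c(seeds, nb))
  keep_e <- ed$child %in% nodes & ed$parent %in% nodes
  OntologyGraph(graph@version,
                graph@terms[graph@terms$term_id %in% nodes, , drop = FALSE],
                ed[keep_e, , drop = FALSE])
}

#' Write a graph as a node/edge TSV pair
#'
#' @param graph an [OntologyGraph-class].
#' @param node_path,edge_path output TSV paths.
#' @export
writeGraphTSV <- function(graph, node_path, edge_path) {
  write.table(graph@terms, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(graph@edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Read a graph from a node/edge TSV pair written by [writeGraphTSV()]
#'
#' @param version version label for the graph.
#' @param node_path,edge_path input TSV paths.
#' @export
readGraphTSV <- function(version, node_path, edge_path) {
  terms <- read.delim(node_path, stringsAsFactors = FALSE)
  edges <- read.delim(edge_path, stringsAsFactors = FALSE)
  OntologyGraph(version, terms, edges)
}
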