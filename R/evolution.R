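# Ontology version comparison: node classification over the selected
# terms + first-neighbour subgraphs, typed edge diff, annotation drift.

# alt_id -> primary id map for one graph version
.alt_map <- function(graph) {
  tr <- graph@terms
  has <- !is.na(tr$alt_ids)
  if (!any(has)) return(character())
  alts <- strsplit(tr$alt_ids[has], ",", fixed = TRUE)
  setNames(rep(tr$term_id[has], lengths(alts)),
           unlist(alts, use.names = FALSE))
}

# resolve possibly-merged ids against a graph; unresolved are reported
.resolve_ids <- function(ids, graph, label) {
  am <- .alt_map(graph)
  merged <- ids %in% names(am)
  ids[merged] <- am[ids[merged]]
  unresolved <- setdiff(ids, graph@terms$term_id)
  if (length(unresolved))
    message(length(unresolved), " selected id(s) unresolvable in ",
            label, ": ", paste(head(unresolved, 5), collapse = ", "))
  unique(ids)
}

#' Classify terms across two ontology versions
#'
#' Builds the selected-terms-plus-first-neighbours subgraph in each
#' version and classifies every node of the union into one of six
#' categories: selected in both and present in both
#' (`shared_selected_both`), present in both but selected by only one
#' side (`shared_selected_only_old` / `shared_selected_only_new`),
#' selected by the old side but obsolete or gone in the new version
#' (`obsoleted_in_new`), selected by the new side but unavailable in the
#' old version (`created_after_old`), and unselected neighbours
#' (`neighbor_unselected`).  Typed edges are diffed between the two
#' subgraphs.
#'
#' Merged ids (alt_id) resolve to their primary id before
#' classification; unresolvable ids are reported.
#'
#' @param graph_old,graph_new the two [OntologyGraph-class] versions
#'   (distinct version labels).
#' @param selected_old,selected_new the term selections made against each
#'   version.
#' @return a [VersionDiff-class].
#' @export
diffVersions <- function(graph_old, graph_new, selected_old,
                         selected_new) {
  if (identical(graph_old@version, graph_new@version))
    stop("the two graphs carry the same version label ('",
         graph_old@version, "'); label versions distinctly")
  sel_old <- .resolve_ids(unique(selected_old), graph_old, "old version")
  sel_new <- .resolve_ids(unique(selected_new), graph_new, "new version")
  sub_old <- suppressWarnings(
    firstNeighborSubgraph(graph_old, intersect(sel_old,
                                               graph_old@terms$term_id)))
  sub_new <- suppressWarnings(
    firstNeighborSubgraph(graph_new, intersect(sel_new,
                                               graph_new@terms$term_id)))
  nodes <- unique(c(sub_old@terms$term_id, sub_new@terms$term_id,
                    sel_old, sel_new))
  active_old <- graph_old@terms$term_id[!graph_old@terms$obsolete]
  active_new <- graph_new@terms$term_id[!graph_new@terms$obsolete]
  classify <- function(t) {
    so <- t %in% sel_old; sn <- t %in% sel_new
    ao <- t %in% active_old; an <- t %in% active_new
    if (so && !an) "obsoleted_in_new"
    else if (sn && !ao) "created_after_old"
    else if (so && sn) "shared_selected_both"
    else if (so) "shared_selected_only_old"
    else if (sn) "shared_selected_only_new"
    else "neighbor_unselected"
  }
  cats <- vapply(nodes, classify, "")
  ekey <- function(g) paste(g@edges$child, g@edges$parent,
                            g@edges$relation, sep = "\r")
  ko <- ekey(sub_old); kn <- ekey(sub_new)
  new("VersionDiff",
      nodes = data.frame(term_id = nodes, category = unname(cats),
                         stringsAsFactors = FALSE),
      edgesAdded = sub_new@edges[!(kn %in% ko), , drop = FALSE],
      edgesRemoved = sub_old@edges[!(ko %in% kn), , drop = FALSE],
      oldVersion = graph_old@version, newVersion = graph_new@version)
}

#' Annotation-count drift of terms between two versions
#'
#' Counts genes annotated to each term (descendant closure applied
#' within each version) in both versions; a term missing or obsolete in
#' a version gets `NA`, not zero.
#'
#' @param graph_old,graph_new the two [OntologyGraph-class] versions.
#' @param annotations_old,annotations_new direct-annotation tables built
#'   against the matching versions.
#' @param terms term ids to report.
#' @param relations closure relations.
#' @return data.frame (term_id, count_old, count_new, delta).
#' @export
annotationCountDrift <- function(graph_old, annotations_old, graph_new,
                                 annotations_new, terms,
                                 relations = c("is_a", "part_of")) {
  count_in <- function(graph, ann, t) {
    active <- graph@terms$term_id[!graph@terms$obsolete]
    if (!(t %in% active)) return(NA_integer_)
    length(annotatedGenes(graph, ann, t, relations))
  }
  old_n <- vapply(terms, count_in, integer(1), graph = graph_old,
                  ann = annotations_old)
  new_n <- vapply(terms, count_in, integer(1), graph = graph_new,
                  ann = annotations_new)
  data.frame(term_id = terms, count_old = old_n, count_new = new_n,
             delta = new_n - old_n, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a version diff as node-classification and edge-diff TSVs
#'
#' @param diff a [VersionDiff-class].
#' @param node_path,edge_path output TSV paths.
#' @export
writeDiffTSV <- function(diff, node_path, edge_path) {
  write.table(diff@nodes, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ea <- diff@edgesAdded; er <- diff@edgesRemoved
  ed <- rbind(if (nrow(ea)) cbind(ea, change = "added"),
              if (nrow(er)) cbind(er, change = "removed"))
  if (is.null(ed))
    ed <- data.frame(child = character(), parent = character(),
                     relation = character(), change = character())
  write.table(ed, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(node_path, edge_path))
}
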