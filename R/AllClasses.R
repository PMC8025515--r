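#' @import methods
#' @importFrom stats as.dist cor cutree dist hclust p.adjust phyper rnorm
#'   rpois runif setNames lm coef
#' @importFrom utils read.delim write.table head packageVersion
NULL

#' Versioned ontology graph
#'
#' A directed acyclic graph of ontology terms connected by typed edges
#' (`is_a`, `part_of`), plus obsolete terms retained without edges so that
#' version comparisons can account for them.  Edges point child -> parent.
#'
#' @slot version single character version label (date or tag).
#' @slot terms data.frame with columns `term_id`, `name`, `namespace`
#'   (one of biological_process, molecular_function, cellular_component,
#'   other), `obsolete` (logical), `replaced_by` (accession or NA),
#'   `alt_ids` (comma-separated merged accessions or NA).
#' @slot edges data.frame with columns `child`, `parent`, `relation`.
#'
#' @export
setClass("OntologyGraph",
  representation(version = "character", terms = "data.frame",
                 edges = "data.frame"))

setValidity("OntologyGraph", function(object) {
  msg <- character()
  tr <- object@terms
  ed <- object@edges
  need <- c("term_id", "name", "namespace", "obsolete", "replaced_by",
            "alt_ids")
  if (!all(need %in% names(tr)))
    msg <- c(msg, paste("terms must have columns:",
                        paste(need, collapse = ", ")))
  else if (anyDuplicated(tr$term_id))
    msg <- c(msg, "duplicated term_id in terms table")
  if (!all(c("child", "parent", "relation") %in% names(ed))) {
    msg <- c(msg, "edges must have columns child, parent, relation")
  } else if (nrow(ed) > 0) {
    if (!all(ed$relation %in% c("is_a", "part_of")))
      msg <- c(msg, "edge relations must be is_a or part_of")
    if (any(ed$child == ed$parent))
      msg <- c(msg, "self-edges are not allowed")
    known <- c(ed$child, ed$parent) %in% tr$term_id
    if (!all(known))
      msg <- c(msg, "every edge endpoint must exist in the terms table")
    obs <- tr$term_id[tr$obsolete]
    if (any(ed$child %in% obs | ed$parent %in% obs))
      msg <- c(msg, "obsolete terms must not carry edges")
    if (all(known)) {
      g <- igraph::graph_from_data_frame(ed[, c("child", "parent")],
                                         directed = TRUE)
      if (!igraph::is_dag(g)) {
        cyc <- .find_cycle(ed)
        msg <- c(msg, paste0("graph contains a cycle: ",
                             paste(cyc, collapse = " -> ")))
      }
    }
  }
  if (length(object@version) != 1L || is.na(object@version))
    msg <- c(msg, "version must be a single non-NA string")
  if (length(msg)) msg else TRUE
})

#' Direct gene-to-term annotation table
#'
#' Stores only direct annotations; true-path propagation to ancestors is
#' applied at query time (see [annotatedGenes()]).
#'
#' @slot entries named list, gene_id -> character vector of term ids.
#' @slot graphVersion version label of the companion [OntologyGraph].
#'
#' @export
setClass("AnnotationTable",
  representation(entries = "list", graphVersion = "character"))

setValidity("AnnotationTable", function(object) {
  msg <- character()
  e <- object@entries
  if (length(e)) {
    if (is.null(names(e)) || any(!nzchar(names(e))) || anyNA(names(e)))
      msg <- c(msg, "entries must be named by non-empty gene ids")
    if (!all(vapply(e, is.character, logical(1))))
      msg <- c(msg, "entries must be character vectors of term ids")
  }
  if (length(object@graphVersion) != 1L)
    msg <- c(msg, "graphVersion must be a single string")
  if (length(msg)) msg else TRUE
})

#' A hallmark mapping scheme
#'
#' Either an ontology-based scheme (per-hallmark term selections) or a
#' pathway-based scheme (a flat gene list, optionally split by pathway),
#' mirroring the two kinds of published mapping.
#'
#' @slot schemeId single character identifier, e.g. `"GO1"`.
#' @slot sourceKind `"ontology_terms"` or `"pathway_genes"`.
#' @slot selections named list hallmark -> character vector of term ids
#'   (ontology kind only; empty otherwise).
#' @slot genes character vector of gene ids (pathway kind only).
#' @slot pathways named list pathway -> gene vector (pathway kind,
#'   optional).
#'
#' @export
setClass("MappingScheme",
  representation(schemeId = "character", sourceKind = "character",
                 selections = "list", genes = "character",
                 pathways = "list"))

setValidity("MappingScheme", function(object) {
  msg <- character()
  if (length(object@schemeId) != 1L || !nzchar(object@schemeId))
    msg <- c(msg, "schemeId must be a single non-empty string")
  if (!object@sourceKind %in% c("ontology_terms", "pathway_genes"))
    msg <- c(msg, "sourceKind must be ontology_terms or pathway_genes")
  if (object@sourceKind == "ontology_terms") {
    sel <- object@selections
    if (length(sel)) {
      bad <- setdiff(names(sel), cancerHallmarks())
      if (length(bad))
        msg <- c(msg, paste("non-canonical hallmark name(s):",
                            paste(bad, collapse = ", ")))
      if (any(lengths(sel) == 0))
        msg <- c(msg, "selections must be non-empty per hallmark")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-hallmark and union gene sets for one scheme
#'
#' @slot schemeId scheme identifier.
#' @slot perHallmark named list hallmark -> character gene vector (empty
#'   for pathway schemes, which join comparisons at union level only).
#' @slot union character vector, union of all hallmark gene sets.
#' @slot skipped data.frame of selected terms that could not be used
#'   (columns `hallmark`, `term_id`, `reason`).
#'
#' @export
setClass("HallmarkGeneSets",
  representation(schemeId = "character", perHallmark = "list",
                 union = "character", skipped = "data.frame"))

setValidity("HallmarkGeneSets", function(object) {
  msg <- character()
  if (length(object@perHallmark)) {
    u <- unlist(object@perHallmark, use.names = FALSE)
    if (is.null(u)) u <- character()
    if (!setequal(unname(object@union), unname(u)))
      msg <- c(msg, "union must equal the union of per-hallmark sets")
  }
  if (length(msg)) msg else TRUE
})

#' Prognostic-hallmark subgroup partition for one scheme
#'
#' Each gene is assigned to the combination equal to the exact set of
#' cancer types where it is a prognostic-hallmark gene; combinations with
#' fewer than `minSize` genes are dropped (and recorded).
#'
#' @slot schemeId scheme identifier.
#' @slot groups named list, combination key -> character gene vector.
#' @slot combos named list, combination key -> character vector of cancer
#'   types (sorted).
#' @slot minSize minimum retained subgroup size.
#' @slot dropped data.frame of excluded combinations (`combo`, `n_genes`).
#'
#' @export
setClass("SubgroupTable",
  representation(schemeId = "character", groups = "list", combos = "list",
                 minSize = "numeric", dropped = "data.frame"))

setValidity("SubgroupTable", function(object) {
  msg <- character()
  g <- unlist(object@groups, use.names = FALSE)
  if (anyDuplicated(g))
    msg <- c(msg, "subgroup gene sets must be pairwise disjoint")
  if (length(object@groups) &&
      any(lengths(object@groups) < object@minSize))
    msg <- c(msg, "retained combination below minSize")
  if (!identical(sort(names(object@groups)), sort(names(object@combos))))
    msg <- c(msg, "groups and combos must share keys")
  if (length(msg)) msg else TRUE
})

#' Result container for the simplified co-expression analysis
#'
#' @slot power soft-thresholding power used for the adjacency.
#' @slot adjacency symmetric gene x gene matrix in `[0,1]`.
#' @slot tom topological overlap matrix, diagonal 1.
#' @slot moduleLabels named integer vector, gene -> module id (0 =
#'   unassigned); modules numbered by decreasing size.
#' @slot kWithin named numeric, intramodular connectivity per gene.
#' @slot hubs named list module -> ordered hub gene vector.
#' @slot enrichment data.frame of per-module enrichment records.
#'
#' @export
setClass("CoexpressionResult",
  representation(power = "numeric", adjacency = "matrix", tom = "matrix",
                 moduleLabels = "integer", kWithin = "numeric",
                 hubs = "list", enrichment = "data.frame"))

#' Classification of terms across two ontology versions
#'
#' Nodes of the union of the two selected+first-neighbour subgraphs,
#' classified into the six availability/selection categories, plus the
#' typed edge differences between the two subgraphs.
#'
#' @slot nodes data.frame with columns `term_id`, `category`.
#' @slot edgesAdded,edgesRemoved data.frames (`child`,`parent`,`relation`).
#' @slot oldVersion,newVersion the two version labels.
#'
#' @export
setClass("VersionDiff",
  representation(nodes = "data.frame", edgesAdded = "data.frame",
                 edgesRemoved = "data.frame", oldVersion = "character",
                 newVersion = "character"))

#' A fully synthetic study world with ground truth
#'
#' Bundles every input the pipeline consumes (ontology version pair,
#' annotations, mapping schemes, prognostic table, expression matrix)
#' together with the planted truth needed to score each stage.
#'
#' @slot seed integer seed the world was generated from.
#' @slot graphOld,graphNew the two [OntologyGraph] versions.
#' @slot annotations named list of [AnnotationTable], one per version.
#' @slot schemes list of [MappingScheme].
#' @slot prognostic named list cancer_type -> gene vector.
#' @slot expression list with elements `matrix` (genes x samples) and
#'   `labels` (named integer planted module labels).
#' @slot truth list of planted quantities (scheme pools, churn events,
#'   module memberships, enriched terms, prognostic combinations).
#'
#' @export
setClass("SyntheticWorld",
  representation(seed = "numeric", graphOld = "OntologyGraph",
                 graphNew = "OntologyGraph", annotations = "list",
                 schemes = "list", prognostic = "list",
                 expression = "list", truth = "list"))

setMethod("show", "OntologyGraph", function(object) {
  n_obs <- sum(object@terms$obsolete)
  cat("OntologyGraph [", object@version, "]: ",
      nrow(object@terms), " terms (", n_obs, " obsolete), ",
      nrow(object@edges), " edges (",
      sum(object@edges$relation == "is_a"), " is_a, ",
      sum(object@edges$relation == "part_of"), " part_of)\n", sep = "")
})

setMethod("show", "AnnotationTable", function(object) {
  cat("AnnotationTable [", object@graphVersion, "]: ",
      length(object@entries), " genes, ",
      length(unique(unlist(object@entries, use.names = FALSE))),
      " distinct terms\n", sep = "")
})

setMethod("show", "MappingScheme", function(object) {
  if (object@sourceKind == "ontology_terms") {
    cat("MappingScheme ", object@schemeId, " (ontology): ",
        length(unique(unlist(object@selections, use.names = FALSE))),
        " terms over ", length(object@selections), " hallmarks\n",
        sep = "")
  } else {
    cat("MappingScheme ", object@schemeId, " (pathway): ",
        length(object@genes), " genes\n", sep = "")
  }
})

setMethod("show", "HallmarkGeneSets", function(object) {
  cat("HallmarkGeneSets ", object@schemeId, ": union of ",
      length(object@union), " genes over ", length(object@perHallmark),
      " hallmarks", sep = "")
  if (nrow(object@skipped))
    cat(" (", nrow(object@skipped), " selected terms skipped)", sep = "")
  cat("\n")
})

setMethod("show", "SubgroupTable", function(object) {
  cat("SubgroupTable ", object@schemeId, ": ", length(object@groups),
      " combinations (min size ", object@minSize, ", ",
      nrow(object@dropped), " dropped)\n", sep = "")
})

setMethod("show", "CoexpressionResult", function(object) {
  k <- sum(unique(object@moduleLabels) != 0)
  cat("CoexpressionResult: ", nrow(object@adjacency), " genes, power ",
      object@power, ", ", k, " modules (",
      sum(object@moduleLabels == 0), " unassigned)\n", sep = "")
})

setMethod("show", "VersionDiff", function(object) {
  tab <- table(object@nodes$category)
  cat("VersionDiff ", object@oldVersion, " -> ", object@newVersion, ": ",
      nrow(object@nodes), " nodes; +", nrow(object@edgesAdded),
      "/-", nrow(object@edgesRemoved), " edges\n", sep = "")
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld (seed ", object@seed, "): ",
      nrow(object@graphOld@terms), "/", nrow(object@graphNew@terms),
      " terms (old/new), ", length(object@schemes), " schemes, ",
      length(object@prognostic), " cancer types, expression ",
      nrow(object@expression$matrix), " x ",
      ncol(object@expression$matrix), "\n", sep = "")
})

# --- plain accessors -------------------------------------------------------

#' @rdname OntologyGraph-class
#' @param x an `OntologyGraph`
#' @export
ontologyVersion <- function(x) x@version

#' @rdname OntologyGraph-class
#' @export
ontologyTerms <- function(x) x@terms

#' @rdname OntologyGraph-class
#' @export
ontologyEdges <- function(x) x@edges

#' @rdname AnnotationTable-class
#' @param x an `AnnotationTable`
#' @export
annotationEntries <- function(x) x@entries

#' @rdname MappingScheme-class
#' @param x a `MappingScheme`
#' @export
schemeId <- function(x) x@schemeId

#' @rdname MappingScheme-class
#' @export
schemeKind <- function(x) x@sourceKind

#' @rdname MappingScheme-class
#' @export
schemeSelections <- function(x) x@selections

#' @rdname MappingScheme-class
#' @export
schemeGenes <- function(x) x@genes

#' @rdname MappingScheme-class
#' @export
hallmarksCovered <- function(x) {
  if (x@sourceKind == "ontology_terms")
    names(x@selections)[lengths(x@selections) > 0]
  else character()
}

#' @rdname HallmarkGeneSets-class
#' @param x a `HallmarkGeneSets`
#' @export
perHallmarkGenes <- function(x) x@perHallmark

#' @rdname HallmarkGeneSets-class
#' @export
hallmarkUnion <- function(x) x@union

#' @rdname HallmarkGeneSets-class
#' @export
skippedTerms <- function(x) x@skipped

#' @rdname SubgroupTable-class
#' @param x a `SubgroupTable`
#' @export
subgroupGenes <- function(x) x@groups

#' @rdname SubgroupTable-class
#' @export
subgroupCombos <- function(x) x@combos

#' @rdname CoexpressionResult-class
#' @param x a `CoexpressionResult`
#' @export
moduleLabels <- function(x) x@moduleLabels

#' @rdname CoexpressionResult-class
#' @export
hubGeneList <- function(x) x@hubs

#' @rdname CoexpressionResult-class
#' @export
enrichmentTable <- function(x) x@enrichment

#' @rdname VersionDiff-class
#' @param x a `VersionDiff`
#' @export
diffNodes <- function(x) x@nodes

#' @rdname VersionDiff-class
#' @export
diffEdges <- function(x)
  list(added = x@edgesAdded, removed = x@edgesRemoved)

#' @rdname SyntheticWorld-class
#' @param x a `SyntheticWorld`
#' @export
worldTruth <- function(x) x@truth
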