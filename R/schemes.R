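# Mapping schemes: hallmark vocabulary, loading, hallmark gene sets.

.HALLMARKS <- c("sustaining proliferative signaling",
                "evading growth suppressor",
                "resisting cell death",
                "enabling replicative immortality",
                "inducing angiogenesis",
                "activating invasion and metastasis",
                "genome instability and mutation",
                "tumor promoting inflammation",
                "deregulating cellular energetic",
                "avoiding immune destruction")

# spelling variants observed across published schemes -> canonical form
.HALLMARK_ALIASES <- c(
  "evading growth suppressors"        = "evading growth suppressor",
  "genome instability"                = "genome instability and mutation",
  "genomic instability and mutation"  = "genome instability and mutation",
  "deregulating cellular energetics"  = "deregulating cellular energetic",
  "deregulated cellular energetics"   = "deregulating cellular energetic",
  "tumour promoting inflammation"     = "tumor promoting inflammation",
  "angiogenesis"                      = "inducing angiogenesis",
  "invasion and metastasis"           = "activating invasion and metastasis",
  "replicative immortality"           = "enabling replicative immortality",
  "enabling replicative signaling"    = "enabling replicative immortality")

#' The ten canonical cancer hallmarks
#'
#' @return character vector of the ten canonical hallmark names
#'   (lower case).
#' @export
cancerHallmarks <- function() .HALLMARKS

#' Resolve hallmark spelling variants to canonical names
#'
#' Normalises case, punctuation and common plural/synonym variants.
#'
#' @param x character vector of hallmark names as found in scheme tables.
#' @return character vector of canonical hallmark names.
#' @export
resolveHallmark <- function(x) {
  norm <- tolower(trimws(gsub("[-_]+", " ", x)))
  norm <- gsub("\\s+", " ", norm)
  out <- ifelse(norm %in% .HALLMARKS, norm,
                unname(.HALLMARK_ALIASES[norm]))
  # last resort: singularise the final word
  sing <- sub("s$", "", norm)
  out <- ifelse(is.na(out) & sing %in% .HALLMARKS, sing, out)
  bad <- which(is.na(out))
  if (length(bad))
    stop("unresolvable hallmark name(s): ",
         paste(sprintf("'%s' (row %d)", x[bad], bad), collapse = ", "))
  out
}

#' Load an ontology-based mapping scheme from (hallmark, term) rows
#'
#' @param table data.frame with columns `hallmark` and `term_id`, or a
#'   path to a TSV with those columns (a `scheme_id` column is ignored in
#'   favour of the `scheme_id` argument).
#' @param scheme_id identifier for the scheme (e.g. `"GO1"`).
#' @return a [MappingScheme-class] of kind `ontology_terms`.
#' @export
loadScheme <- function(table, scheme_id) {
  if (is.character(table) && length(table) == 1L)
    table <- read.delim(table, stringsAsFactors = FALSE)
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  stopifnot(all(c("hallmark", "term_id") %in% names(table)))
  table$hallmark <- resolveHallmark(table$hallmark)
  dup <- duplicated(table[, c("hallmark", "term_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicated (hallmark, term) row(s) deduplicated ",
            "in scheme ", scheme_id)
    table <- table[!dup, , drop = FALSE]
  }
  sel <- lapply(split(table$term_id, table$hallmark), unique)
  new("MappingScheme", schemeId = scheme_id,
      sourceKind = "ontology_terms", selections = sel,
      genes = character(), pathways = list())
}

#' Load a pathway-based scheme from a flat gene list
#'
#' Pathway schemes carry no hallmark-level term selections; they join the
#' comparisons only at the level of their gene-set union (the published
#' pathway scheme did not state which pathway maps to which hallmark).
#'
#' @param table data.frame with a `gene_id` column (an optional `pathway`
#'   column keeps per-pathway gene lists), or a TSV path.
#' @param scheme_id identifier, e.g. `"PW1"`.
#' @return a [MappingScheme-class] of kind `pathway_genes`.
#' @export
loadPathwayScheme <- function(table, scheme_id) {
  if (is.character(table) && length(table) == 1L)
    table <- read.delim(table, stringsAsFactors = FALSE)
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  stopifnot("gene_id" %in% names(table))
  if (nrow(table) == 0) stop("empty pathway gene list for ", scheme_id)
  pw <- if ("pathway" %in% names(table))
    lapply(split(table$gene_id, table$pathway), unique) else list()
  new("MappingScheme", schemeId = scheme_id,
      sourceKind = "pathway_genes", selections = list(),
      genes = unique(table$gene_id), pathways = pw)
}

#' Build hallmark gene sets for an ontology-based scheme
#'
#' For every hallmark, takes the union over its selected terms of the
#' genes annotated to the term or any descendant (true-path rule).
#' Selected terms that are obsolete or unknown in the graph version in
#' use are skipped and reported, never silently dropped.
#'
#' @param scheme a [MappingScheme-class] of kind `ontology_terms`.
#' @param graph an [OntologyGraph-class].
#' @param annotations an [AnnotationTable-class].
#' @param relations edge types used for descendant closure.
#' @return a [HallmarkGeneSets-class].
#' @export
buildHallmarkGeneSets <- function(scheme, graph, annotations,
                                  relations = c("is_a", "part_of")) {
  stopifnot(scheme@sourceKind == "ontology_terms")
  known <- graph@terms$term_id
  obsolete <- known[graph@terms$obsolete]
  skipped <- list()
  per <- lapply(names(scheme@selections), function(h) {
    terms <- scheme@selections[[h]]
    bad_u <- setdiff(terms, known)
    bad_o <- intersect(terms, obsolete)
    if (length(c(bad_u, bad_o)))
      skipped[[h]] <<- data.frame(
        hallmark = h, term_id = c(bad_u, bad_o),
        reason = rep(c("unknown", "obsolete"),
                     c(length(bad_u), length(bad_o))))
    ok <- setdiff(terms, c(bad_u, bad_o))
    sort(unique(unlist(lapply(ok, function(t)
      annotatedGenes(graph, annotations, t, relations)))))
  })
  names(per) <- names(scheme@selections)
  skipped <- if (length(skipped)) do.call(rbind, c(skipped,
                                                   make.row.names = FALSE))
             else data.frame(hallmark = character(), term_id = character(),
                             reason = character())
  u <- unlist(per, use.names = FALSE)
  new("HallmarkGeneSets", schemeId = scheme@schemeId, perHallmark = per,
      union = if (is.null(u)) character() else sort(unique(u)),
      skipped = skipped)
}

#' Gene sets for a pathway-based scheme (union only)
#'
#' @param scheme a [MappingScheme-class] of kind `pathway_genes`.
#' @return a [HallmarkGeneSets-class] with an empty per-hallmark list.
#' @export
pathwaySchemeGenes <- function(scheme) {
  stopifnot(scheme@sourceKind == "pathway_genes")
  if (!length(scheme@genes)) stop("pathway scheme has no genes")
  new("HallmarkGeneSets", schemeId = scheme@schemeId,
      perHallmark = list(), union = sort(unique(scheme@genes)),
      skipped = data.frame(hallmark = character(), term_id = character(),
                           reason = character()))
}
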