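# Term-selection statistics, consensus terms, exclusive intersections.

.onto_schemes <- function(schemes) {
  Filter(function(s) s@sourceKind == "ontology_terms", schemes)
}

#' Term selection frequency across schemes
#'
#' Counts, for every selected term, how many schemes selected it at all
#' (a term mapped by one scheme to two hallmarks counts once), and how
#' many schemes selected it for each individual hallmark.
#'
#' @param schemes list of ontology-kind [MappingScheme-class] objects
#'   (at least two).
#' @return list with `overall` (named integer vector term -> scheme
#'   count) and `perHallmark` (named list hallmark -> named integer
#'   vector).
#' @export
termSelectionFrequency <- function(schemes) {
  schemes <- .onto_schemes(schemes)
  if (length(schemes) < 2)
    stop("need at least 2 ontology-kind schemes")
  per_scheme_terms <- lapply(schemes, function(s)
    unique(unlist(s@selections, use.names = FALSE)))
  overall <- table(unlist(per_scheme_terms))
  overall <- setNames(as.integer(overall), names(overall))
  hallmarks <- unique(unlist(lapply(schemes, function(s)
    names(s@selections))))
  perH <- lapply(hallmarks, function(h) {
    t_h <- unlist(lapply(schemes, function(s)
      unique(s@selections[[h]])), use.names = FALSE)
    if (is.null(t_h) || !length(t_h)) return(integer())
    tab <- table(t_h)
    setNames(as.integer(tab), names(tab))
  })
  names(perH) <- hallmarks
  list(overall = overall, perHallmark = perH)
}

#' Percentage of a scheme's terms selected by no other scheme
#'
#' @param scheme the focal [MappingScheme-class].
#' @param schemes the full list of compared schemes (must contain
#'   `scheme`).
#' @return percentage in `[0, 100]`, half-up rounded to one decimal.
#' @export
uniqueTermFraction <- function(scheme, schemes) {
  schemes <- .onto_schemes(schemes)
  own <- unique(unlist(scheme@selections, use.names = FALSE))
  if (!length(own))
    stop("scheme ", scheme@schemeId, " selects no terms; ",
         "unique fraction undefined")
  others <- unique(unlist(lapply(
    Filter(function(s) s@schemeId != scheme@schemeId, schemes),
    function(s) unlist(s@selections, use.names = FALSE))))
  roundHalfUp(100 * length(setdiff(own, others)) / length(own), 1)
}

#' Convert a pathway scheme to term selections via a correspondence table
#'
#' Pathway databases publish mappings from pathways to ontology terms;
#' this ingests such a table (it is supplied, never re-derived) so a
#' pathway scheme can join per-hallmark consensus counting.
#'
#' @param scheme a pathway-kind [MappingScheme-class].
#' @param correspondence data.frame with columns `hallmark` and
#'   `term_id` (optionally `pathway`), or a TSV path.
#' @return an ontology-kind [MappingScheme-class] with the same id.
#' @export
convertPathwayScheme <- function(scheme, correspondence) {
  stopifnot(scheme@sourceKind == "pathway_genes")
  if (is.character(correspondence) && length(correspondence) == 1L)
    correspondence <- read.delim(correspondence, stringsAsFactors = FALSE)
  loadScheme(correspondence[, c("hallmark", "term_id")], scheme@schemeId)
}

#' Consensus terms across mapping schemes
#'
#' A term is a consensus term for a hallmark when at least `min_schemes`
#' schemes selected it for that hallmark (selection of the same term for
#' different hallmarks does not accumulate).  The overall consensus set
#' is the union of the per-hallmark sets; because a term can be consensus
#' in two hallmarks, both the unique-term count and the per-hallmark
#' total are reported.
#'
#' @param schemes list of ontology-kind [MappingScheme-class] objects
#'   (convert pathway schemes first, see [convertPathwayScheme()]).
#' @param min_schemes consensus threshold (default 3).
#' @return list with `perHallmark` (hallmark -> consensus term vector),
#'   `overall` (unique consensus terms), `nUnique` and
#'   `nPerHallmarkTotal`.
#' @export
consensusTerms <- function(schemes, min_schemes = 3) {
  schemes <- .onto_schemes(schemes)
  if (min_schemes > length(schemes))
    stop("min_schemes (", min_schemes, ") exceeds number of schemes (",
         length(schemes), ")")
  freq <- termSelectionFrequency(schemes)
  perH <- lapply(freq$perHallmark, function(counts)
    sort(names(counts)[counts >= min_schemes]))
  perH <- perH[order(names(perH))]
  overall <- sort(unique(unlist(perH, use.names = FALSE)))
  list(perHallmark = perH, overall = overall,
       nUnique = length(overall),
       nPerHallmarkTotal = sum(lengths(perH)))
}

#' Exclusive intersections of named sets (upset counts)
#'
#' Partitions the union of the input sets by exact membership signature:
#' each element is counted in the one combination equal to the sets that
#' contain it.  The exclusive counts therefore sum to the size of the
#' global union, which is asserted on every call.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return data.frame with columns `combo` (set names joined by `+`),
#'   `degree`, `n`, and a list-column `elements`; per-set totals are
#'   attached as `attr(, "set_totals")`.
#' @export
exclusiveIntersections <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)))
    stop("need >= 2 named sets")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL,
                                                               names(sets)))
  sig <- apply(member, 1, function(m)
    paste(names(sets)[m], collapse = "+"))
  split_el <- split(universe, sig)
  out <- data.frame(combo = names(split_el),
                    degree = vapply(strsplit(names(split_el), "+",
                                             fixed = TRUE),
                                    length, integer(1)),
                    n = lengths(split_el), stringsAsFactors = FALSE)
  out$elements <- unname(split_el)
  out <- out[order(-out$n, out$combo), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(sum(out$n) == length(universe))  # partition property
  attr(out, "set_totals") <- lengths(sets)
  out
}

#' Exclusive gene intersections for one hallmark across schemes
#'
#' Schemes without genes for the hallmark are omitted from the profile.
#'
#' @param gene_sets list of [HallmarkGeneSets-class], one per scheme.
#' @param hallmark canonical hallmark name.
#' @return as [exclusiveIntersections()].
#' @export
perHallmarkGeneComparison <- function(gene_sets, hallmark) {
  hallmark <- resolveHallmark(hallmark)
  sets <- lapply(gene_sets, function(gs) gs@perHallmark[[hallmark]])
  names(sets) <- vapply(gene_sets, function(gs) gs@schemeId, "")
  sets <- Filter(function(s) !is.null(s) && length(s) > 0, sets)
  if (length(sets) < 2)
    stop("fewer than 2 schemes cover hallmark '", hallmark, "'")
  exclusiveIntersections(sets)
}

#' Write upset counts as a TSV (combination, degree, count)
#'
#' @param profile result of [exclusiveIntersections()].
#' @param path output TSV path.
#' @export
writeIntersectionTSV <- function(profile, path) {
  write.table(profile[, c("combo", "degree", "n")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
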