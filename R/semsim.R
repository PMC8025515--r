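# Wang-method semantic similarity and best-match-average aggregation.
#
# The semantic contribution S of an ancestor t to an anchor term A is the
# best (max) product of edge-type weights along any child-to-parent path
# from A up to t; S(A) = 1.  Similarity of two terms is the sum of their
# S values over shared ancestors, normalised by the two total semantic
# values SV.

#' Default edge-type semantic contribution factors
#'
#' The conventional Wang-method weights: 0.8 for `is_a`, 0.6 for
#' `part_of`.
#'
#' @export
wangWeights <- function() c(is_a = 0.8, part_of = 0.6)

#' Semantic contribution values of a term's ancestor closure
#'
#' @param graph an [OntologyGraph-class].
#' @param term anchor term id (present, non-obsolete).
#' @param weights named numeric in `(0,1)`, one factor per traversed
#'   relation type.
#' @return list with `term`, `S` (named numeric over the anchor and its
#'   ancestors; `S[term] == 1`) and `SV = sum(S)`.
#' @export
sValues <- function(graph, term, weights = wangWeights()) {
  stopifnot(all(weights > 0), all(weights < 1))
  rels <- names(weights)
  anc <- ancestors(graph, term, relations = rels)
  keyed <- c(term, anc)
  ed <- graph@edges
  ed <- ed[ed$relation %in% rels & ed$child %in% keyed &
           ed$parent %in% keyed, , drop = FALSE]
  S <- setNames(rep(-Inf, length(keyed)), keyed)
  S[term] <- 1
  if (nrow(ed)) {
    g <- igraph::graph_from_data_frame(ed[, c("child", "parent")],
                                       directed = TRUE,
                                       vertices = data.frame(name = keyed))
    ord <- names(igraph::topo_sort(g, mode = "out"))
    for (t in ord) {
      if (t == term) next
      into <- ed[ed$parent == t, , drop = FALSE]
      S[t] <- max(weights[into$relation] * S[into$child])
    }
  }
  list(term = term, S = S, SV = sum(S))
}

#' Wang similarity of two terms
#'
#' Terms in disjoint rooted components (e.g. different namespaces) share
#' no ancestors and score 0.
#'
#' @inheritParams sValues
#' @param t1,t2 term ids.
#' @return score in `[0, 1]`; 1 iff the terms are identical (weights
#'   below 1).
#' @export
termSimilarity <- function(graph, t1, t2, weights = wangWeights()) {
  s1 <- sValues(graph, t1, weights)
  s2 <- sValues(graph, t2, weights)
  shared <- intersect(names(s1$S), names(s2$S))
  if (!length(shared)) return(0)
  sum(s1$S[shared] + s2$S[shared]) / (s1$SV + s2$SV)
}

.svalue_cache <- function(graph, terms, weights) {
  cache <- lapply(terms, sValues, graph = graph, weights = weights)
  names(cache) <- terms
  cache
}

.sim_from_cache <- function(s1, s2) {
  shared <- intersect(names(s1$S), names(s2$S))
  if (!length(shared)) return(0)
  sum(s1$S[shared] + s2$S[shared]) / (s1$SV + s2$SV)
}

#' Best-match-average similarity of two term sets
#'
#' Averages, over both directions, each term's best similarity against
#' the other set.  Terms unknown or obsolete in the graph version in use
#' are dropped with a warning before the comparison.
#'
#' @inheritParams sValues
#' @param set1,set2 character vectors of term ids.
#' @return score in `[0, 1]`.
#' @export
setSimilarityBMA <- function(graph, set1, set2, weights = wangWeights()) {
  valid <- graph@terms$term_id[!graph@terms$obsolete]
  drop <- setdiff(unique(c(set1, set2)), valid)
  if (length(drop))
    warning(length(drop), " term(s) unknown/obsolete in version ",
            graph@version, " dropped: ",
            paste(head(drop, 5), collapse = ", "))
  set1 <- unique(intersect(set1, valid))
  set2 <- unique(intersect(set2, valid))
  if (!length(set1) || !length(set2))
    stop("term set empty after dropping invalid terms")
  cache <- .svalue_cache(graph, unique(c(set1, set2)), weights)
  simmat <- matrix(0, length(set1), length(set2),
                   dimnames = list(set1, set2))
  for (a in set1) for (b in set2)
    simmat[a, b] <- .sim_from_cache(cache[[a]], cache[[b]])
  (sum(apply(simmat, 1, max)) + sum(apply(simmat, 2, max))) /
    (length(set1) + length(set2))
}

#' Pairwise BMA similarity between modules' enriched term sets
#'
#' Modules enriched in fewer than `min_terms` terms (default 3, i.e. the
#' rule that modules with only 1 or 2 enriched terms are not compared)
#' are excluded with a message.
#'
#' @inheritParams sValues
#' @param modules named list module_id -> enriched term id vector.
#' @param min_terms minimum enriched-term count for inclusion.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
moduleSimilarityMatrix <- function(modules, graph,
                                   weights = wangWeights(),
                                   min_terms = 3) {
  keep <- lengths(modules) >= min_terms
  if (any(!keep))
    message("excluded ", sum(!keep), " module(s) with < ", min_terms,
            " enriched terms: ",
            paste(names(modules)[!keep], collapse = ", "))
  modules <- modules[keep]
  if (!length(modules))
    stop("all modules excluded (fewer than ", min_terms,
         " enriched terms each)")
  n <- length(modules)
  out <- matrix(1, n, n, dimnames = list(names(modules), names(modules)))
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <-
        setSimilarityBMA(graph, modules[[i]], modules[[j]], weights)
    }
  out
}
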