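# Prognostic-hallmark genes, cancer-type subgroup partition, Jaccard.

#' Read a prognostic table from TSV (cancer_type, gene_id)
#'
#' @param path TSV with columns `cancer_type` and `gene_id`.
#' @return named list cancer_type -> character gene vector.
#' @export
readPrognosticTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cancer_type", "gene_id") %in% names(df)))
  lapply(split(df$gene_id, df$cancer_type), unique)
}

#' Prognostic-hallmark genes per cancer type
#'
#' Genes that are both prognostic for a cancer type and in the scheme's
#' hallmark gene union.
#'
#' @param hallmark_union character vector of a scheme's hallmark genes
#'   (or a [HallmarkGeneSets-class], whose union is taken).
#' @param prognostic named list cancer_type -> prognostic gene vector.
#' @return named list cancer_type -> intersected gene vector.
#' @export
prognosticHallmarkGenes <- function(hallmark_union, prognostic) {
  if (is(hallmark_union, "HallmarkGeneSets"))
    hallmark_union <- hallmark_union@union
  stopifnot(length(hallmark_union) > 0, length(prognostic) > 0)
  lapply(prognostic, function(g) sort(intersect(unique(g),
                                                hallmark_union)))
}

#' Partition genes into exact cancer-type-combination subgroups
#'
#' Each gene goes to the single combination equal to the exact set of
#' cancer types where it appears (a gene prognostic-hallmark in three
#' cancers belongs only to that three-cancer combination, not to any
#' sub-combination).  Combinations with fewer than `min_size` genes are
#' dropped and recorded.
#'
#' @param per_cancer named list cancer_type -> gene vector (as returned
#'   by [prognosticHallmarkGenes()]).
#' @param min_size minimum retained subgroup size (default 5).
#' @param scheme_id identifier recorded on the result.
#' @return a [SubgroupTable-class].
#' @export
subgroupPartition <- function(per_cancer, min_size = 5,
                              scheme_id = "scheme") {
  stopifnot(length(per_cancer) >= 1)
  genes <- unique(unlist(per_cancer, use.names = FALSE))
  if (length(genes)) {
    sig <- vapply(genes, function(g)
      comboKey(names(per_cancer)[vapply(per_cancer, function(s) g %in% s,
                                        logical(1))]), "")
    groups <- split(genes, sig)
  } else groups <- list()
  keep <- lengths(groups) >= min_size
  dropped <- data.frame(combo = names(groups)[!keep],
                        n_genes = unname(lengths(groups)[!keep]),
                        stringsAsFactors = FALSE)
  groups <- lapply(groups[keep], sort)
  combos <- lapply(names(groups), function(k)
    strsplit(k, "+", fixed = TRUE)[[1]])
  names(combos) <- names(groups)
  new("SubgroupTable", schemeId = scheme_id, groups = groups,
      combos = combos, minSize = min_size, dropped = dropped)
}

#' Jaccard index of two gene sets
#'
#' @param a,b character vectors; must not both be empty.
#' @return `|a . b| / |a u b|` in `[0, 1]`.
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b))
    stop("Jaccard index undefined for two empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise scheme similarity over subgroup partitions
#'
#' For every cancer-type combination retained by at least one scheme and
#' every scheme pair, the Jaccard index of the two subgroup gene sets; a
#' combination missing from one scheme of a pair scores 0.
#'
#' @param tables list of [SubgroupTable-class], one per scheme (>= 2).
#' @return numeric matrix, rows = combinations (union over schemes),
#'   columns = scheme pairs (`"A|B"`).
#' @export
pairwiseSchemeSimilarity <- function(tables) {
  if (length(tables) < 2) stop("need >= 2 subgroup tables")
  ids <- vapply(tables, function(t) t@schemeId, "")
  names(tables) <- ids
  combos <- sort(unique(unlist(lapply(tables, function(t)
    names(t@groups)))))
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  out <- matrix(0, nrow = length(combos), ncol = length(pairs),
                dimnames = list(combos, vapply(pairs, paste,
                                               collapse = "|", "")))
  for (cb in combos) for (j in seq_along(pairs)) {
    ga <- tables[[pairs[[j]][1]]]@groups[[cb]]
    gb <- tables[[pairs[[j]][2]]]@groups[[cb]]
    out[cb, j] <- if (is.null(ga) || is.null(gb)) 0
                  else jaccardIndex(ga, gb)
  }
  out
}

#' Write the similarity matrix in long format (combination, pair, jaccard)
#'
#' @param mat matrix from [pairwiseSchemeSimilarity()].
#' @param path output TSV path.
#' @export
writeSimilarityTSV <- function(mat, path) {
  long <- data.frame(combination = rep(rownames(mat), ncol(mat)),
                     scheme_pair = rep(colnames(mat),
                                       each = nrow(mat)),
                     jaccard = as.vector(mat))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
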