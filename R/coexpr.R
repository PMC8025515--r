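# Simplified weighted co-expression analysis: preprocessing, soft
# threshold, adjacency, topological overlap, modules, hubs, enrichment.
#
# Single-block clustering with a static tree cut replaces block-wise
# processing with dynamic cutting: the gene sets fed into this stage are
# desk-scale (a few hundred prognostic-hallmark genes).

#' Read an expression matrix from TSV (genes x samples)
#'
#' @param path TSV with gene ids in the first column, sample ids as the
#'   header.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Log-transform an abundance matrix and optionally drop outlier samples
#'
#' Values become `log2(value + log_offset)`.  If `outlier_cut_height` is
#' given, samples are average-linkage clustered on Euclidean distance and
#' every sample first merging above the cut is removed (reported via
#' message).
#'
#' @param expr numeric matrix, genes x samples, non-negative.
#' @param log_offset pseudo-count added before the log (default 1).
#' @param outlier_cut_height optional dendrogram cut height.
#' @return transformed matrix, possibly with fewer samples.
#' @export
preprocessExpression <- function(expr, log_offset = 1,
                                 outlier_cut_height = NULL) {
  stopifnot(is.matrix(expr), all(is.finite(expr)), all(expr >= 0))
  out <- log2(expr + log_offset)
  if (!is.null(outlier_cut_height)) {
    hc <- hclust(dist(t(out)), method = "average")
    cl <- cutree(hc, h = outlier_cut_height)
    main <- as.integer(names(which.max(table(cl))))
    drop <- colnames(out)[cl != main]
    if (length(drop) == ncol(out))
      stop("outlier cut removed every sample")
    if (length(drop))
      message("removed ", length(drop), " outlier sample(s): ",
              paste(head(drop, 5), collapse = ", "))
    out <- out[, cl == main, drop = FALSE]
  }
  out
}

#' Scale-free topology fit of a connectivity vector
#'
#' Bins `log10(k)`, regresses log10 bin frequency on the mean log10
#' connectivity per bin, and returns the slope-signed R-squared
#' (`-sign(slope) * R^2`), positive when the degree distribution decays
#' as a power law.
#'
#' @param k positive connectivity values.
#' @param n_bins number of bins (default 10).
#' @return list with `fit` (signed R-squared) and `slope`.
#' @export
scaleFreeFit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(fit = 0, slope = NA_real_))
  br <- seq(min(k), max(k) + 1e-9, length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(list(fit = 0, slope = NA_real_))
  fit <- lm(log10(freq[ok]) ~ log10(kmean[ok]))
  r2 <- summary(fit)$r.squared
  slope <- coef(fit)[[2]]
  list(fit = -sign(slope) * r2, slope = slope)
}

#' Pick the soft-thresholding power
#'
#' For each candidate power, computes whole-network connectivity
#' `k_i = sum_j |cor(i,j)|^beta` and its scale-free fit; returns the
#' smallest power whose signed fit reaches `r2_cut`, or the power with
#' the best fit if none does.
#'
#' @param expr genes x samples matrix (already log-scale).
#' @param powers candidate integer powers (default 1:20).
#' @param r2_cut signed R-squared threshold (default 0.8).
#' @return list with `power` and `table` (power, fit, slope, mean_k).
#' @export
pickSoftThreshold <- function(expr, powers = 1:20, r2_cut = 0.8) {
  stopifnot(nrow(expr) >= 3, ncol(expr) >= 4)
  expr <- .drop_constant_genes(expr)
  ac <- abs(cor(t(expr)))
  diag(ac) <- 0
  tab <- do.call(rbind, lapply(powers, function(p) {
    k <- rowSums(ac^p)
    sf <- scaleFreeFit(k)
    data.frame(power = p, fit = sf$fit, slope = sf$slope,
               mean_k = mean(k))
  }))
  hit <- which(tab$fit >= r2_cut)
  power <- if (length(hit)) tab$power[hit[1]]
           else tab$power[which.max(tab$fit)]
  list(power = power, table = tab)
}

.drop_constant_genes <- function(expr) {
  sds <- apply(expr, 1, function(x) stats::sd(x))
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- rownames(expr)[sds == 0 | !is.finite(sds)]
    warning("dropping ", length(bad), " constant gene(s): ",
            paste(head(bad, 5), collapse = ", "))
    expr <- expr[!(rownames(expr) %in% bad), , drop = FALSE]
  }
  expr
}

#' Weighted co-expression adjacency
#'
#' Unsigned by default: `a_ij = |cor_ij|^beta`; signed:
#' `a_ij = ((1 + cor_ij)/2)^beta`.  The diagonal is set to 0 so
#' connectivity sums exclude self-adjacency.
#'
#' @param expr genes x samples matrix.
#' @param beta soft-thresholding power (>= 1).
#' @param signed use the signed transform (default unsigned).
#' @return symmetric genes x genes matrix in `[0, 1]`, zero diagonal.
#' @export
adjacencyMatrix <- function(expr, beta, signed = FALSE) {
  stopifnot(beta >= 1)
  expr <- .drop_constant_genes(expr)
  cc <- cor(t(expr))
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu` (u ranging over the other genes); the diagonal is
#' set to 1.
#'
#' @param adjacency symmetric matrix in `[0, 1]`.
#' @return symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
tomMatrix <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by clustering the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut statically
#' at `cut_height`; clusters below `min_module_size` are labelled 0
#' (unassigned) and modules are renumbered by decreasing size.
#'
#' @param tom topological overlap matrix.
#' @param min_module_size smallest retained module (default 20).
#' @param cut_height static tree-cut height on `1 - TOM` (default 0.995).
#' @return named integer vector, gene -> module label.
#' @export
detectModules <- function(tom, min_module_size = 20, cut_height = 0.995) {
  stopifnot(nrow(tom) == ncol(tom))
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  # average linkage is monotone; float noise can still produce tiny
  # height inversions that cutree rejects
  hc$height <- cummax(round(hc$height, 12))
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(cl))
  names(labels) <- rownames(tom)
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) labels[cl == as.integer(ord[i])] <- i
  }
  labels
}

#' Intramodular hub genes
#'
#' Ranks genes by intramodular connectivity (`kWithin`, the sum of a
#' gene's adjacency to other genes of its module) and keeps the top `n`
#' per module; genes tied with the n-th value are all included, so a
#' module can yield more than `n` hubs.
#'
#' @param adjacency symmetric adjacency matrix.
#' @param module_labels named integer vector from [detectModules()].
#' @param n hubs per module before tie extension (default 5).
#' @return list with `hubs` (module -> ordered gene vector) and
#'   `kWithin` (named numeric over all assigned genes).
#' @export
hubGenes <- function(adjacency, module_labels, n = 5) {
  mods <- sort(setdiff(unique(module_labels), 0L))
  if (!length(mods)) stop("no assigned modules")
  kw <- numeric(0)
  hubs <- list()
  for (m in mods) {
    genes <- names(module_labels)[module_labels == m]
    sub <- adjacency[genes, genes, drop = FALSE]
    diag(sub) <- 0
    k <- rowSums(sub)
    kw <- c(kw, k)
    k <- sort(k, decreasing = TRUE)
    if (length(k) <= n) {
      warning("module ", m, " has <= ", n, " genes; all returned as hubs")
      hubs[[as.character(m)]] <- names(k)
    } else {
      thresh <- k[n]
      hubs[[as.character(m)]] <- names(k)[k >= thresh]
    }
  }
  list(hubs = hubs, kWithin = kw)
}

#' Hypergeometric enrichment of a module against a background
#'
#' For every biological_process term with at least one module gene after
#' true-path propagation, tests over-representation with the one-sided
#' hypergeometric upper tail; Benjamini-Hochberg adjusted p-values are
#' reported alongside the raw ones (the raw `p < alpha` rule selects the
#' significant records, matching the common enrichment-service default).
#'
#' @param module_genes character vector, subset of `background_genes`.
#' @param background_genes character vector, the enrichment universe.
#' @param graph an [OntologyGraph-class].
#' @param annotations an [AnnotationTable-class].
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param namespace ontology namespace tested (default
#'   `biological_process`; use `NULL` for all).
#' @param relations closure relations for the true-path propagation.
#' @return data.frame (term_id, k, K, n, N, p_raw, p_adjusted,
#'   significant), sorted by `p_raw`.
#' @export
enrichModule <- function(module_genes, background_genes, graph,
                         annotations, alpha = 0.05,
                         namespace = "biological_process",
                         relations = c("is_a", "part_of")) {
  background_genes <- unique(background_genes)
  module_genes <- unique(module_genes)
  if (!length(background_genes)) stop("empty background")
  stopifnot(all(module_genes %in% background_genes))
  terms <- graph@terms
  cand <- terms$term_id[!terms$obsolete]
  if (!is.null(namespace))
    cand <- intersect(cand, terms$term_id[terms$namespace %in% namespace])
  # propagate: per candidate term, the annotated background genes
  g <- ontoIgraph(graph, relations)
  t2g <- termGeneIndex(annotations)
  N <- length(background_genes)
  n <- length(module_genes)
  rows <- lapply(cand, function(t) {
    fam <- names(igraph::subcomponent(g, t, mode = "in"))
    genes <- unique(unlist(t2g[fam], use.names = FALSE))
    Kg <- intersect(genes, background_genes)
    k <- length(intersect(Kg, module_genes))
    if (k == 0) return(NULL)
    K <- length(Kg)
    data.frame(term_id = t, k = k, K = K, n = n, N = N,
               p_raw = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(term_id = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_raw < alpha
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full co-expression stage
#'
#' Preprocess, pick (or accept) the soft power, build adjacency and TOM,
#' detect modules, rank hubs, and (when a graph and annotations are
#' supplied) enrich every module against the expression background.
#'
#' @inheritParams preprocessExpression
#' @inheritParams enrichModule
#' @param beta soft power; `NULL` to auto-pick via
#'   [pickSoftThreshold()].
#' @param signed signed adjacency transform.
#' @param min_module_size,cut_height module detection parameters.
#' @param n_hubs hubs per module before tie extension.
#' @param preprocessed set `TRUE` if `expr` is already log-scale.
#' @return a [CoexpressionResult-class].
#' @export
runCoexpression <- function(expr, beta = NULL, signed = FALSE,
                            log_offset = 1, outlier_cut_height = NULL,
                            min_module_size = 20, cut_height = 0.995,
                            n_hubs = 5, graph = NULL, annotations = NULL,
                            alpha = 0.05, preprocessed = FALSE) {
  if (!preprocessed)
    expr <- preprocessExpression(expr, log_offset, outlier_cut_height)
  if (is.null(beta)) beta <- pickSoftThreshold(expr)$power
  adj <- adjacencyMatrix(expr, beta, signed)
  tom <- tomMatrix(adj)
  labels <- detectModules(tom, min_module_size, cut_height)
  enr <- data.frame()
  hubs <- list(); kw <- numeric(0)
  if (any(labels != 0)) {
    hb <- hubGenes(adj, labels, n_hubs)
    hubs <- hb$hubs; kw <- hb$kWithin
    if (!is.null(graph) && !is.null(annotations)) {
      bg <- rownames(expr)
      enr <- do.call(rbind, lapply(names(hubs), function(m) {
        e <- enrichModule(names(labels)[labels == as.integer(m)], bg,
                          graph, annotations, alpha)
        if (nrow(e)) cbind(module = as.integer(m), e) else NULL
      }))
      if (is.null(enr)) enr <- data.frame()
    }
  }
  new("CoexpressionResult", power = as.numeric(beta), adjacency = adj,
      tom = tom, moduleLabels = labels, kWithin = kw, hubs = hubs,
      enrichment = enr)
}
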