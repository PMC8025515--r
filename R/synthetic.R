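# Seeded generators for every pipeline input, with planted ground truth.
#
# Each generator is a pure function of its parameters and seed; the
# world-level generator derives one named sub-seed per component, so
# adding a generator never perturbs the draws of existing ones.

.term_id <- function(i) sprintf("SYN:%06d", i)
.gene_id <- function(i) sprintf("G%05d", i)

#' Generate a layered random ontology DAG
#'
#' Terms are created in order; every non-root draws its parents from
#' earlier terms (Poisson-distributed count around `mean_parents`, floor
#' 1), which makes the graph acyclic by construction.  Each edge is
#' `part_of` with probability `p_part_of`, else `is_a`.
#'
#' @param n_terms total number of terms (>= `n_roots`).
#' @param n_roots number of root terms (default 1).
#' @param mean_parents mean parent count per non-root (default 1.5).
#' @param p_part_of probability an edge is `part_of` (default 0.2).
#' @param seed integer seed.
#' @param version version label (default `"v1"`).
#' @param namespace namespace for every term.
#' @return an [OntologyGraph-class].
#' @export
generateOntology <- function(n_terms, n_roots = 1, mean_parents = 1.5,
                             p_part_of = 0.2, seed = 1, version = "v1",
                             namespace = "biological_process") {
  if (n_roots < 1 || n_terms < n_roots)
    stop("need n_terms >= n_roots >= 1")
  if (mean_parents < 0 || p_part_of < 0 || p_part_of > 1)
    stop("invalid mean_parents or p_part_of")
  withSeed(seed, {
    ids <- .term_id(seq_len(n_terms))
    edges <- NULL
    if (n_terms > n_roots) {
      edges <- do.call(rbind, lapply((n_roots + 1):n_terms, function(i) {
        np <- min(max(1L, rpois(1, mean_parents)), i - 1L)
        parents <- sample.int(i - 1L, np)
        data.frame(child = ids[i], parent = ids[parents],
                   relation = ifelse(runif(np) < p_part_of, "part_of",
                                     "is_a"),
                   stringsAsFactors = FALSE)
      }))
    }
    terms <- data.frame(term_id = ids,
                        name = paste("synthetic term", seq_len(n_terms)),
                        namespace = namespace, obsolete = FALSE,
                        replaced_by = NA_character_,
                        alt_ids = NA_character_,
                        stringsAsFactors = FALSE)
    OntologyGraph(version, terms, edges)
  })
}

#' Generate direct gene annotations biased toward deep terms
#'
#' Each gene draws a Poisson number of direct terms (floor 1) with
#' probability proportional to term depth + 1, so true-path propagation
#' is non-trivial.
#'
#' @param graph an [OntologyGraph-class].
#' @param n_genes number of genes.
#' @param mean_terms_per_gene mean direct annotations per gene.
#' @param seed integer seed.
#' @param gene_ids optional gene id vector (length `n_genes`).
#' @return an [AnnotationTable-class].
#' @export
generateAnnotations <- function(graph, n_genes, mean_terms_per_gene = 3,
                                seed = 1, gene_ids = NULL) {
  active <- graph@terms$term_id[!graph@terms$obsolete]
  if (is.null(gene_ids)) gene_ids <- .gene_id(seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  depth <- .term_depths(graph)
  w <- depth[active] + 1
  withSeed(seed, {
    pairs <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      nt <- min(max(1L, rpois(1, mean_terms_per_gene)), length(active))
      data.frame(gene_id = gene_ids[i],
                 term_id = sample(active, nt, prob = w),
                 stringsAsFactors = FALSE)
    }))
    suppressWarnings(AnnotationTable(pairs, graph = graph))
  })
}

# longest-path depth from any root, per active term
.term_depths <- function(graph) {
  g <- ontoIgraph(graph)
  ord <- rev(names(igraph::topo_sort(g, mode = "out")))  # parents first
  depth <- setNames(rep(0, length(ord)), ord)
  ed <- graph@edges
  for (t in ord) {
    ps <- ed$parent[ed$child == t]
    if (length(ps)) depth[t] <- max(depth[ps]) + 1
  }
  depth
}

#' Generate mapping schemes with a planted consensus pool
#'
#' For every hallmark a shared pool of `terms_per_hallmark` terms is
#' planted.  Each scheme fills its per-hallmark selection with a
#' Binomial(`terms_per_hallmark`, `overlap_p`) draw from the pool and
#' unique terms (disjoint across schemes) for the rest, then hallmark
#' coverage masks hallmarks per scheme (emulating published schemes that
#' cover only 8 of the 10).
#'
#' @param graph an [OntologyGraph-class] supplying active terms.
#' @param n_schemes number of schemes (ids `S1`, `S2`, ...).
#' @param terms_per_hallmark selection size per covered hallmark.
#' @param coverage integer vector (length `n_schemes`) of hallmarks
#'   covered per scheme; default full coverage.
#' @param overlap_p expected fraction of a selection drawn from the
#'   shared pool, in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `schemes` (list of [MappingScheme-class]) and
#'   `truth` (pools, per-scheme selections, coverage).
#' @export
generateSchemes <- function(graph, n_schemes = 4, terms_per_hallmark = 5,
                            coverage = rep(10, n_schemes),
                            overlap_p = 0.5, seed = 1) {
  stopifnot(overlap_p >= 0, overlap_p <= 1,
            length(coverage) == n_schemes)
  active <- graph@terms$term_id[!graph@terms$obsolete]
  hallmarks <- cancerHallmarks()
  need <- terms_per_hallmark * length(hallmarks) * (1 + n_schemes)
  if (length(active) < need)
    stop("term pool too small: need >= ", need, " active terms, have ",
         length(active))
  withSeed(seed, {
    shuffled <- sample(active)
    take <- function(n) {
      out <- shuffled[seq_len(n)]
      shuffled <<- shuffled[-seq_len(n)]
      out
    }
    pools <- lapply(hallmarks, function(h) take(terms_per_hallmark))
    names(pools) <- hallmarks
    covered <- lapply(seq_len(n_schemes), function(s)
      sample(hallmarks, coverage[s]))
    schemes <- list()
    selections_truth <- list()
    for (s in seq_len(n_schemes)) {
      sel <- list()
      for (h in covered[[s]]) {
        n_shared <- stats::rbinom(1, terms_per_hallmark, overlap_p)
        shared <- if (n_shared > 0) sample(pools[[h]], n_shared)
                  else character()
        uniq <- if (n_shared < terms_per_hallmark)
          take(terms_per_hallmark - n_shared) else character()
        sel[[h]] <- c(shared, uniq)
      }
      id <- paste0("S", s)
      rows <- data.frame(hallmark = rep(names(sel), lengths(sel)),
                         term_id = unlist(sel, use.names = FALSE))
      schemes[[id]] <- loadScheme(rows, id)
      selections_truth[[id]] <- sel
    }
    list(schemes = schemes,
         truth = list(pools = pools, selections = selections_truth,
                      coverage = setNames(lengths(covered),
                                          names(schemes))))
  })
}

#' Generate a churned second ontology version
#'
#' The new version obsoletes a random fraction of non-root terms
#' (removing their edges), adds new terms attached to surviving terms,
#' and rewires a fraction of the surviving edges to a different
#' (cycle-safe) parent.  All churn events are recorded as truth.
#'
#' @param graph the old [OntologyGraph-class].
#' @param p_obsolete fraction of terms obsoleted.
#' @param n_new_terms number of terms added.
#' @param p_rewire fraction of surviving edges rewired.
#' @param seed integer seed.
#' @param new_version version label for the new graph (default `"v2"`).
#' @return list `old`, `new`, `truth` (obsoleted, added, edges
#'   added/removed).
#' @export
generateVersionPair <- function(graph, p_obsolete = 0.05,
                                n_new_terms = 20, p_rewire = 0.05,
                                seed = 1, new_version = "v2") {
  stopifnot(p_obsolete >= 0, p_obsolete <= 1, p_rewire >= 0,
            p_rewire <= 1, n_new_terms >= 0)
  withSeed(seed, {
    terms <- graph@terms
    edges <- graph@edges
    roots <- setdiff(terms$term_id, edges$child)
    cand <- setdiff(terms$term_id[!terms$obsolete], roots)
    n_obs <- round(p_obsolete * length(cand))
    obsoleted <- if (n_obs > 0) sample(cand, n_obs) else character()
    terms$obsolete[terms$term_id %in% obsoleted] <- TRUE
    drop_e <- edges$child %in% obsoleted | edges$parent %in% obsoleted
    removed_edges <- edges[drop_e, , drop = FALSE]
    edges <- edges[!drop_e, , drop = FALSE]
    survivors <- terms$term_id[!terms$obsolete]
    # rewire: give a sampled edge a different cycle-safe parent
    added_edges <- NULL
    if (p_rewire > 0 && nrow(edges) > 1) {
      n_rw <- round(p_rewire * nrow(edges))
      if (n_rw > 0) {
        for (i in sample(nrow(edges), n_rw)) {
          # rebuild after every rewire: cycle-safety must be judged on
          # the current edge set
          g <- igraph::graph_from_data_frame(
            edges[, c("child", "parent")], directed = TRUE)
          ch <- edges$child[i]
          below <- if (ch %in% igraph::V(g)$name)
            names(igraph::subcomponent(g, ch, mode = "in"))
          else ch
          ok <- setdiff(survivors, c(below, edges$parent[i]))
          if (!length(ok)) next
          removed_edges <- rbind(removed_edges, edges[i, , drop = FALSE])
          edges$parent[i] <- sample(ok, 1)
          added_edges <- rbind(added_edges, edges[i, , drop = FALSE])
        }
      }
    }
    # add new terms attached to surviving terms
    added_terms <- character()
    if (n_new_terms > 0) {
      added_terms <- sprintf("SYN:9%05d", seq_len(n_new_terms))
      terms <- rbind(terms, data.frame(
        term_id = added_terms, name = "new synthetic term",
        namespace = terms$namespace[1], obsolete = FALSE,
        replaced_by = NA_character_, alt_ids = NA_character_))
      new_e <- do.call(rbind, lapply(added_terms, function(id) {
        np <- max(1L, rpois(1, 1.5))
        data.frame(child = id,
                   parent = sample(survivors, min(np, length(survivors))),
                   relation = "is_a", stringsAsFactors = FALSE)
      }))
      edges <- rbind(edges, new_e)
      added_edges <- rbind(added_edges, new_e)
    }
    new_graph <- OntologyGraph(new_version, terms, edges)
    list(old = graph, new = new_graph,
         truth = list(obsoleted = obsoleted, added = added_terms,
                      edges_added = added_edges,
                      edges_removed = removed_edges))
  })
}

#' Generate an FPKM-like expression matrix with planted modules
#'
#' Per module, a latent per-sample profile; member genes load on it so
#' the expected pairwise within-module Pearson correlation (on the log
#' scale) equals `within_cor`; background genes are independent noise.
#' Values are exponentiated to an FPKM-like scale, inverted by
#' [preprocessExpression()] with the default offset.
#'
#' @param n_genes total genes (>= `sum(module_sizes)`).
#' @param n_samples number of samples.
#' @param module_sizes integer vector of planted module sizes.
#' @param within_cor target within-module correlation in `[0, 1)`.
#' @param noise_sd per-gene noise standard deviation.
#' @param seed integer seed.
#' @param gene_ids optional gene ids (length `n_genes`).
#' @return list `matrix` (genes x samples, FPKM-like), `labels` (named
#'   integer; 0 = background).
#' @export
generateExpression <- function(n_genes, n_samples, module_sizes,
                               within_cor = 0.8, noise_sd = 1, seed = 1,
                               gene_ids = NULL) {
  stopifnot(n_genes >= sum(module_sizes), within_cor >= 0,
            within_cor < 1, noise_sd > 0)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  withSeed(seed, {
    labels <- rep(0L, n_genes)
    if (length(module_sizes))
      labels[seq_len(sum(module_sizes))] <-
        rep(seq_along(module_sizes), module_sizes)
    names(labels) <- gene_ids
    loading <- noise_sd * sqrt(within_cor / (1 - within_cor))
    latent <- matrix(rnorm(length(module_sizes) * n_samples),
                     nrow = length(module_sizes))
    logx <- matrix(rnorm(n_genes * n_samples, sd = noise_sd), n_genes,
                   n_samples, dimnames = list(gene_ids,
                                              sprintf("S%03d",
                                                      seq_len(n_samples))))
    for (m in seq_along(module_sizes))
      logx[labels == m, ] <- sweep(logx[labels == m, , drop = FALSE], 2,
                                   loading * latent[m, ], `+`)
    fpkm <- pmax(2^(5 + logx) - 1, 0)
    list(matrix = fpkm, labels = labels)
  })
}

#' Generate a prognostic table with planted cancer-type combinations
#'
#' Plants gene groups whose exact prognostic signature equals a given
#' cancer-type combination, plus background genes prognostic in random
#' cancers at `per_cancer_rate` (background signatures colliding with a
#' planted combination are redrawn so the planted truth stays exact).
#'
#' @param gene_pool genes to draw from.
#' @param n_cancers number of cancer types (`C01`, `C02`, ...).
#' @param per_cancer_rate probability a background gene is prognostic in
#'   any given cancer.
#' @param planted_combinations list of `list(cancers = <indices or
#'   names>, n = <genes>)`.
#' @param seed integer seed.
#' @return list `prognostic` (cancer_type -> gene vector) and `truth`
#'   (combination key -> planted gene vector).
#' @export
generatePrognostic <- function(gene_pool, n_cancers = 17,
                               per_cancer_rate = 0.02,
                               planted_combinations = list(), seed = 1) {
  stopifnot(n_cancers >= 1, per_cancer_rate >= 0, per_cancer_rate <= 1)
  cancers <- sprintf("C%02d", seq_len(n_cancers))
  withSeed(seed, {
    pool <- sample(gene_pool)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    truth <- list()
    sets <- setNames(vector("list", n_cancers), cancers)
    planted_keys <- character()
    for (pc in planted_combinations) {
      cs <- if (is.numeric(pc$cancers)) cancers[pc$cancers]
            else pc$cancers
      genes <- take(pc$n)
      key <- comboKey(cs)
      planted_keys <- c(planted_keys, key)
      truth[[key]] <- sort(genes)
      for (cn in cs) sets[[cn]] <- c(sets[[cn]], genes)
    }
    if (per_cancer_rate > 0) {
      for (g in pool) {
        for (try in 1:20) {
          sig <- cancers[runif(n_cancers) < per_cancer_rate]
          if (!(comboKey(sig) %in% planted_keys)) break
        }
        for (cn in sig) sets[[cn]] <- c(sets[[cn]], g)
      }
    }
    sets <- lapply(sets, function(x) sort(unique(x)))
    list(prognostic = sets[lengths(sets) > 0], truth = truth)
  })
}

#' Generate a complete synthetic study world
#'
#' Bundles an ontology version pair with churn, per-version annotations,
#' mapping schemes with a planted consensus pool, a prognostic table
#' with planted cancer-type combinations, and an expression matrix with
#' planted co-expression modules whose genes are annotated to dedicated
#' marker terms (so enrichment has a known answer).  Defaults follow the
#' scale of the study data this emulates (about 10000 genes, 600 terms,
#' 4 schemes, 17 cancer types, 100 samples); `scale` shrinks gene and
#' term counts proportionally for quick runs.
#'
#' @param seed master integer seed; every component derives a named
#'   sub-seed from it.
#' @param scale multiplier on gene/term counts (default 1).
#' @param n_schemes,coverage,overlap_p passed to [generateSchemes()].
#' @param n_cancers passed to [generatePrognostic()].
#' @param n_samples,module_sizes,within_cor passed to
#'   [generateExpression()].
#' @return a [SyntheticWorld-class].
#' @export
syntheticWorld <- function(seed = 1, scale = 1, n_schemes = 4,
                           coverage = c(10, 10, 8, 8), overlap_p = 0.5,
                           n_cancers = 17, n_samples = 100,
                           module_sizes = c(50, 50, 50),
                           within_cor = 0.8) {
  n_terms <- max(300, round(600 * scale))
  n_genes <- max(500, round(10000 * scale))
  graph_old <- generateOntology(n_terms, n_roots = 1, mean_parents = 1.5,
                                p_part_of = 0.2,
                                seed = subSeed(seed, "ontology"),
                                version = "v-old")
  pair <- generateVersionPair(graph_old, p_obsolete = 0.05,
                              n_new_terms = round(n_terms * 0.05),
                              p_rewire = 0.05,
                              seed = subSeed(seed, "versions"),
                              new_version = "v-new")
  ann_old <- generateAnnotations(graph_old, n_genes,
                                 mean_terms_per_gene = 3,
                                 seed = subSeed(seed, "annotations"))
  ann_new <- .drift_annotations(ann_old, pair$new,
                                seed = subSeed(seed, "drift"))
  # schemes select from terms active in both versions, as published
  # selections mostly survive churn
  shared_active <- intersect(
    graph_old@terms$term_id[!graph_old@terms$obsolete],
    pair$new@terms$term_id[!pair$new@terms$obsolete])
  sel_graph <- OntologyGraph(
    "selection-pool",
    graph_old@terms[graph_old@terms$term_id %in% shared_active, ,
                    drop = FALSE],
    graph_old@edges[graph_old@edges$child %in% shared_active &
                    graph_old@edges$parent %in% shared_active, ,
                    drop = FALSE])
  sch <- generateSchemes(sel_graph, n_schemes = n_schemes,
                         terms_per_hallmark = 5, coverage = coverage,
                         overlap_p = overlap_p,
                         seed = subSeed(seed, "schemes"))
  genes <- names(ann_old@entries)
  prog <- generatePrognostic(
    genes, n_cancers = n_cancers, per_cancer_rate = 0.02,
    planted_combinations = list(list(cancers = 1:2, n = 8),
                                list(cancers = 2:4, n = 6),
                                list(cancers = c(1, 5), n = 10)),
    seed = subSeed(seed, "prognostic"))
  n_expr <- sum(module_sizes) + max(50, round(150 * scale))
  expr_genes <- withSeed(subSeed(seed, "exprgenes"),
                         sample(genes, min(n_expr, length(genes))))
  expr <- generateExpression(length(expr_genes), n_samples, module_sizes,
                             within_cor = within_cor,
                             seed = subSeed(seed, "expression"),
                             gene_ids = expr_genes)
  # marker terms: one fresh leaf term per planted module, annotating
  # exactly the module's genes in both versions
  marked <- .plant_markers(pair$old, pair$new, ann_old, ann_new,
                           expr$labels)
  new("SyntheticWorld", seed = as.numeric(seed),
      graphOld = marked$graph_old, graphNew = marked$graph_new,
      annotations = list(old = marked$ann_old, new = marked$ann_new),
      schemes = sch$schemes, prognostic = prog$prognostic,
      expression = expr,
      truth = list(schemes = sch$truth, churn = pair$truth,
                   prognostic = prog$truth,
                   modules = expr$labels,
                   enriched_terms = marked$marker_terms))
}

# new-version annotations: keep old pairs (minus those to obsoleted
# terms), annotate new terms, and add extra annotations to a sampled
# subset of genes (general annotation growth)
.drift_annotations <- function(ann_old, graph_new, seed,
                               growth_rate = 0.1) {
  active <- graph_new@terms$term_id[!graph_new@terms$obsolete]
  e <- ann_old@entries
  pairs <- data.frame(gene_id = rep(names(e), lengths(e)),
                      term_id = unlist(e, use.names = FALSE))
  pairs <- pairs[pairs$term_id %in% active, , drop = FALSE]
  withSeed(seed, {
    n_extra <- round(growth_rate * nrow(pairs))
    if (n_extra > 0)
      pairs <- rbind(pairs, data.frame(
        gene_id = sample(names(e), n_extra, replace = TRUE),
        term_id = sample(active, n_extra, replace = TRUE)))
    suppressWarnings(AnnotationTable(pairs, graph = graph_new))
  })
}

# attach one marker leaf term per planted expression module to both
# graph versions and annotate exactly the module's genes with it
.plant_markers <- function(graph_old, graph_new, ann_old, ann_new,
                           labels) {
  mods <- sort(setdiff(unique(labels), 0L))
  marker <- sprintf("SYN:MOD%03d", mods)
  add_terms <- function(graph) {
    root <- setdiff(graph@terms$term_id, graph@edges$child)[1]
    terms <- rbind(graph@terms, data.frame(
      term_id = marker, name = paste("module marker", mods),
      namespace = graph@terms$namespace[1], obsolete = FALSE,
      replaced_by = NA_character_, alt_ids = NA_character_))
    edges <- rbind(graph@edges,
                   data.frame(child = marker, parent = root,
                              relation = "is_a"))
    OntologyGraph(graph@version, terms, edges)
  }
  add_ann <- function(ann, graph) {
    e <- ann@entries
    pairs <- data.frame(gene_id = rep(names(e), lengths(e)),
                        term_id = unlist(e, use.names = FALSE))
    extra <- do.call(rbind, lapply(mods, function(m) data.frame(
      gene_id = names(labels)[labels == m], term_id = marker[m])))
    suppressWarnings(AnnotationTable(rbind(pairs, extra), graph = graph))
  }
  graph_old <- add_terms(graph_old)
  graph_new <- add_terms(graph_new)
  list(graph_old = graph_old, graph_new = graph_new,
       ann_old = add_ann(ann_old, graph_old),
       ann_new = add_ann(ann_new, graph_new),
       marker_terms = setNames(marker, mods))
}

#' Write a synthetic world to disk in the formats the pipeline reads
#'
#' OBO for the two graph versions, TSVs for annotations, schemes,
#' prognostic table and expression matrix, and the truth as JSON.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeOBO(world@graphOld, p("ontology-old.obo"))
  writeOBO(world@graphNew, p("ontology-new.obo"))
  wr_ann <- function(ann, f) {
    e <- ann@entries
    write.table(data.frame(gene_id = rep(names(e), lengths(e)),
                           term_id = unlist(e, use.names = FALSE)),
                p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr_ann(world@annotations$old, "annotations-old.tsv")
  wr_ann(world@annotations$new, "annotations-new.tsv")
  sch <- do.call(rbind, lapply(world@schemes, function(s) {
    sel <- s@selections
    data.frame(scheme_id = s@schemeId,
               hallmark = rep(names(sel), lengths(sel)),
               term_id = unlist(sel, use.names = FALSE))
  }))
  write.table(sch, p("schemes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pr <- world@prognostic
  write.table(data.frame(cancer_type = rep(names(pr), lengths(pr)),
                         gene_id = unlist(pr, use.names = FALSE)),
              p("prognostic.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  m <- world@expression$matrix
  write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              p("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(world@truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  out <- c(ontology_old = p("ontology-old.obo"),
           ontology_new = p("ontology-new.obo"),
           annotations_old = p("annotations-old.tsv"),
           annotations_new = p("annotations-new.tsv"),
           schemes = p("schemes.tsv"), prognostic = p("prognostic.tsv"),
           expression = p("expression.tsv"), truth = p("truth.json"))
  out
}
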