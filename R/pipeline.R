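# End-to-end orchestration with config validation and provenance.

.CONFIG_KEYS <- c(
  # input paths
  "ontology_old", "ontology_new", "annotations_old", "annotations_new",
  "schemes", "pathway_genes", "correspondence", "prognostic",
  "expression",
  # parameters
  "relations", "min_schemes", "min_size", "beta", "signed",
  "cut_height", "min_module_size", "n_hubs", "alpha", "weight_is_a",
  "weight_part_of", "log_offset", "outlier_cut_height", "seed",
  # output
  "out_dir")

.PATH_KEYS <- c("ontology_old", "ontology_new", "annotations_old",
                "annotations_new", "schemes", "pathway_genes",
                "correspondence", "prognostic", "expression")

#' Validate a pipeline run configuration
#'
#' A config is a named list (or a YAML file holding one).  Unknown keys
#' are an error (named in the message); every referenced input path must
#' exist; parameter ranges are checked.  Defaults are filled in
#' explicitly so that the provenance record echoes every effective
#' parameter.
#'
#' @param config named list or YAML path.
#' @return the validated config with defaults filled in.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(relations = c("is_a", "part_of"), min_schemes = 3,
                   min_size = 5, beta = "auto", signed = FALSE,
                   cut_height = 0.995, min_module_size = 20, n_hubs = 5,
                   alpha = 0.05, weight_is_a = 0.8, weight_part_of = 0.6,
                   log_offset = 1, outlier_cut_height = NULL, seed = 1,
                   out_dir = "hallmark-run")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[k] <- defaults[k]
  for (k in intersect(.PATH_KEYS, names(config)))
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      stop("config path '", k, "' does not exist: ", config[[k]])
  if (is.null(config$ontology_old))
    stop("config requires 'ontology_old'")
  if (is.null(config$annotations_old))
    stop("config requires 'annotations_old'")
  if (is.null(config$schemes)) stop("config requires 'schemes'")
  with(config, {
    stopifnot(min_schemes >= 1, min_size >= 1, alpha > 0, alpha < 1,
              weight_is_a > 0, weight_is_a < 1, weight_part_of > 0,
              weight_part_of < 1, cut_height > 0, cut_height <= 1)
    if (!identical(beta, "auto")) stopifnot(beta >= 1)
    stopifnot(all(relations %in% c("is_a", "part_of")))
  })
  config
}

.provenance <- function(config) {
  paths <- unlist(config[intersect(.PATH_KEYS, names(config))])
  # hash inputs and parameters only: two runs differing solely in
  # out_dir are the same analysis
  hashed <- config[setdiff(names(config), "out_dir")]
  canon <- jsonlite::toJSON(hashed[order(names(hashed))],
                            auto_unbox = TRUE, null = "null")
  tmp <- tempfile(); writeLines(canon, tmp)
  list(tool = "hallmarkConsensus",
       tool_version = as.character(packageVersion("hallmarkConsensus")),
       config_hash = unname(tools::md5sum(tmp)),
       input_digests = as.list(tools::md5sum(paths)),
       config = config,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

# TSV with a provenance-id comment header
.stage_tsv <- function(df, path, run_id) {
  con <- file(path, "w")
  writeLines(paste0("# provenance: ", run_id), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the full comparison pipeline
#'
#' Executes, in order: ontology + annotation loading, scheme loading and
#' hallmark gene-set construction, set-comparison reports (term
#' frequency, unique fractions, consensus terms, union upset), the
#' prognostic subgroup comparison, the optional co-expression stage
#' (expression input present), and the optional version diff (second
#' ontology present).  Stages whose optional inputs are missing are
#' skipped with a log message, never silently; a failing stage stops the
#' run with its name.
#'
#' @param config named list or YAML path, see [validateRunConfig()].
#' @return invisible list of stage results, written paths and the
#'   provenance record.
#' @export
runPipeline <- function(config) {
  config <- validateRunConfig(config)
  prov <- .provenance(config)
  run_id <- prov$config_hash
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  rels <- config$relations
  weights <- c(is_a = config$weight_is_a,
               part_of = config$weight_part_of)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list(provenance = prov)

  res$graph_old <- stage("ontology", parseOBO(config$ontology_old))
  res$annotations_old <- stage("annotations",
    readAnnotationsTSV(config$annotations_old, res$graph_old))

  res$schemes <- stage("schemes", {
    tab <- read.delim(config$schemes, stringsAsFactors = FALSE)
    lapply(split(tab, tab$scheme_id), function(df)
      loadScheme(df, df$scheme_id[1]))
  })
  res$gene_sets <- stage("hallmark_gene_sets",
    lapply(res$schemes, buildHallmarkGeneSets, graph = res$graph_old,
           annotations = res$annotations_old, relations = rels))
  if (!is.null(config$pathway_genes)) {
    res$pathway_scheme <- stage("pathway_scheme",
      loadPathwayScheme(config$pathway_genes, "PW1"))
    res$gene_sets$PW1 <- pathwaySchemeGenes(res$pathway_scheme)
  } else message("no pathway_genes input; pathway scheme skipped")

  res$setcomp <- stage("setcomp", {
    freq <- termSelectionFrequency(res$schemes)
    uniq <- vapply(res$schemes, uniqueTermFraction,
                   numeric(1), schemes = res$schemes)
    cons_schemes <- res$schemes
    if (!is.null(config$correspondence) &&
        !is.null(res$pathway_scheme))
      cons_schemes <- c(cons_schemes,
                        list(convertPathwayScheme(res$pathway_scheme,
                                                  config$correspondence)))
    cons <- if (length(cons_schemes) >= config$min_schemes)
      consensusTerms(cons_schemes, config$min_schemes) else NULL
    unions <- lapply(res$gene_sets, hallmarkUnion)
    upset <- exclusiveIntersections(unions)
    .stage_tsv(data.frame(term_id = names(freq$overall),
                          n_schemes = unname(freq$overall)),
               file.path(out, "term_frequency.tsv"), run_id)
    .stage_tsv(data.frame(scheme_id = names(uniq),
                          unique_pct = unname(uniq)),
               file.path(out, "unique_fraction.tsv"), run_id)
    if (!is.null(cons)) {
      ch <- cons$perHallmark
      .stage_tsv(data.frame(
        hallmark = rep(names(ch), lengths(ch)),
        term_id = unlist(ch, use.names = FALSE)),
        file.path(out, "consensus_terms.tsv"), run_id)
    }
    .stage_tsv(upset[, c("combo", "degree", "n")],
               file.path(out, "upset_counts.tsv"), run_id)
    list(frequency = freq, unique_fraction = uniq, consensus = cons,
         upset = upset)
  })

  if (!is.null(config$prognostic)) {
    res$prognostic <- stage("prognostic", {
      prog <- readPrognosticTSV(config$prognostic)
      onto_sets <- Filter(function(g) length(g@perHallmark) > 0,
                          res$gene_sets)
      tables <- lapply(onto_sets, function(gs)
        subgroupPartition(prognosticHallmarkGenes(gs, prog),
                          config$min_size, gs@schemeId))
      sim <- if (length(tables) >= 2)
        pairwiseSchemeSimilarity(tables) else NULL
      if (!is.null(sim)) {
        long <- data.frame(
          combination = rep(rownames(sim), ncol(sim)),
          scheme_pair = rep(colnames(sim), each = nrow(sim)),
          jaccard = as.vector(sim))
        .stage_tsv(long, file.path(out, "subgroup_jaccard.tsv"), run_id)
      }
      list(tables = tables, similarity = sim)
    })
  } else message("no prognostic input; prognostic stage skipped")

  if (!is.null(config$expression)) {
    res$coexpr <- stage("coexpr", {
      expr <- readExpressionTSV(config$expression)
      beta <- if (identical(config$beta, "auto")) NULL else config$beta
      cx <- runCoexpression(expr, beta = beta, signed = config$signed,
                            log_offset = config$log_offset,
                            outlier_cut_height =
                              config$outlier_cut_height,
                            min_module_size = config$min_module_size,
                            cut_height = config$cut_height,
                            n_hubs = config$n_hubs,
                            graph = res$graph_old,
                            annotations = res$annotations_old,
                            alpha = config$alpha)
      .stage_tsv(data.frame(gene_id = names(cx@moduleLabels),
                            module = unname(cx@moduleLabels)),
                 file.path(out, "modules.tsv"), run_id)
      if (length(cx@hubs))
        .stage_tsv(data.frame(
          module = rep(names(cx@hubs), lengths(cx@hubs)),
          gene_id = unlist(cx@hubs, use.names = FALSE)),
          file.path(out, "hub_genes.tsv"), run_id)
      if (nrow(cx@enrichment))
        .stage_tsv(cx@enrichment, file.path(out, "enrichment.tsv"),
                   run_id)
      sig <- if (nrow(cx@enrichment))
        cx@enrichment[cx@enrichment$significant, , drop = FALSE]
      else cx@enrichment
      modterms <- if (nrow(sig))
        lapply(split(sig$term_id, sig$module), unique) else list()
      simmat <- tryCatch(
        moduleSimilarityMatrix(modterms, res$graph_old, weights),
        error = function(e) NULL)
      if (!is.null(simmat))
        .stage_tsv(data.frame(module = rownames(simmat), simmat,
                              check.names = FALSE),
                   file.path(out, "module_similarity.tsv"), run_id)
      list(result = cx, module_similarity = simmat)
    })
  } else message("no expression input; coexpr stage skipped")

  if (!is.null(config$ontology_new)) {
    res$evolution <- stage("evolution", {
      graph_new <- parseOBO(config$ontology_new)
      ids <- names(res$schemes)
      sel_old <- unique(unlist(res$schemes[[ids[1]]]@selections))
      sel_new <- unique(unlist(
        res$schemes[[ids[min(2, length(ids))]]]@selections))
      vd <- diffVersions(res$graph_old, graph_new, sel_old, sel_new)
      .stage_tsv(vd@nodes, file.path(out, "version_diff_nodes.tsv"),
                 run_id)
      drift <- NULL
      if (!is.null(config$annotations_new)) {
        ann_new <- readAnnotationsTSV(config$annotations_new, graph_new)
        all_sel <- unique(c(sel_old, sel_new))
        drift <- annotationCountDrift(res$graph_old,
                                      res$annotations_old, graph_new,
                                      ann_new, all_sel, rels)
        .stage_tsv(drift, file.path(out, "annotation_drift.tsv"),
                   run_id)
      }
      list(diff = vd, drift = drift)
    })
  } else message("no ontology_new input; evolution stage skipped")

  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(res)
}
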