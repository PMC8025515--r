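test_that("generators are pure functions of their seed", {
  expect_identical(generateOntology(80, seed = 5),
                   generateOntology(80, seed = 5))
  g <- generateOntology(80, seed = 5)
  expect_identical(generateAnnotations(g, 50, 2, seed = 6),
                   generateAnnotations(g, 50, 2, seed = 6))
  expect_identical(generateSchemes(g, 2, 2, coverage = c(10, 10),
                                   seed = 7),
                   generateSchemes(g, 2, 2, coverage = c(10, 10),
                                   seed = 7))
  expect_identical(generateVersionPair(g, seed = 8),
                   generateVersionPair(g, seed = 8))
  expect_identical(generateExpression(30, 10, c(10), seed = 9),
                   generateExpression(30, 10, c(10), seed = 9))
  expect_identical(
    generatePrognostic(sprintf("g%03d", 1:100), 5, 0.1, seed = 10),
    generatePrognostic(sprintf("g%03d", 1:100), 5, 0.1, seed = 10))
  # different seeds draw different worlds
  expect_false(identical(generateOntology(80, seed = 5),
                         generateOntology(80, seed = 6)))
})

test_that("ontology generator respects structure parameters", {
  one <- generateOntology(1, seed = 1)
  expect_equal(nrow(ontologyTerms(one)), 1)
  expect_equal(nrow(ontologyEdges(one)), 0)
  # mean_parents at the floor: every non-root has exactly one parent
  forest <- generateOntology(60, n_roots = 3, mean_parents = 0,
                             seed = 2)
  expect_equal(nrow(ontologyEdges(forest)), 57)
  expect_false(anyDuplicated(ontologyEdges(forest)$child) > 0)
  expect_error(generateOntology(2, n_roots = 5), "n_roots")
  # generated graphs always validate (acyclic, closed edge set)
  for (s in 1:3)
    expect_s4_class(generateOntology(100, n_roots = 2, seed = s),
                    "OntologyGraph")
})

test_that("annotation generator covers every gene with >= 1 direct term", {
  g <- generateOntology(70, seed = 11)
  ann <- generateAnnotations(g, 120, 2, seed = 12)
  expect_length(annotationEntries(ann), 120)
  expect_true(all(lengths(annotationEntries(ann)) >= 1))
  expect_true(all(unlist(annotationEntries(ann)) %in%
                    ontologyTerms(g)$term_id))
})

test_that("scheme generator hits overlap extremes and coverage masks", {
  g <- generateOntology(400, seed = 13)
  full <- generateSchemes(g, 3, 4, coverage = rep(10, 3),
                          overlap_p = 1, seed = 14)
  sel <- lapply(full$schemes, function(s)
    lapply(schemeSelections(s), sort))
  expect_identical(sel[[1]], sel[[2]][names(sel[[1]])])
  expect_equal(uniqueTermFraction(full$schemes[[1]], full$schemes), 0)
  disj <- generateSchemes(g, 3, 4, coverage = rep(10, 3),
                          overlap_p = 0, seed = 15)
  terms <- lapply(disj$schemes, function(s)
    unique(unlist(schemeSelections(s))))
  expect_length(Reduce(intersect, terms), 0)
  expect_equal(uniqueTermFraction(disj$schemes[[1]], disj$schemes), 100)
  masked <- generateSchemes(g, 2, 3, coverage = c(10, 8), seed = 16)
  expect_length(hallmarksCovered(masked$schemes[[2]]), 8)
  expect_error(generateSchemes(generateOntology(20, seed = 1), 4, 5),
               "pool too small")
})

test_that("version-pair churn is fully recorded and trivial at zero", {
  g <- generateOntology(100, seed = 17)
  none <- generateVersionPair(g, 0, 0, 0, seed = 18)
  expect_identical(ontologyTerms(none$new)$obsolete,
                   ontologyTerms(g)$obsolete)
  expect_identical(ontologyEdges(none$new), ontologyEdges(g))
  vp <- generateVersionPair(g, 0.1, 8, 0.05, seed = 19)
  tr_new <- ontologyTerms(vp$new)
  expect_setequal(tr_new$term_id[tr_new$obsolete], vp$truth$obsoleted)
  expect_true(all(vp$truth$added %in% tr_new$term_id))
  # obsolete terms carry no edges in the new version
  ed <- ontologyEdges(vp$new)
  expect_false(any(ed$child %in% vp$truth$obsoleted |
                     ed$parent %in% vp$truth$obsoleted))
})

test_that("expression generator plants modules at the target correlation", {
  none <- generateExpression(60, 40, integer(), seed = 20)
  expect_true(all(none$labels == 0))
  lab <- detectModules(tomMatrix(adjacencyMatrix(
    preprocessExpression(none$matrix), 6)))
  expect_true(all(lab == 0))   # no structure to find
  # realised within-module correlation near the target
  target <- 0.9
  cors <- vapply(1:5, function(s) {
    ex <- generateExpression(60, 100, c(50), within_cor = target,
                             seed = s)
    lm <- preprocessExpression(ex$matrix)[ex$labels == 1, ]
    cc <- cor(t(lm))
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  expect_lt(abs(mean(cors) - target), 0.05)
})

test_that("prognostic generator plants exact-signature combinations", {
  pool <- sprintf("g%04d", 1:500)
  pr <- generatePrognostic(pool, 5, 0.05,
                           list(list(cancers = 1:2, n = 8)), seed = 21)
  tab <- subgroupPartition(pr$prognostic, min_size = 5, "S")
  expect_setequal(subgroupGenes(tab)[["C01+C02"]],
                  pr$truth[["C01+C02"]])
  expect_length(pr$truth[["C01+C02"]], 8)
  empty <- generatePrognostic(pool, 5, 0, seed = 22)
  expect_length(empty$prognostic, 0)
})

test_that("the assembled world is reproducible and self-consistent", {
  w1 <- syntheticWorld(seed = 101, scale = 0.05)
  w2 <- syntheticWorld(seed = 101, scale = 0.05)
  expect_identical(worldTruth(w1), worldTruth(w2))
  expect_identical(w1@expression$matrix, w2@expression$matrix)
  # marker terms annotate exactly the planted module genes
  mk <- worldTruth(w1)$enriched_terms
  for (m in names(mk)) {
    genes <- names(worldTruth(w1)$modules)[
      worldTruth(w1)$modules == as.integer(m)]
    expect_setequal(
      annotatedGenes(w1@graphOld, w1@annotations$old, mk[[m]]), genes)
  }
  # written world is readable by the pipeline loaders
  dir <- file.path(tempdir(), "worldrt")
  paths <- writeWorld(w1, dir)
  g <- parseOBO(paths[["ontology_old"]])
  expect_equal(nrow(ontologyTerms(g)),
               nrow(ontologyTerms(w1@graphOld)))
  prog <- readPrognosticTSV(paths[["prognostic"]])
  expect_identical(lapply(prog, sort), lapply(w1@prognostic, sort))
})
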