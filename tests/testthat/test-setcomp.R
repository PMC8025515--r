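mk_scheme <- function(id, ...) {
  sel <- list(...)
  loadScheme(data.frame(hallmark = rep(names(sel), lengths(sel)),
                        term_id = unlist(sel, use.names = FALSE)), id)
}

test_that("term selection frequency counts schemes, not hallmark slots", {
  s1 <- mk_scheme("GO1", "resisting cell death" = c("GO:1", "GO:2"),
                  "inducing angiogenesis" = "GO:1")
  s2 <- mk_scheme("GO2", "resisting cell death" = "GO:1")
  freq <- termSelectionFrequency(list(s1, s2))
  # GO:1 appears in two hallmarks of GO1 but counts once per scheme
  expect_equal(freq$overall[["GO:1"]], 2)
  expect_equal(freq$overall[["GO:2"]], 1)
  expect_equal(freq$perHallmark[["resisting cell death"]][["GO:1"]], 2)
  expect_equal(freq$perHallmark[["inducing angiogenesis"]][["GO:1"]], 1)
  expect_error(termSelectionFrequency(list(s1)), "at least 2")
})

test_that("unique-term fractions hit the 0/100 extremes and ignore order", {
  a <- mk_scheme("A", "resisting cell death" = c("GO:1", "GO:2"))
  b <- mk_scheme("B", "resisting cell death" = c("GO:1", "GO:2"))
  c_ <- mk_scheme("C", "resisting cell death" = c("GO:8", "GO:9"))
  expect_equal(uniqueTermFraction(a, list(a, b)), 0)
  expect_equal(uniqueTermFraction(c_, list(a, b, c_)), 100)
  # a 1-of-3 case with one decimal, half-up
  d <- mk_scheme("D", "resisting cell death" = c("GO:1", "GO:3",
                                                 "GO:4"))
  expect_equal(uniqueTermFraction(d, list(a, d)), 66.7)
  expect_equal(uniqueTermFraction(d, list(d, a)), 66.7)  # order
  expect_error(uniqueTermFraction(
    new("MappingScheme", schemeId = "Z", sourceKind = "ontology_terms",
        selections = list(), genes = character(), pathways = list()),
    list(a, b)), "no terms")
})

test_that("consensus terms are hallmark-scoped with a tunable threshold", {
  schemes <- list(
    mk_scheme("S1", "resisting cell death" = "GO:1",
              "inducing angiogenesis" = "GO:7"),
    mk_scheme("S2", "resisting cell death" = "GO:1",
              "inducing angiogenesis" = "GO:9"),
    mk_scheme("S3", "resisting cell death" = "GO:1"),
    mk_scheme("S4", "inducing angiogenesis" = "GO:1"),
    mk_scheme("S5", "resisting cell death" = "GO:2"))
  cons <- consensusTerms(schemes, 3)
  # GO:1 selected for resisting cell death by exactly 3 schemes
  expect_equal(cons$perHallmark[["resisting cell death"]], "GO:1")
  # its 4th selection was for a different hallmark: no accumulation
  expect_length(cons$perHallmark[["inducing angiogenesis"]], 0)
  expect_equal(cons$overall, "GO:1")
  expect_equal(cons$nUnique, 1)
  # threshold 1 returns all selected terms; threshold n the shared core
  all_terms <- consensusTerms(schemes, 1)
  expect_setequal(all_terms$overall, c("GO:1", "GO:2", "GO:7", "GO:9"))
  core <- consensusTerms(schemes, 5)
  expect_length(core$overall, 0)
  expect_error(consensusTerms(schemes, 6), "exceeds")
  # a term consensus in two hallmarks counts once in nUnique, twice in
  # the per-hallmark total
  sch2 <- lapply(1:3, function(i)
    mk_scheme(paste0("T", i), "resisting cell death" = "GO:5",
              "inducing angiogenesis" = "GO:5"))
  c2 <- consensusTerms(sch2, 3)
  expect_equal(c2$nUnique, 1)
  expect_equal(c2$nPerHallmarkTotal, 2)
})

test_that("pathway-to-term conversion lets a pathway scheme join consensus", {
  pw <- loadPathwayScheme(data.frame(gene_id = c("a", "b")), "PW1")
  conv <- convertPathwayScheme(pw, data.frame(
    hallmark = "resisting cell death", term_id = c("GO:1", "GO:2")))
  expect_equal(schemeKind(conv), "ontology_terms")
  expect_equal(schemeId(conv), "PW1")
  expect_setequal(schemeSelections(conv)[["resisting cell death"]],
                  c("GO:1", "GO:2"))
})

test_that("exclusive intersections partition the union (oracle check)", {
  p <- exclusiveIntersections(list(A = c("1", "2"), B = c("2", "3")))
  expect_setequal(p$combo, c("A", "B", "A+B"))
  expect_equal(p$n[p$combo == "A+B"], 1)
  expect_equal(p$elements[p$combo == "A"][[1]], "1")
  ident <- exclusiveIntersections(list(X = c("1", "2"),
                                       Y = c("1", "2")))
  expect_equal(ident$combo, "X+Y")
  expect_equal(ident$n, 2)
  set.seed(99)
  for (r in 1:5) {
    sets <- lapply(1:5, function(i)
      sample(sprintf("g%04d", 1:2000), 1000))
    names(sets) <- LETTERS[1:5]
    prof <- exclusiveIntersections(sets)
    orc <- oracle_signatures(sets)
    expect_equal(sum(prof$n), length(unique(unlist(sets))))
    got <- setNames(prof$n, prof$combo)
    expect_equal(got[names(orc)], setNames(as.integer(orc),
                                           names(orc)))
  }
})

test_that("per-hallmark gene comparison drops absent schemes", {
  mk_gs <- function(id, genes) {
    new("HallmarkGeneSets", schemeId = id,
        perHallmark = list("resisting cell death" = genes),
        union = genes,
        skipped = data.frame(hallmark = character(),
                             term_id = character(),
                             reason = character()))
  }
  gs <- list(mk_gs("GO1", c("a", "b")), mk_gs("GO3", c("a", "b")),
             mk_gs("GO4", character()))
  prof <- perHallmarkGeneComparison(gs, "Resisting Cell Death")
  # GO4 has no genes for this hallmark: omitted entirely
  expect_false(any(grepl("GO4", prof$combo)))
  # identical sets leave no exclusive single-scheme cells
  expect_equal(prof$combo, "GO1+GO3")
})
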