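test_that("parseOBO transcribes stanzas, flags obsoletes, rejects cycles", {
  g <- parseOBO(obo_fixture())
  expect_equal(ontologyVersion(g), "2020-01-01")
  tr <- ontologyTerms(g)
  expect_setequal(tr$term_id,
                  c("GO:0000001", "GO:0000002", "GO:0000003",
                    "GO:0000004"))
  ed <- ontologyEdges(g)
  expect_equal(nrow(ed), 2)
  expect_equal(ed$relation[ed$child == "GO:0000002"], "is_a")
  expect_equal(ed$relation[ed$child == "GO:0000003"], "part_of")
  # obsolete term: flagged, replacement recorded, no edges
  ob <- tr[tr$term_id == "GO:0000004", ]
  expect_true(ob$obsolete)
  expect_equal(ob$replaced_by, "GO:0000002")
  expect_equal(ob$alt_ids, "GO:0000044")
  expect_false("GO:0000004" %in% c(ed$child, ed$parent))
  # cycle A is_a B, B is_a A
  expect_error(parseOBO(c("[Term]", "id: A", "is_a: B",
                          "[Term]", "id: B", "is_a: A")),
               "cycle")
  # malformed stanza names the line
  expect_error(parseOBO(c("[Term]", "id: A", "not a tag line")),
               "line 3")
})

test_that("descendant closure matches chain, leaf and matrix-power oracle", {
  chain <- OntologyGraph("t",
    data.frame(term_id = c("A", "B", "C")),
    data.frame(child = c("C", "B"), parent = c("B", "A"),
               relation = "is_a"))
  expect_setequal(descendants(chain, "A", "is_a"), c("B", "C"))
  expect_length(descendants(chain, "C"), 0)   # leaf
  expect_error(descendants(chain, "Z"), "unknown term")
  obo <- parseOBO(obo_fixture())
  expect_error(descendants(obo, "GO:0000004"), "obsolete")
  set.seed(42)
  for (i in 1:5) {
    dag <- random_dag_edges(50)
    g <- dag_as_graph(dag)
    root <- dag$ids[1]
    expect_setequal(descendants(g, root),
                    oracle_descendants(dag$edges, dag$ids, root))
    # relation-restricted closure agrees too
    expect_setequal(descendants(g, root, "is_a"),
                    oracle_descendants(dag$edges, dag$ids, root,
                                       "is_a"))
  }
})

test_that("descendants is monotone under edge addition", {
  set.seed(7)
  dag <- random_dag_edges(30)
  g <- dag_as_graph(dag)
  before <- lapply(dag$ids, descendants, graph = g)
  # add an edge between two previously unrelated nodes (child index
  # higher, keeping the DAG)
  extra <- data.frame(child = dag$ids[25], parent = dag$ids[3],
                      relation = "is_a")
  g2 <- dag_as_graph(list(ids = dag$ids,
                          edges = unique(rbind(dag$edges, extra))))
  after <- lapply(dag$ids, descendants, graph = g2)
  for (i in seq_along(dag$ids))
    expect_true(all(before[[i]] %in% after[[i]]))
})

test_that("true-path annotation queries match the per-gene scan oracle", {
  chain <- OntologyGraph("t",
    data.frame(term_id = c("A", "B", "C")),
    data.frame(child = c("C", "B"), parent = c("B", "A"),
               relation = "is_a"))
  ann <- AnnotationTable(data.frame(gene_id = "g", term_id = "C"),
                         chain)
  expect_true("g" %in% annotatedGenes(chain, ann, "A"))
  expect_length(annotatedGenes(chain, ann, "B"), 1)
  # term with nothing annotated at or below it
  lone <- OntologyGraph("t", data.frame(term_id = c("A", "X")),
                        data.frame(child = "X", parent = "A",
                                   relation = "is_a"))
  ann2 <- AnnotationTable(data.frame(gene_id = "g", term_id = "A"),
                          lone)
  expect_length(annotatedGenes(lone, ann2, "X"), 0)
  # 200-gene / 100-term fixture vs oracle
  set.seed(11)
  dag <- random_dag_edges(100)
  g <- dag_as_graph(dag)
  ann3 <- generateAnnotations(g, 200, 2, seed = 12)
  for (t in sample(dag$ids, 10)) {
    fam <- c(t, oracle_descendants(dag$edges, dag$ids, t))
    expect_setequal(annotatedGenes(g, ann3, t),
                    oracle_annotated(annotationEntries(ann3), fam))
  }
  # union over roots covers every annotated gene with known terms
  roots <- setdiff(dag$ids, dag$edges$child)
  covered <- unique(unlist(lapply(roots, annotatedGenes, graph = g,
                                  annotations = ann3)))
  expect_setequal(covered, names(annotationEntries(ann3)))
})

test_that("first-neighbour subgraph equals the adjacency-list oracle", {
  chain <- OntologyGraph("t",
    data.frame(term_id = c("A", "B", "C")),
    data.frame(child = c("C", "B"), parent = c("B", "A"),
               relation = "is_a"))
  sub <- firstNeighborSubgraph(chain, "B")
  expect_setequal(ontologyTerms(sub)$term_id, c("A", "B", "C"))
  expect_equal(nrow(ontologyEdges(sub)), 2)
  iso <- OntologyGraph("t", data.frame(term_id = c("A", "B")),
                       data.frame(child = "B", parent = "A",
                                  relation = "is_a"))
  iso2 <- OntologyGraph("t", data.frame(term_id = c("A", "B", "Z")),
                        data.frame(child = "B", parent = "A",
                                   relation = "is_a"))
  sub_iso <- firstNeighborSubgraph(iso2, "Z")
  expect_equal(ontologyTerms(sub_iso)$term_id, "Z")
  expect_equal(nrow(ontologyEdges(sub_iso)), 0)
  expect_warning(firstNeighborSubgraph(iso, character()), "empty seed")
  expect_warning(firstNeighborSubgraph(iso2, c("B", "NOPE")),
                 "not in graph")
  set.seed(5)
  dag <- random_dag_edges(50)
  g <- dag_as_graph(dag)
  seeds <- sample(dag$ids, 5)
  ed <- dag$edges
  expected <- unique(c(seeds, ed$parent[ed$child %in% seeds],
                       ed$child[ed$parent %in% seeds]))
  sub <- firstNeighborSubgraph(g, seeds)
  expect_setequal(ontologyTerms(sub)$term_id, expected)
  # edges between retained nodes only, all retained
  keep <- ed$child %in% expected & ed$parent %in% expected
  expect_equal(nrow(ontologyEdges(sub)), sum(keep))
})

test_that("serialisation round trips preserve terms and edges", {
  g <- parseOBO(obo_fixture())
  g2 <- parseOBO(writeOBO(g))
  expect_setequal(ontologyTerms(g2)$term_id, ontologyTerms(g)$term_id)
  ek <- function(x) paste(ontologyEdges(x)$child, ontologyEdges(x)$parent,
                          ontologyEdges(x)$relation)
  expect_setequal(ek(g2), ek(g))
  expect_equal(ontologyTerms(g2)$obsolete[
    ontologyTerms(g2)$term_id == "GO:0000004"], TRUE)
  # node/edge TSV round trip
  nf <- tempfile(); ef <- tempfile()
  writeGraphTSV(g, nf, ef)
  g3 <- readGraphTSV(ontologyVersion(g), nf, ef)
  expect_setequal(ek(g3), ek(g))
  expect_equal(sort(ontologyTerms(g3)$term_id),
               sort(ontologyTerms(g)$term_id))
})

test_that("written OBO agrees with an independent OBO reader", {
  g <- generateOntology(60, n_roots = 2, seed = 9)
  f <- tempfile(fileext = ".obo")
  writeOBO(g, f)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import obonet\n",
    "g = obonet.read_obo(\"", f, "\")\n",
    "print(len(g.nodes))\n",
    "for c, p, k in sorted(g.edges(keys=True)):\n",
    "    print(c, p, k)\n"))), stdout = TRUE, stderr = FALSE))
  expect_equal(as.integer(out[1]), sum(!ontologyTerms(g)$obsolete))
  ed <- ontologyEdges(g)
  expect_identical(sort(out[-1]),
                   sort(paste(ed$child, ed$parent, ed$relation)))
})

test_that("annotation readers handle 2-column TSV and GAF subsets", {
  g <- parseOBO(obo_fixture())
  tf <- tempfile()
  writeLines(c("gene_id\tterm_id", "g1\tGO:0000003", "g2\tGO:0000002"),
             tf)
  ann <- readAnnotationsTSV(tf, g)
  expect_setequal(names(annotationEntries(ann)), c("g1", "g2"))
  gaf <- tempfile()
  writeLines(c("!gaf-version: 2.1",
               paste("DB", "g1", "SYM", "", "GO:0000003", "REF", "IEA",
                     sep = "\t"),
               paste("DB", "g3", "SYM", "", "GO:0000001", "REF", "IEA",
                     sep = "\t")), gaf)
  ann2 <- readGAF(gaf, g)
  expect_setequal(names(annotationEntries(ann2)), c("g1", "g3"))
  expect_equal(annotationEntries(ann2)$g3, "GO:0000001")
  # unknown term flagged
  tf2 <- tempfile()
  writeLines(c("gene_id\tterm_id", "g1\tGO:9999999"), tf2)
  expect_warning(readAnnotationsTSV(tf2, g), "unknown")
})
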