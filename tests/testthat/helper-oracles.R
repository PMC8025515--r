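# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the code paths (and igraph) they verify.

# reflexive-transitive closure by boolean matrix powering;
# returns descendants of `root` (root excluded)
oracle_descendants <- function(edges, nodes, root,
                               relations = c("is_a", "part_of")) {
  ed <- edges[edges$relation %in% relations, , drop = FALSE]
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(ed)) A[cbind(ed$child, ed$parent)] <- TRUE
  R <- diag(TRUE, n); dimnames(R) <- dimnames(A)
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  # descendants of root = nodes that reach root
  setdiff(nodes[R[, root]], root)
}

# per-gene scan: genes with any direct term in {term} + descendants
oracle_annotated <- function(entries, fam) {
  names(entries)[vapply(entries, function(ts) any(ts %in% fam),
                        logical(1))]
}

# per-element membership-signature tally
oracle_signatures <- function(sets) {
  universe <- unique(unlist(sets, use.names = FALSE))
  sig <- vapply(universe, function(el)
    paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "+"), "")
  table(sig)
}

# all-paths Wang oracle: S(t) = max over child->parent paths from anchor
# to t of the product of edge weights; enumerated recursively
oracle_svalues <- function(edges, anchor, weights) {
  S <- new.env(parent = emptyenv())
  assign(anchor, 1, envir = S)
  walk <- function(node, val) {
    up <- edges[edges$child == node &
                edges$relation %in% names(weights), , drop = FALSE]
    for (i in seq_len(nrow(up))) {
      v <- val * weights[[up$relation[i]]]
      p <- up$parent[i]
      cur <- mget(p, envir = S, ifnotfound = -Inf)[[1]]
      if (v > cur) assign(p, v, envir = S)
      walk(p, v)
    }
  }
  walk(anchor, 1)
  unlist(as.list(S))
}

oracle_term_sim <- function(edges, t1, t2, weights) {
  s1 <- oracle_svalues(edges, t1, weights)
  s2 <- oracle_svalues(edges, t2, weights)
  shared <- intersect(names(s1), names(s2))
  if (!length(shared)) return(0)
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

oracle_bma <- function(edges, set1, set2, weights) {
  m <- matrix(0, length(set1), length(set2))
  for (i in seq_along(set1)) for (j in seq_along(set2))
    m[i, j] <- oracle_term_sim(edges, set1[i], set2[j], weights)
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) /
    (length(set1) + length(set2))
}

# triple-loop topological overlap
oracle_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j)
      num <- num + a[i, u] * a[u, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# random small DAG as an edge table (child -> parent), indices increase
# child -> lower-index parents, so acyclic by construction
random_dag_edges <- function(n, mean_parents = 1.3, p_part_of = 0.3) {
  ids <- sprintf("T%03d", seq_len(n))
  ed <- do.call(rbind, lapply(2:n, function(i) {
    np <- min(max(1L, rpois(1, mean_parents)), i - 1L)
    data.frame(child = ids[i],
               parent = ids[sample.int(i - 1L, np)],
               relation = ifelse(runif(np) < p_part_of, "part_of",
                                 "is_a"),
               stringsAsFactors = FALSE)
  }))
  list(ids = ids, edges = ed)
}

dag_as_graph <- function(dag, version = "test") {
  OntologyGraph(version, data.frame(term_id = dag$ids), dag$edges)
}

# small OBO fixture used across ontology tests
obo_fixture <- function() c(
  "format-version: 1.2",
  "data-version: 2020-01-01",
  "",
  "[Term]",
  "id: GO:0000001",
  "name: alpha",
  "namespace: biological_process",
  "",
  "[Term]",
  "id: GO:0000002",
  "name: beta",
  "namespace: biological_process",
  "is_a: GO:0000001 ! alpha",
  "",
  "[Term]",
  "id: GO:0000003",
  "name: gamma",
  "namespace: biological_process",
  "relationship: part_of GO:0000002 ! beta",
  "",
  "[Term]",
  "id: GO:0000004",
  "name: retired",
  "alt_id: GO:0000044",
  "is_obsolete: true",
  "replaced_by: GO:0000002")
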