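# Shared internal helpers.

# Half-up rounding (R's round() is round-half-even); used for report
# percentages quoted to one decimal.
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stable key for a set of labels (order-insensitive).
comboKey <- function(x) paste(sort(unique(x)), collapse = "+")

# Locate one directed cycle in an edge table (child -> parent) for error
# reporting; returns the node sequence of the first cycle found.
.find_cycle <- function(edges) {
  adj <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character()
  cyc <- NULL
  visit <- function(v) {
    if (!is.null(cyc)) return()
    st <- mget(v, envir = state, ifnotfound = "white")[[1]]
    if (st == "grey") {
      i <- match(v, path)
      cyc <<- c(path[i:length(path)], v)
      return()
    }
    if (st == "black") return()
    assign(v, "grey", envir = state)
    path <<- c(path, v)
    for (w in adj[[v]]) visit(w)
    path <<- path[-length(path)]
    assign(v, "black", envir = state)
  }
  for (v in unique(edges$child)) {
    visit(v)
    if (!is.null(cyc)) break
  }
  if (is.null(cyc)) "<none>" else cyc
}

# Build an igraph (edges child -> parent) over the active (non-obsolete)
# part of an OntologyGraph, restricted to the given relation types.
# Every active term is present as a vertex even if isolated.
ontoIgraph <- function(graph, relations = c("is_a", "part_of")) {
  active <- graph@terms$term_id[!graph@terms$obsolete]
  ed <- graph@edges[graph@edges$relation %in% relations, , drop = FALSE]
  igraph::graph_from_data_frame(ed[, c("child", "parent")],
                                directed = TRUE,
                                vertices = data.frame(name = active))
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stream
# name, so each generator owns an independent named substream.
subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Evaluate an expression under a locally-seeded RNG without disturbing the
# caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
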