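test_that("preprocessing log-transforms and removes planted outliers", {
  z <- matrix(0, 4, 6, dimnames = list(paste0("g", 1:4),
                                       paste0("s", 1:6)))
  expect_true(all(preprocessExpression(z) == 0))   # log2(0 + 1) = 0
  set.seed(31)
  m <- matrix(2^rnorm(40 * 20, 5), 40, 20,
              dimnames = list(sprintf("g%02d", 1:40),
                              sprintf("s%02d", 1:20)))
  expect_equal(ncol(preprocessExpression(m)), 20)   # no cut: unchanged
  bad <- m
  bad[, 7] <- 2^rnorm(40, 15)   # one sample far from the rest
  expect_message(out <- preprocessExpression(bad,
                                             outlier_cut_height = 20),
                 "s07")
  expect_equal(setdiff(colnames(bad), colnames(out)), "s07")
})

test_that("scale-free fit and soft-threshold selection behave", {
  # connectivity drawn from an exact power law: near-perfect signed fit
  k <- rep(1:10, times = round(2000 * (1:10)^-2))
  sf <- scaleFreeFit(k)
  expect_gt(sf$fit, 0.95)
  expect_lt(sf$slope, 0)
  # hub-like loadings give a decaying degree distribution already at
  # power 1, so a zero cut accepts the first candidate
  set.seed(33)
  latent <- rnorm(60)
  a_load <- runif(100)^3
  expr <- a_load %o% latent + matrix(rnorm(100 * 60, sd = 0.5), 100, 60)
  dimnames(expr) <- list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:60))
  expect_equal(pickSoftThreshold(expr, r2_cut = 0)$power, 1)
  p1 <- pickSoftThreshold(expr)
  p2 <- pickSoftThreshold(expr)
  expect_equal(p1$power, p2$power)   # deterministic given data
  expect_equal(nrow(p1$table), 20)
})

test_that("adjacency follows |cor|^beta with constant genes dropped", {
  s <- seq_len(10)
  expr <- rbind(up = s, up2 = s * 2 + 3, noise = NA)
  set.seed(35)
  expr["noise", ] <- rnorm(10)
  a <- adjacencyMatrix(expr, 6)
  expect_equal(a["up", "up2"], 1)   # perfect correlation at any power
  expect_lt(a["up", "noise"]^1, 0.3)
  # uncorrelated pair at large beta goes to 0
  expect_lt(adjacencyMatrix(expr, 20)["up", "noise"], 1e-4)
  # 5x5 fixture equals the element-wise formula
  set.seed(36)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  a5 <- adjacencyMatrix(m, 3)
  cc <- abs(cor(t(m)))^3
  diag(cc) <- 0
  expect_equal(a5, cc)
  const <- rbind(m, flat = rep(1, 10))
  expect_warning(ac <- adjacencyMatrix(const, 2), "constant")
  expect_false("flat" %in% rownames(ac))
})

test_that("topological overlap equals the triple-loop oracle", {
  # zero off-diagonal adjacency keeps TOM zero off the diagonal
  z <- matrix(0, 4, 4)
  tz <- tomMatrix(z)
  expect_true(all(tz[upper.tri(tz)] == 0))
  expect_equal(diag(tz), rep(1, 4))
  # hand-computed 3-node value
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.5
  a[1, 3] <- a[3, 1] <- 0.3
  a[2, 3] <- a[3, 2] <- 0.4
  expect_equal(tomMatrix(a)[1, 2], 0.62 / 1.3)
  expect_error(tomMatrix(matrix(runif(9), 3, 3)), "symmetric")
  set.seed(37)
  for (r in 1:3) {
    x <- matrix(runif(400), 20, 20)
    x <- (x + t(x)) / 2
    diag(x) <- 0
    tom <- tomMatrix(x)
    expect_equal(tom, oracle_tom(x), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(tom, t(tom))
  }
})

test_that("module detection recovers block structure and labels by size", {
  block <- function(n, v) {
    m <- matrix(v, n, n); diag(m) <- 0; m
  }
  n1 <- 30; n2 <- 25
  adj <- matrix(0, n1 + n2, n1 + n2)
  adj[1:n1, 1:n1] <- block(n1, 0.8)
  adj[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <- block(n2, 0.8)
  rownames(adj) <- colnames(adj) <- sprintf("g%02d", 1:(n1 + n2))
  lab <- detectModules(tomMatrix(adj), min_module_size = 20)
  expect_equal(sort(unique(lab)), c(1L, 2L))
  expect_equal(sum(lab == 1), n1)   # larger block gets label 1
  expect_equal(sum(lab == 2), n2)
  expect_true(all(lab[1:n1] == 1))
  # identical profiles collapse into a single module
  one <- matrix(1, 25, 25); diag(one) <- 0
  rownames(one) <- colnames(one) <- paste0("g", 1:25)
  expect_equal(unique(detectModules(tomMatrix(one),
                                    min_module_size = 20)), 1L)
  # clusters below min size stay unassigned
  lab2 <- detectModules(tomMatrix(adj), min_module_size = 40)
  expect_true(all(lab2 == 0))
})

test_that("hub ranking extends through ties and ignores input order", {
  # star adjacency with a tie at the 5th connectivity value
  n <- 7
  a <- matrix(0, n, n,
              dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  w <- c(0.9, 0.8, 0.7, 0.3, 0.3, 0.1)
  for (j in 2:n) a[1, j] <- a[j, 1] <- w[j - 1]
  lab <- setNames(rep(1L, n), rownames(a))
  hb <- hubGenes(a, lab, n = 5)
  expect_length(hb$hubs[["1"]], 6)   # two genes tie at rank 5
  expect_setequal(hb$hubs[["1"]], c("g1", "g2", "g3", "g4", "g5",
                                    "g6"))
  # module of exactly n genes: all are hubs (with a warning)
  small <- a[1:5, 1:5]
  expect_warning(hb2 <- hubGenes(small, setNames(rep(1L, 5),
                                                 rownames(small))),
                 "all returned")
  expect_length(hb2$hubs[["1"]], 5)
  # brute force on a random fixture + permutation invariance
  set.seed(41)
  m <- matrix(runif(900), 30, 30)
  m <- (m + t(m)) / 2; diag(m) <- 0
  rownames(m) <- colnames(m) <- sprintf("g%02d", 1:30)
  labs <- setNames(rep(1:2, each = 15), rownames(m))
  hb3 <- hubGenes(m, labs, n = 5)
  for (mod in c("1", "2")) {
    genes <- names(labs)[labs == as.integer(mod)]
    k <- rowSums(m[genes, genes])
    thr <- sort(k, decreasing = TRUE)[5]
    expect_setequal(hb3$hubs[[mod]], names(k)[k >= thr])
  }
  perm <- sample(rownames(m))
  hb4 <- hubGenes(m[perm, perm], labs[perm], n = 5)
  expect_setequal(hb4$hubs[["1"]], hb3$hubs[["1"]])
})

test_that("hypergeometric enrichment matches closed forms and the null", {
  g <- OntologyGraph("t",
    data.frame(term_id = c("ROOT", "T1", "T2"),
               namespace = "biological_process"),
    data.frame(child = c("T1", "T2"), parent = "ROOT",
               relation = "is_a"))
  bg <- sprintf("g%02d", 1:10)
  ann <- AnnotationTable(data.frame(
    gene_id = c(bg, bg[1:5]),
    term_id = c(rep("T2", 10), rep("T1", 5))), g)
  # a term annotating the whole background is never enriched
  e <- enrichModule(bg[1:3], bg, g, ann)
  expect_equal(e$p_raw[e$term_id == "T2"], 1)
  # N=10, K=5, n=3, k=3 -> C(5,3)/C(10,3) = 10/120
  expect_equal(e$p_raw[e$term_id == "T1"], 10 / 120)
  expect_equal(e$k[e$term_id == "T1"], 3)
  expect_error(enrichModule("g01", character(), g, ann), "background")
  # p-values are (super-)uniform under random module membership
  set.seed(43)
  big_bg <- sprintf("G%04d", 1:1000)
  ann2 <- AnnotationTable(data.frame(gene_id = big_bg[1:300],
                                     term_id = "T1"), g)
  p <- replicate(200, {
    mod <- sample(big_bg, 100)
    ee <- enrichModule(mod, big_bg, g, ann2)
    if ("T1" %in% ee$term_id) ee$p_raw[ee$term_id == "T1"] else 1
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the assembled co-expression stage recovers planted modules", {
  ex <- generateExpression(120, 80, c(40, 40), within_cor = 0.8,
                           seed = 47)
  cx <- runCoexpression(ex$matrix, beta = 6)
  expect_s4_class(cx, "CoexpressionResult")
  lab <- moduleLabels(cx)
  # planted modules map one-to-one onto detected ones
  expect_equal(length(unique(lab[ex$labels == 1])), 1)
  expect_equal(length(unique(lab[ex$labels == 2])), 1)
  expect_length(hubGeneList(cx), 2)
})
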