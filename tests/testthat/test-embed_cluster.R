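test_that("variable gene selection orders by variance with stable ties", {
  m <- matrix(0, 5, 4, dimnames = list(c("a", "b", "c", "d", "e"),
                                       sprintf("c%d", 1:4)))
  m[1, ] <- c(0, 8, 0, 8)   # high variance
  m[2, ] <- c(0, 4, 0, 4)
  m[3, ] <- c(0, 2, 0, 2)
  m[4, ] <- c(0, 1, 0, 1)
  m[5, ] <- 3               # constant
  sm <- Matrix::Matrix(m, sparse = TRUE)
  expect_identical(select_variable_genes(sm, 2), c("a", "b"))
  # a constant gene is never selected while non-constant genes remain
  expect_false("e" %in% select_variable_genes(sm, 4))
  # exact tie at the boundary: earlier gene order wins
  m2 <- m; m2[4, ] <- m2[3, ]
  expect_identical(select_variable_genes(Matrix::Matrix(m2, sparse = TRUE), 3),
                   c("a", "b", "c"))
  expect_error(select_variable_genes(sm, 6), "exceeds")
})

make_scaled_toy <- function(n_genes = 30, n_cells = 40, seed = 2) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_cells), n_genes, n_cells,
              dimnames = list(sprintf("g%d", seq_len(n_genes)),
                              sprintf("c%d", seq_len(n_cells))))
  m - rowMeans(m)
}

test_that("unit weights reproduce unweighted PCA up to sign", {
  x <- make_scaled_toy()
  w1 <- weighted_pca(x, rownames(x), NULL, n_pcs = 5)
  pr <- prcomp(t(x), center = TRUE, scale. = FALSE)
  expect_equal(w1$sdev, pr$sdev[1:5], tolerance = 1e-8)
  for (k in 1:5)
    expect_equal(unname(abs(w1$scores[, k])), unname(abs(pr$x[, k])),
                 tolerance = 1e-8)
})

test_that("zero-weight genes are equivalent to excluding them", {
  x <- make_scaled_toy(seed = 3)
  w0 <- marker_weights(c(g1 = 0))
  a <- weighted_pca(x, rownames(x), w0, n_pcs = 4)
  b <- weighted_pca(x, setdiff(rownames(x), "g1"), NULL, n_pcs = 4)
  expect_equal(a$sdev, b$sdev, tolerance = 1e-8)
  for (k in 1:4)
    expect_equal(abs(a$scores[, k]), abs(b$scores[, k]), tolerance = 1e-8)
})

test_that("a doubled feature row equals weight two on that feature", {
  x <- make_scaled_toy(n_genes = 3, n_cells = 6, seed = 4)
  a <- weighted_pca(x, rownames(x), marker_weights(c(g1 = 2)), n_pcs = 2)
  x2 <- x; x2["g1", ] <- 2 * x2["g1", ]
  sv <- svd(x2 - rowMeans(x2))
  expect_equal(a$sdev * sqrt(ncol(x) - 1), sv$d[1:2], tolerance = 1e-8)
  scores_oracle <- sweep(sv$v[, 1:2], 2, sv$d[1:2], "*")
  for (k in 1:2)
    expect_equal(unname(abs(a$scores[, k])), abs(scores_oracle[, k]),
                 tolerance = 1e-8)
})

test_that("pca scores are invariant to cell order", {
  x <- make_scaled_toy(seed = 5)
  perm <- sample(ncol(x))
  a <- weighted_pca(x, rownames(x), NULL, n_pcs = 3)
  b <- weighted_pca(x[, perm], rownames(x), NULL, n_pcs = 3)
  expect_equal(abs(b$scores), abs(a$scores[perm, ]), tolerance = 1e-8)
  expect_error(weighted_pca(x, character(0)), "empty feature")
})

test_that("knn graph matches hand geometry on collinear points", {
  emb <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "PC1"))
  g <- knn_graph(emb, k = 1)
  deg <- igraph::degree(g)
  expect_identical(unname(deg[c("a", "b", "c")]), c(1, 2, 1))
  # duplicated coordinates are mutual nearest neighbors
  emb2 <- matrix(c(0, 0, 5), 3, 1, dimnames = list(c("a", "b", "c"), "PC1"))
  g2 <- knn_graph(emb2, k = 1)
  expect_true(igraph::are_adjacent(g2, "a", "b"))
  # saturation: k = n-1 yields the complete graph
  emb3 <- matrix(rnorm(10), 5, 2,
                 dimnames = list(sprintf("p%d", 1:5), c("x", "y")))
  g3 <- knn_graph(emb3, k = 4)
  expect_identical(igraph::ecount(g3), choose(5, 2))
  expect_error(knn_graph(emb3, k = 5), "smaller")
})

test_that("two cliques joined by one edge split into two communities", {
  # modularity optimum for two K6 cliques with a single bridge is the
  # two-clique partition (verifiable by enumeration at this size)
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(6)
  g <- igraph::add_edges(g, c(1, 7))
  igraph::V(g)$name <- sprintf("v%d", 1:12)
  cl <- cluster_graph(g, resolution = 1, seed = 1)
  expect_identical(length(unique(cl)), 2L)
  expect_identical(length(unique(cl[1:6])), 1L)
  expect_identical(length(unique(cl[7:12])), 1L)
  # a single clique stays one cluster
  k <- igraph::make_full_graph(8)
  igraph::V(k)$name <- sprintf("v%d", 1:8)
  expect_identical(length(unique(cluster_graph(k, 1, seed = 1))), 1L)
})

test_that("cluster labels are 0-based and ordered by decreasing size", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(9)
  igraph::V(g)$name <- sprintf("v%d", 1:14)
  cl <- cluster_graph(g, resolution = 1, seed = 1)
  expect_identical(sort(unique(cl)), c(0L, 1L))
  expect_identical(unname(table(cl)[["0"]]), 9L)
  # same seed is reproducible
  expect_identical(cl, cluster_graph(g, resolution = 1, seed = 1))
})

test_that("pseudobulk equals a brute-force group-by mean", {
  set.seed(7)
  m <- Matrix::Matrix(matrix(rpois(200, 3), 10, 20,
                             dimnames = list(sprintf("g%d", 1:10),
                                             sprintf("c%d", 1:20))),
                      sparse = TRUE)
  labels <- setNames(sample(c("A", "B", "C"), 20, replace = TRUE),
                     colnames(m))
  pb <- pseudobulk(m, labels)
  for (l in c("A", "B", "C")) for (g in rownames(m)) {
    expect_equal(pb[l, g], mean(m[g, names(labels)[labels == l]]))
  }
  # cluster of identical cells reproduces the cell profile
  m2 <- m; m2[, labels == "A"] <- m[, which(labels == "A")[1]]
  pb2 <- pseudobulk(m2, labels)
  expect_equal(unname(pb2["A", ]), unname(m2[, which(labels == "A")[1]]))
})

test_that("clustering recovers well-separated compartments", {
  sf <- matrix(0, 5, 6, dimnames = list(c("CD4", "CD8", "DN", "DP", "GD"),
                                        c("naive", "effector", "memory",
                                          "SLEC", "Pexh", "Texh")))
  sf[, "effector"] <- 1
  panel <- default_marker_panel()
  panel$log2_fold[panel$level == "compartment"] <- 3
  cfg <- sim_config(n_samples = 2, cells_per_sample = 400,
                    disease_of_sample = c(S1 = "diabetic", S2 = "diabetic"),
                    compartment_fractions = c(CD4 = 0.3, CD8 = 0.3, DN = 0.3,
                                              DP = 0, GD = 0.1),
                    state_fractions = sf, marker_panel = panel,
                    dropout_rate = 0.02, shared_clone_count = 10, seed = 11)
  co <- generate_cohort(cfg)
  norm <- normalize_cp10k_log(filter_cells(co$counts)$counts)
  lineage <- c("Cd4", "Cd8a", "Cd8b1", "Trgv2")
  features <- union(lineage, select_variable_genes(norm, 400))
  scaled <- scale_genes(norm, features)
  emb <- weighted_pca(scaled, features,
                      marker_weights(setNames(rep(5, 4), lineage)), n_pcs = 10)
  cl <- cluster_graph(knn_graph(emb$scores, k = 20), resolution = 1.5, seed = 1)
  truth <- co$truth$cells$compartment[match(colnames(norm),
                                            co$truth$cells$cell_id)]
  expect_gte(mclust::adjustedRandIndex(cl, truth), 0.8)
})
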