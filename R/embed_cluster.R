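#' Select the most variable genes
#'
#' The `n` genes with highest variance of normalized expression, ties broken
#' by gene order in the matrix (earlier wins).
#'
#' @param normalized genes x cells normalized matrix.
#' @param n number of genes to select.
#' @return character vector of gene names, in decreasing-variance order.
#' @export
select_variable_genes <- function(normalized, n = 400L) {
  if (n > nrow(normalized))
    stop_config("n (%d) exceeds the number of genes (%d)", n, nrow(normalized))
  v <- row_vars_sparse(normalized)
  ord <- order(-v, seq_along(v))
  rownames(normalized)[ord[seq_len(n)]]
}

#' Marker weights for the weighted embedding
#'
#' @param weights named numeric vector of per-gene weights (>= 0; 0 excludes
#'   the gene from the embedding).
#' @param default_weight weight for genes not listed.
#' @return function of a gene-name vector returning weights.
#' @export
marker_weights <- function(weights = numeric(0), default_weight = 1) {
  if (length(weights) && (is.null(names(weights)) || any(weights < 0)))
    stop_config("weights must be a named non-negative vector")
  function(genes) {
    w <- rep(default_weight, length(genes))
    hit <- match(genes, names(weights))
    w[!is.na(hit)] <- weights[hit[!is.na(hit)]]
    setNames(w, genes)
  }
}

#' Marker-weighted principal component embedding
#'
#' Each feature's (centered, scaled) row is multiplied by its weight before
#' a singular value decomposition; cell scores for the leading components
#' are returned.  With unit weights this is ordinary PCA of the feature set.
#' Component signs are fixed so the loading of largest magnitude is
#' positive, making scores reproducible rather than sign-ambiguous.
#'
#' @param scaled dense genes x cells matrix from [scale_genes()].
#' @param features feature set to embed (typically the union of weighted
#'   markers and the most variable genes); must all be present.
#' @param weights a [marker_weights()] function, a named vector, or `NULL`
#'   for unit weights.
#' @param n_pcs number of components to keep.
#' @return list of class `wpca`: `scores` (cells x n_pcs), `loadings`
#'   (features x n_pcs), `sdev`, `var_share`, `weights`.
#' @export
weighted_pca <- function(scaled, features = rownames(scaled), weights = NULL,
                         n_pcs = 10L) {
  if (length(features) == 0) stop_config("empty feature set")
  miss <- setdiff(features, rownames(scaled))
  if (length(miss))
    stop_config("features absent from the matrix: %s",
                paste(head(miss, 5), collapse = ", "))
  wfun <- if (is.function(weights)) weights
          else if (is.null(weights)) marker_weights()
          else marker_weights(weights)
  w <- wfun(features)
  x <- scaled[features, , drop = FALSE] * w
  x <- x - rowMeans(x)     # weighting preserves centering, but be safe
  n_pcs <- min(n_pcs, nrow(x), ncol(x) - 1L)
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  d <- sv$d[seq_len(n_pcs)]
  flip <- vapply(seq_len(n_pcs), function(k) {
    u <- sv$u[, k]
    if (u[which.max(abs(u))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(sv$u, 2, flip, "*")
  scores <- sweep(sv$v, 2, d * flip, "*")
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(n_pcs)))
  dimnames(loadings) <- list(features, paste0("PC", seq_len(n_pcs)))
  structure(list(scores = scores, loadings = loadings,
                 sdev = d / sqrt(max(ncol(x) - 1, 1)),
                 var_share = sv$d^2 / sum(sv$d^2),
                 weights = w),
            class = "wpca")
}

#' k-nearest-neighbor graph in embedding space
#'
#' Each cell is connected to its `k` Euclidean nearest neighbors among the
#' embedding coordinates; the directed kNN relation is symmetrized by
#' union.  Distance ties are broken by cell index.
#'
#' @param embedding cells x dims matrix (e.g. `wpca$scores`) or a `wpca`.
#' @param k number of neighbors.
#' @return undirected simple `igraph` with vertex names from rownames.
#' @export
knn_graph <- function(embedding, k = 20L) {
  if (inherits(embedding, "wpca")) embedding <- embedding$scores
  x <- as.matrix(embedding)
  n <- nrow(x)
  if (k >= n) stop_config("k (%d) must be smaller than the cell count (%d)", k, n)
  sq <- rowSums(x^2)
  edges <- vector("list", ceiling(n / 512))
  bi <- 0L
  for (start in seq(1L, n, by = 512L)) {
    idx <- start:min(start + 511L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * x[idx, , drop = FALSE] %*% t(x)
    res <- apply(d2, 1, function(row) {
      order(row)[2:(k + 1L)]        # order() breaks ties by index; drop self
    })
    nb <- t(matrix(res, nrow = k))  # apply() drops dims when k == 1
    # guard: if duplicated coordinates put self beyond position 1
    for (r in seq_along(idx)) {
      if (idx[r] %in% nb[r, ]) {
        o <- order(d2[r, ])
        nb[r, ] <- setdiff(o, idx[r])[seq_len(k)]
      }
    }
    bi <- bi + 1L
    edges[[bi]] <- cbind(rep(idx, each = k), as.vector(t(nb)))
  }
  e <- do.call(rbind, edges)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- rownames(x) %||% as.character(seq_len(n))
  g
}

#' Louvain community detection on a neighbor graph
#'
#' Modularity-based multilevel (Louvain) clustering at the given
#' resolution.  Deterministic given the seed; labels are consecutive
#' integers starting at 0 ordered by decreasing cluster size (ties by first
#' occurrence).
#'
#' @param graph undirected `igraph` (e.g. from [knn_graph()]).
#' @param resolution modularity resolution parameter.
#' @param seed RNG seed.
#' @return integer vector of 0-based cluster labels named by vertex.
#' @export
cluster_graph <- function(graph, resolution = 1.5, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop_config("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord) - 1L, names(sizes)[ord])
  out <- relabel[as.character(memb)]
  setNames(as.integer(out), igraph::V(graph)$name)
}

#' Per-cluster mean expression (pseudobulk)
#'
#' @param normalized genes x cells normalized matrix.
#' @param labels cluster labels, named by cell or aligned with columns.
#' @return clusters x genes matrix of arithmetic means.
#' @export
pseudobulk <- function(normalized, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(normalized)]
  if (anyNA(labels)) stop_config("every cell must be labelled")
  labs <- sort(unique(labels))
  out <- t(vapply(labs, function(l)
    Matrix::rowMeans(normalized[, labels == l, drop = FALSE]),
    numeric(nrow(normalized))))
  rownames(out) <- as.character(labs)
  out
}
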