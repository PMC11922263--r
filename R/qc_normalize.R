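#' Quality-control parameters
#'
#' Thresholds for the cell and gene filters: a CD3 positivity requirement,
#' detected-feature bounds, a mitochondrial-fraction ceiling, housekeeping
#' detection, and a minimum number of cells per retained gene.
#'
#' @param min_cells_per_gene genes must be detected in at least this many
#'   retained cells.
#' @param min_features,max_features detected-feature bounds per cell.
#' @param cd3_gene gene whose count must exceed zero (`NULL` disables).
#' @param housekeeping_genes at least one must have count > 0 (`NULL`
#'   disables).
#' @param max_mito_fraction ceiling on the mitochondrial count fraction.
#' @param mito_prefix rowname prefix identifying mitochondrial genes.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_cells_per_gene = 3L,
                      min_features = 200L,
                      max_features = 5000L,
                      cd3_gene = "Cd3e",
                      housekeeping_genes = c("Actb", "B2m", "Gapdh"),
                      max_mito_fraction = 0.10,
                      mito_prefix = "mt-") {
  if (min_features >= max_features)
    stop_config("min_features must be smaller than max_features")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop_config("max_mito_fraction must lie in [0, 1]")
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 cd3_gene = cd3_gene,
                 housekeeping_genes = housekeeping_genes,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix),
            class = "qc_params")
}

#' Filter cells and genes on quality criteria
#'
#' Cells must pass, in order: CD3 count > 0; detected features within
#' `[min_features, max_features]`; mitochondrial fraction at most
#' `max_mito_fraction`; at least one housekeeping gene detected.  Attrition
#' is attributed to the first failing filter.  Genes detected in fewer than
#' `min_cells_per_gene` retained cells are then dropped.
#'
#' @param counts genes x cells integer matrix.
#' @param params a [qc_params()] object.
#' @return list with `counts` (filtered matrix) and `report` (a `qc_report`:
#'   per-filter attrition, retained barcodes and genes).
#' @export
filter_cells <- function(counts, params = qc_params()) {
  genes <- rownames(counts)
  if (!is.null(params$cd3_gene) && !(params$cd3_gene %in% genes))
    stop_config("CD3 gene '%s' not present in the matrix", params$cd3_gene)
  hk <- params$housekeeping_genes
  if (!is.null(hk)) {
    miss <- setdiff(hk, genes)
    if (length(miss))
      stop_config("housekeeping gene(s) absent from the matrix: %s",
                  paste(miss, collapse = ", "))
  }

  n_in <- ncol(counts)
  detected <- Matrix::colSums(counts > 0)
  totals <- Matrix::colSums(counts)
  mito_genes <- genes[startsWith(genes, params$mito_prefix)]
  mito_frac <- if (length(mito_genes))
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) / pmax(totals, 1)
  else rep(0, n_in)

  pass_cd3 <- if (is.null(params$cd3_gene)) rep(TRUE, n_in)
              else as.vector(counts[params$cd3_gene, ] > 0)
  pass_feat <- detected >= params$min_features & detected <= params$max_features
  pass_mito <- mito_frac <= params$max_mito_fraction
  pass_hk <- if (is.null(hk)) rep(TRUE, n_in)
             else Matrix::colSums(counts[hk, , drop = FALSE] > 0) > 0

  fail_first <- rep(NA_character_, n_in)
  fail_first[!pass_cd3] <- "cd3"
  fail_first[is.na(fail_first) & !pass_feat] <- "features"
  fail_first[is.na(fail_first) & !pass_mito] <- "mito"
  fail_first[is.na(fail_first) & !pass_hk] <- "housekeeping"
  keep <- is.na(fail_first)

  out <- counts[, keep, drop = FALSE]
  gene_cells <- Matrix::rowSums(out > 0)
  keep_genes <- gene_cells >= params$min_cells_per_gene
  out <- out[keep_genes, , drop = FALSE]

  attrition <- data.frame(
    filter = c("cd3", "features", "mito", "housekeeping"),
    removed = c(sum(fail_first == "cd3", na.rm = TRUE),
                sum(fail_first == "features", na.rm = TRUE),
                sum(fail_first == "mito", na.rm = TRUE),
                sum(fail_first == "housekeeping", na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  report <- structure(list(
    n_cells_in = n_in,
    n_cells_out = ncol(out),
    n_genes_in = nrow(counts),
    n_genes_out = nrow(out),
    attrition = attrition,
    genes_removed = sum(!keep_genes),
    retained_barcodes = colnames(out),
    retained_genes = rownames(out),
    params = params
  ), class = "qc_report")
  stopifnot(report$n_cells_in == report$n_cells_out + sum(attrition$removed))
  list(counts = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d/%d cells retained, %d/%d genes retained\n",
              x$n_cells_out, x$n_cells_in, x$n_genes_out, x$n_genes_in))
  for (i in seq_len(nrow(x$attrition)))
    cat(sprintf("  removed by %-12s %d\n",
                paste0(x$attrition$filter[i], ":"), x$attrition$removed[i]))
  invisible(x)
}

#' Log-normalize counts per 10,000
#'
#' `value = ln(1 + 10000 * count / cell_total)`.  The sparsity pattern is
#' preserved (zero counts stay exactly zero).
#'
#' @param counts genes x cells matrix of filtered counts; every cell total
#'   must be positive.
#' @return `dgCMatrix` of the same shape.
#' @export
normalize_cp10k_log <- function(counts) {
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0))
    stop("cells with zero total counts cannot be normalized; run QC first",
         call. = FALSE)
  m <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  per_col <- diff(m@p)
  m@x <- log1p(1e4 * m@x / rep.int(totals, per_col))
  m
}

#' Center and scale genes to unit variance
#'
#' Per-gene mean 0 and variance 1 (denominator n-1), values clipped to
#' `[-clip, clip]`.  Constant genes map to all-zero rows.  Returns a dense
#' matrix, so restrict `genes` to the features you intend to embed.
#'
#' @param normalized genes x cells normalized matrix.
#' @param genes optional subset of rownames to scale (default: all).
#' @param clip magnitude at which scaled values are clipped.
#' @return dense genes x cells matrix.
#' @export
scale_genes <- function(normalized, genes = NULL, clip = 10) {
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(normalized))
    if (length(miss))
      stop_config("genes absent from the matrix: %s",
                  paste(head(miss, 5), collapse = ", "))
    normalized <- normalized[genes, , drop = FALSE]
  }
  x <- as.matrix(normalized)
  n <- ncol(x)
  mu <- rowMeans(x)
  sdv <- sqrt(pmax(rowSums((x - mu)^2) / (n - 1), 0))
  x <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  x[sdv == 0, ] <- 0
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  x
}
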