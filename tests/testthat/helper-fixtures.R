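# Shared fixtures and independent oracles used across test files.

# Small cohort configuration; states collapsed where a test only needs
# compartment structure.
small_cohort_config <- function(seed, n_samples = 4L, cells_per_sample = 250L,
                                shared_clone_count = 50L, ...) {
  sim_config(n_samples = n_samples, cells_per_sample = cells_per_sample,
             shared_clone_count = shared_clone_count, seed = seed, ...)
}

# Brute-force all-pairs cross-tissue chain comparison.  Works from the raw
# chain table: for every pair (blood cell, islet cell) with both alpha and
# beta chains, checks whether any alpha CDR3 string or any beta CDR3 string
# is shared.  O(n^2) by construction; independent of match_tissues().
brute_force_matches <- function(chains, tissue) {
  cell <- chains$cell_id
  ab <- chains[chains$locus %in% c("TRA", "TRB"), , drop = FALSE]
  alpha <- tapply(ab$cdr3_aa[ab$locus == "TRA"], ab$cell_id[ab$locus == "TRA"],
                  function(x) sort(unique(x)))
  beta <- tapply(ab$cdr3_aa[ab$locus == "TRB"], ab$cell_id[ab$locus == "TRB"],
                 function(x) sort(unique(x)))
  cells <- intersect(names(alpha), names(beta))
  tis <- tissue[cells]
  blood <- cells[tis == "blood"]
  islet <- cells[tis == "islet"]
  flagged <- character(0)
  for (b in blood) {
    for (i in islet) {
      if (length(intersect(alpha[[b]], alpha[[i]])) > 0 ||
          length(intersect(beta[[b]], beta[[i]])) > 0) {
        flagged <- c(flagged, b, i)
      }
    }
  }
  sort(unique(flagged))
}

# Vectorized all-pairs variant for cohorts where every clonal cell carries
# exactly one alpha and one beta chain (as the generator produces): builds
# the full blood x islet comparison matrices with outer().  Still an
# exhaustive pairwise comparison, independent of match_tissues().
brute_force_matches_outer <- function(chains, tissue) {
  ab <- chains[chains$locus %in% c("TRA", "TRB"), , drop = FALSE]
  a <- ab[ab$locus == "TRA", ]
  b <- ab[ab$locus == "TRB", ]
  stopifnot(!anyDuplicated(a$cell_id), !anyDuplicated(b$cell_id))
  cells <- intersect(a$cell_id, b$cell_id)
  alpha <- setNames(a$cdr3_aa, a$cell_id)[cells]
  beta <- setNames(b$cdr3_aa, b$cell_id)[cells]
  tis <- tissue[cells]
  bl <- cells[tis == "blood"]
  is <- cells[tis == "islet"]
  m <- outer(alpha[bl], alpha[is], "==") | outer(beta[bl], beta[is], "==")
  sort(unique(c(bl[rowSums(m) > 0], is[colSums(m) > 0])))
}

# Toy counts matrix builder with named genes/cells.
toy_counts <- function(mat, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(mat)))
  cells <- cells %||% sprintf("c%d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, cells)
  methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                          "generalMatrix"), "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal chain table row constructor.
chain_row <- function(cell_id, locus, cdr3) {
  data.frame(cell_id = cell_id, locus = locus, cdr3_aa = cdr3,
             cdr3_nt = NA_character_, v_gene = NA_character_,
             j_gene = NA_character_, productive = TRUE,
             stringsAsFactors = FALSE)
}
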