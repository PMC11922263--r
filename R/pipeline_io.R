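#' Read a Cell Ranger style filtered-matrix triplet
#'
#' Reads `matrix.mtx` + `barcodes.tsv` + `features.tsv` from a directory (or
#' explicit paths) into a genes x cells sparse integer matrix.  Gene
#' identifiers keep file order; the second features column (gene symbol) is
#' used for rownames when present, made unique.
#'
#' @param dir directory containing the triplet, or `NULL` if paths given.
#' @param mtx,barcodes,features explicit file paths (override `dir`).
#' @return `dgCMatrix`, genes x cells, integer-valued.
#' @export
read_matrix <- function(dir = NULL, mtx = NULL, barcodes = NULL, features = NULL) {
  if (!is.null(dir)) {
    mtx <- mtx %||% file.path(dir, "matrix.mtx")
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
    features <- features %||% file.path(dir, "features.tsv")
  }
  for (f in c(mtx, barcodes, features))
    if (!file.exists(f)) stop_format("file not found: %s", f)
  m <- Matrix::readMM(mtx)
  bc <- data.table::fread(barcodes, header = FALSE, sep = "\t",
                          colClasses = "character")[[1]]
  ft <- data.table::fread(features, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(m) != length(bc))
    stop_format("%s declares %d columns but %s has %d barcodes",
                mtx, ncol(m), barcodes, length(bc))
  if (nrow(m) != nrow(ft))
    stop_format("%s declares %d rows but %s has %d features",
                mtx, nrow(m), features, nrow(ft))
  if (anyDuplicated(bc))
    stop_format("duplicate barcodes in %s", barcodes)
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (any(vals != round(vals)) || any(vals < 0))
    stop_format("non-integer or negative entries in %s", mtx)
  sym <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(make.unique(sym), bc)
  m
}

#' Write a matrix as a Cell Ranger style triplet
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @export
write_matrix <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  ft <- data.frame(id = rownames(counts), name = rownames(counts),
                   type = "Gene Expression")
  data.table::fwrite(ft, file.path(dir, "features.tsv"),
                     sep = "\t", col.names = FALSE)
  invisible(dir)
}

#' Read a 10x `filtered_contig_annotations.csv` style contig table
#'
#' Keeps one chain record per productive row with a non-empty CDR3
#' amino-acid sequence and a TRA/TRB/TRG/TRD chain call.  `productive` may
#' be logical or the 10x "True"/"False"/"None" strings; CDR3 values of
#' `""`, `"None"` or `NA` are dropped.
#'
#' @param path CSV file path.
#' @return data.frame with columns `barcode`, `locus`, `cdr3_aa`, `cdr3_nt`,
#'   `v_gene`, `j_gene`, `productive` (all retained rows are `TRUE`).
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  x <- data.table::fread(path, colClasses = list(character = "barcode"))
  need <- c("barcode", "chain", "cdr3", "productive")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_format("%s is missing required column(s): %s", path,
                paste(miss, collapse = ", "))
  prod <- x$productive
  prod <- if (is.logical(prod)) prod & !is.na(prod)
          else toupper(trimws(as.character(prod))) == "TRUE"
  cdr3 <- toupper(trimws(as.character(x$cdr3)))
  ok <- prod & !is.na(cdr3) & cdr3 != "" & cdr3 != "NONE" &
    x$chain %in% c("TRA", "TRB", "TRG", "TRD")
  out <- data.frame(
    barcode = x$barcode[ok],
    locus = x$chain[ok],
    cdr3_aa = cdr3[ok],
    cdr3_nt = if ("cdr3_nt" %in% names(x)) as.character(x$cdr3_nt)[ok] else NA_character_,
    v_gene = if ("v_gene" %in% names(x)) as.character(x$v_gene)[ok] else NA_character_,
    j_gene = if ("j_gene" %in% names(x)) as.character(x$j_gene)[ok] else NA_character_,
    productive = TRUE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write chain records in the 10x contig CSV dialect
#' @param chains data.frame as returned by [read_contigs()] (a `barcode` or
#'   `cell_id` column is used as the barcode).
#' @param path output CSV path.
#' @export
write_contigs <- function(chains, path) {
  bc <- chains$barcode %||% chains$cell_id
  out <- data.frame(
    barcode = bc,
    is_cell = "True",
    high_confidence = "True",
    chain = chains$locus,
    v_gene = chains$v_gene,
    d_gene = "None",
    j_gene = chains$j_gene,
    cdr3 = chains$cdr3_aa,
    cdr3_nt = chains$cdr3_nt,
    productive = ifelse(chains$productive, "True", "False"),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a VDJdb-style TSV of CDR3-epitope records
#'
#' Accepts either plain (`cdr3`, `gene`, `epitope`, `species`) or the VDJdb
#' export headers (`antigen.epitope`, `complex.id`, ...).  CDR3 strings are
#' uppercased; duplicate CDR3s with different epitopes are all retained.
#'
#' @param path TSV file path.
#' @return data.frame with columns `cdr3`, `locus`, `epitope`, `species`.
#' @export
read_vdjdb <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  x <- data.table::fread(path, sep = "\t")
  nm <- names(x)
  pick <- function(...) {
    for (cand in c(...)) if (cand %in% nm) return(as.character(x[[cand]]))
    NULL
  }
  cdr3 <- pick("cdr3", "CDR3")
  if (is.null(cdr3)) stop_format("%s has no CDR3 column", path)
  locus <- pick("gene", "Gene", "locus") %||% rep(NA_character_, length(cdr3))
  epitope <- pick("epitope", "antigen.epitope") %||% rep(NA_character_, length(cdr3))
  species <- pick("species", "Species") %||% rep(NA_character_, length(cdr3))
  data.frame(cdr3 = toupper(trimws(cdr3)), locus = locus,
             epitope = epitope, species = species, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk in external formats
#'
#' One directory per sample holding the Matrix Market triplet and a 10x
#' dialect `filtered_contig_annotations.csv`, plus cohort-level TSVs:
#' `samples.tsv` (sample/tissue/disease), `truth_cells.tsv` and
#' `truth_clones.tsv`.
#'
#' @param cohort an `sc_cohort` from [generate_cohort()].
#' @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$meta
  for (s in unique(meta$sample)) {
    sdir <- file.path(dir, s)
    cells <- meta$cell_id[meta$sample == s]
    m <- cohort$counts[, cells, drop = FALSE]
    colnames(m) <- meta$barcode[match(cells, meta$cell_id)]
    write_matrix(m, sdir)
    ch <- cohort$chains[cohort$chains$cell_id %in% cells, , drop = FALSE]
    ch$barcode <- meta$barcode[match(ch$cell_id, meta$cell_id)]
    write_contigs(ch, file.path(sdir, "filtered_contig_annotations.csv"))
  }
  smp <- unique(meta[, c("sample", "tissue", "disease")])
  data.table::fwrite(smp, file.path(dir, "samples.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth$cells, file.path(dir, "truth_cells.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth$clones, file.path(dir, "truth_clones.tsv"), sep = "\t")
  invisible(dir)
}

#' Load a cohort written by [write_cohort()], pooling samples
#'
#' Barcodes are suffixed with `_<sample>` to disambiguate collisions across
#' pooled libraries; chain records get a `cell_id` column using the same
#' scheme.
#'
#' @param dir cohort directory.
#' @return list with `counts`, `meta`, `chains`.
#' @export
read_cohort <- function(dir) {
  smp <- data.table::fread(file.path(dir, "samples.tsv"), colClasses = "character")
  mats <- list(); metas <- list(); chains <- list()
  for (i in seq_len(nrow(smp))) {
    s <- smp$sample[i]
    m <- read_matrix(file.path(dir, s))
    cid <- paste0(colnames(m), "_", s)
    meta <- data.frame(cell_id = cid, barcode = colnames(m), sample = s,
                       tissue = smp$tissue[i], disease = smp$disease[i],
                       stringsAsFactors = FALSE)
    colnames(m) <- cid
    ch <- read_contigs(file.path(dir, s, "filtered_contig_annotations.csv"))
    ch$cell_id <- paste0(ch$barcode, "_", s)
    mats[[s]] <- m; metas[[s]] <- meta; chains[[s]] <- ch
  }
  genes <- rownames(mats[[1]])
  for (m in mats) stopifnot(identical(rownames(m), genes))
  list(counts = do.call(cbind, mats),
       meta = do.call(rbind, c(metas, list(make.row.names = FALSE))),
       chains = do.call(rbind, c(chains, list(make.row.names = FALSE))))
}

#' Read a pipeline run configuration from YAML
#'
#' Missing fields are filled from [default_run_config()].
#' @param path YAML file.
#' @return nested configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(default_run_config(), cfg)
}

#' Default pipeline run configuration
#'
#' All stage parameters with their defaults: QC thresholds, marker weights,
#' gating marker lists, clustering parameters, transition bootstrap
#' parameters, and classifier parameters.  `simulate` holds the synthetic
#' cohort settings used when the pipeline starts from simulation rather
#' than existing triplets.
#' @return nested list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "tcrtrace_out",
    simulate = list(n_samples = 4L, cells_per_sample = 500L),
    qc = list(min_cells_per_gene = 3L, min_features = 200L, max_features = 5000L,
              cd3_gene = "Cd3e", housekeeping_genes = c("Actb", "B2m", "Gapdh"),
              max_mito_fraction = 0.10, mito_prefix = "mt-"),
    embed = list(n_variable_genes = 400L, n_pcs = 10L, knn_k = 20L,
                 resolution = 1.5, marker_weight = 5),
    gating = list(mode = "median_midpoint", fixed_value = 0.5,
                  cd8_rule = "or", exhaustion_min = 2L),
    transitions = list(n_reps = 100L, min_clone_size_exclusive = 3L),
    classifier = list(reg_strength = 1, folds = 5L, batch_size = 100L,
                      subset_compartment = "CD8", subset_tissue = "blood")
  )
}
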