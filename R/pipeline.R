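PIPELINE_STAGES <- c("simulate", "qc", "embed", "gate", "clonotype",
                     "match", "transitions", "classify", "report")

tsv_write <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

tsv_read <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", ...))
}

# Normalized (real-valued) matrix triplet, same layout as write_matrix but
# without the integer contract.
write_real_matrix <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  invisible(dir)
}

read_real_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  bc <- readLines(file.path(dir, "barcodes.tsv"))
  ft <- readLines(file.path(dir, "features.tsv"))
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(ft, bc)
  m
}

pipeline_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message(sprintf(...))
}

#' Run the analysis pipeline
#'
#' Executes the stage chain `simulate -> qc -> embed -> gate -> clonotype ->
#' match -> transitions -> classify -> report` from one configuration,
#' writing each stage's tables under `config$outdir`.  Stages communicate
#' through files only, so any suffix of the chain can be re-run.  The whole
#' chain is deterministic given `config$seed`.
#'
#' @param config nested configuration list (see [default_run_config()]), or
#'   a path to a YAML file.
#' @param stages subset of stages to run, in order.
#' @return `config$outdir`, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = PIPELINE_STAGES) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- modifyList(default_run_config(), config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  for (s in stages) {
    pipeline_log(cfg, "[%s] starting", s)
    switch(s,
      simulate = stage_simulate(cfg),
      qc = stage_qc(cfg),
      embed = stage_embed(cfg),
      gate = stage_gate(cfg),
      clonotype = stage_clonotype(cfg),
      match = stage_match(cfg),
      transitions = stage_transitions(cfg),
      classify = stage_classify(cfg),
      report = stage_report(cfg))
  }
  invisible(cfg$outdir)
}

stage_simulate <- function(cfg) {
  args <- cfg$simulate
  args$seed <- args$seed %||% cfg$seed
  sc <- do.call(sim_config, args)
  cohort <- generate_cohort(sc)
  write_cohort(cohort, file.path(cfg$outdir, "cohort"))
  pipeline_log(cfg, "[simulate] %d cells x %d genes, %d clones",
               ncol(cohort$counts), nrow(cohort$counts),
               nrow(cohort$truth$clones))
}

stage_qc <- function(cfg) {
  raw <- read_cohort(file.path(cfg$outdir, "cohort"))
  params <- do.call(qc_params, cfg$qc)
  res <- filter_cells(raw$counts, params)
  norm <- normalize_cp10k_log(res$counts)
  qdir <- file.path(cfg$outdir, "qc")
  dir.create(qdir, showWarnings = FALSE)
  write_matrix(res$counts, file.path(qdir, "counts"))
  write_real_matrix(norm, file.path(qdir, "normalized"))
  meta <- raw$meta[raw$meta$cell_id %in% colnames(res$counts), , drop = FALSE]
  tsv_write(meta, file.path(qdir, "meta.tsv"))
  tsv_write(res$report$attrition, file.path(qdir, "attrition.tsv"))
  tsv_write(data.frame(n_cells_in = res$report$n_cells_in,
                       n_cells_out = res$report$n_cells_out,
                       n_genes_in = res$report$n_genes_in,
                       n_genes_out = res$report$n_genes_out,
                       genes_removed = res$report$genes_removed),
            file.path(qdir, "qc_summary.tsv"))
  pipeline_log(cfg, "[qc] %d -> %d cells, %d -> %d genes",
               res$report$n_cells_in, res$report$n_cells_out,
               res$report$n_genes_in, res$report$n_genes_out)
}

# Immune markers entering the embedding: all gating markers join the
# feature set, but only the lineage-discriminating ones are up-weighted
# (up-weighting markers expressed uniformly across compartments would
# amplify their sampling noise without adding separation).
pipeline_marker_genes <- function(genes) {
  spec <- gate_spec()
  all_markers <- unique(c(spec$cd4, spec$cd8, spec$gd, unlist(spec$th),
                          unlist(spec$slec), spec$exhaustion,
                          "Cd3e", "Sell", "Ccr7"))
  weighted <- unique(c(spec$cd4, spec$cd8, spec$gd,
                       unlist(spec$slec), spec$exhaustion))
  list(features = intersect(all_markers, genes),
       weighted = intersect(weighted, genes))
}

stage_embed <- function(cfg) {
  norm <- read_real_matrix(file.path(cfg$outdir, "qc", "normalized"))
  p <- cfg$embed
  hvg <- select_variable_genes(norm, min(p$n_variable_genes, nrow(norm)))
  mk <- pipeline_marker_genes(rownames(norm))
  markers <- mk$features
  features <- union(markers, hvg)
  scaled <- scale_genes(norm, features)
  w <- marker_weights(setNames(rep(p$marker_weight, length(mk$weighted)),
                               mk$weighted))
  emb <- weighted_pca(scaled, features, w, n_pcs = p$n_pcs)
  g <- knn_graph(emb$scores, k = p$knn_k)
  clusters <- cluster_graph(g, resolution = p$resolution, seed = cfg$seed)
  edir <- file.path(cfg$outdir, "embed")
  dir.create(edir, showWarnings = FALSE)
  tsv_write(data.frame(cell_id = rownames(emb$scores),
                       as.data.frame(emb$scores, row.names = NULL)),
            file.path(edir, "pca_scores.tsv"))
  tsv_write(data.frame(gene = hvg), file.path(edir, "variable_genes.tsv"))
  tsv_write(data.frame(cell_id = names(clusters),
                       cluster = paste0("C", unname(clusters))),
            file.path(edir, "clusters.tsv"))
  pb <- pseudobulk(norm[markers, , drop = FALSE],
                   setNames(paste0("C", clusters), names(clusters)))
  tsv_write(data.frame(cluster = rownames(pb), as.data.frame(pb, row.names = NULL)),
            file.path(edir, "pseudobulk_markers.tsv"))
  pipeline_log(cfg, "[embed] %d features, %d PCs, %d clusters",
               length(features), ncol(emb$scores), length(unique(clusters)))
}

stage_gate <- function(cfg) {
  norm <- read_real_matrix(file.path(cfg$outdir, "qc", "normalized"))
  p <- cfg$gating
  spec <- gate_spec(mode = p$mode, fixed_value = p$fixed_value,
                    cd8_rule = p$cd8_rule, exhaustion_min = p$exhaustion_min)
  thresholds <- compute_gates(norm, spec)
  comp <- classify_compartment(norm, spec, thresholds)
  pheno <- classify_phenotype(norm, spec, thresholds)
  non_cd8 <- comp$cell_id[!comp$compartment %in% c("CD8", "DP")]
  th <- classify_th_subset(norm[, non_cd8, drop = FALSE], spec, thresholds)
  gdir <- file.path(cfg$outdir, "gate")
  dir.create(gdir, showWarnings = FALSE)
  tsv_write(comp, file.path(gdir, "compartments.tsv"))
  tsv_write(data.frame(gene = names(thresholds),
                       threshold = unname(thresholds)),
            file.path(gdir, "thresholds.tsv"))
  tsv_write(pheno, file.path(gdir, "phenotype.tsv"))
  tsv_write(th, file.path(gdir, "th_subsets.tsv"))
  tally <- as.data.frame(table(compartment = comp$compartment),
                         stringsAsFactors = FALSE)
  names(tally)[2] <- "n_cells"
  tsv_write(tally, file.path(gdir, "compartment_counts.tsv"))
  pipeline_log(cfg, "[gate] %s",
               paste(sprintf("%s=%d", tally$compartment, tally$n_cells),
                     collapse = " "))
}

read_pooled_chains <- function(cfg) {
  cdir <- file.path(cfg$outdir, "cohort")
  smp <- tsv_read(file.path(cdir, "samples.tsv"), colClasses = "character")
  out <- lapply(smp$sample, function(s) {
    ch <- read_contigs(file.path(cdir, s, "filtered_contig_annotations.csv"))
    ch$cell_id <- paste0(ch$barcode, "_", s)
    ch
  })
  do.call(rbind, out)
}

stage_clonotype <- function(cfg) {
  chains <- read_pooled_chains(cfg)
  meta <- tsv_read(file.path(cfg$outdir, "qc", "meta.tsv"))
  chains <- chains[chains$cell_id %in% meta$cell_id, , drop = FALSE]
  ct <- assign_clonotypes(chains)
  cdir <- file.path(cfg$outdir, "clonotype")
  dir.create(cdir, showWarnings = FALSE)
  tsv_write(ct$clonotypes, file.path(cdir, "clonotypes.tsv"))
  tsv_write(ct$cells, file.path(cdir, "cell_clonotypes.tsv"))
  tsv_write(data.frame(cell_id = ct$excluded),
            file.path(cdir, "excluded_cells.tsv"))
  tsv_write(expansion_summary(ct, meta), file.path(cdir, "expansion_summary.tsv"))
  pipeline_log(cfg, "[clonotype] %d clonotypes over %d cells (%d excluded)",
               nrow(ct$clonotypes), nrow(ct$cells), length(ct$excluded))
}

read_clonotype_set <- function(cfg) {
  cdir <- file.path(cfg$outdir, "clonotype")
  structure(list(
    clonotypes = tsv_read(file.path(cdir, "clonotypes.tsv"),
                          colClasses = list(character = c("clonotype_id", "alpha_cdr3", "beta_cdr3"))),
    cells = tsv_read(file.path(cdir, "cell_clonotypes.tsv"), colClasses = "character"),
    excluded = tsv_read(file.path(cdir, "excluded_cells.tsv"), colClasses = "character")$cell_id
  ), class = "clonotype_set")
}

stage_match <- function(cfg) {
  ct <- read_clonotype_set(cfg)
  meta <- tsv_read(file.path(cfg$outdir, "qc", "meta.tsv"))
  tissue <- setNames(meta$tissue, meta$cell_id)
  res <- match_tissues(ct, tissue)
  mdir <- file.path(cfg$outdir, "match")
  dir.create(mdir, showWarnings = FALSE)
  tsv_write(res$cell_flags, file.path(mdir, "infiltration.tsv"))
  tsv_write(res$matched_chains, file.path(mdir, "matched_chains.tsv"))
  tsv_write(data.frame(clonotype_id = res$matched_clonotypes),
            file.path(mdir, "matched_clonotypes.tsv"))
  pipeline_log(cfg, "[match] %d matching clonotypes, %d infiltrating cells",
               length(res$matched_clonotypes), sum(res$cell_flags$infiltrating))
}

# Cluster-level state annotation: transition nodes are clusters; a cluster
# is SLEC-like / exhausted when the majority of its cells carry the
# corresponding gate flag, and its compartment is the modal gated call.
cluster_states <- function(cfg) {
  clusters <- tsv_read(file.path(cfg$outdir, "embed", "clusters.tsv"),
                       colClasses = "character")
  comp <- tsv_read(file.path(cfg$outdir, "gate", "compartments.tsv"),
                   colClasses = "character")
  pheno <- tsv_read(file.path(cfg$outdir, "gate", "phenotype.tsv"))
  m <- merge(merge(clusters, comp, by = "cell_id"), pheno, by = "cell_id")
  modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  ann <- do.call(rbind, lapply(split(m, m$cluster), function(d) {
    data.frame(cluster = d$cluster[1],
               compartment = modal(d$compartment),
               slec_like = mean(d$slec_like) > 0.5,
               exhausted = mean(d$exhausted) > 0.5,
               n_cells = nrow(d), stringsAsFactors = FALSE)
  }))
  list(states = setNames(m$cluster, m$cell_id), annotation = ann)
}

stage_transitions <- function(cfg) {
  ct <- read_clonotype_set(cfg)
  cs <- cluster_states(cfg)
  compartment_of <- setNames(cs$annotation$compartment, cs$annotation$cluster)
  p <- cfg$transitions
  states <- cs$states[ct$cells$cell_id]
  boot <- bootstrap_transitions(ct, cs$states, n_reps = p$n_reps,
                                min_clone_size_exclusive = p$min_clone_size_exclusive,
                                seed = cfg$seed, compartment_of = compartment_of)
  exact <- exact_transitions(ct, cs$states,
                             min_clone_size_exclusive = p$min_clone_size_exclusive,
                             compartment_of = compartment_of)
  slec_states <- cs$annotation$cluster[cs$annotation$slec_like]
  texh_states <- cs$annotation$cluster[cs$annotation$exhausted]
  fates <- classify_clone_fate(ct, cs$states, slec_states, texh_states)
  tdir <- file.path(cfg$outdir, "transitions")
  dir.create(tdir, showWarnings = FALSE)
  tsv_write(boot$edges, file.path(tdir, "transitions_bootstrap.tsv"))
  tsv_write(exact$edges, file.path(tdir, "transitions_exact.tsv"))
  tsv_write(cs$annotation, file.path(tdir, "cluster_annotation.tsv"))
  tsv_write(fates, file.path(tdir, "clone_fates.tsv"))
  tally <- as.data.frame(table(fate = fates$fate), stringsAsFactors = FALSE)
  names(tally)[2] <- "n_clones"
  tsv_write(tally, file.path(tdir, "fate_counts.tsv"))
  pipeline_log(cfg, "[transitions] %d eligible clones, %d edges",
               boot$n_clones, nrow(boot$edges))
}

stage_classify <- function(cfg) {
  norm <- read_real_matrix(file.path(cfg$outdir, "qc", "normalized"))
  meta <- tsv_read(file.path(cfg$outdir, "qc", "meta.tsv"))
  comp <- tsv_read(file.path(cfg$outdir, "gate", "compartments.tsv"),
                   colClasses = "character")
  infil <- tsv_read(file.path(cfg$outdir, "match", "infiltration.tsv"))
  p <- cfg$classifier
  keep <- merge(meta, comp, by = "cell_id")
  keep <- keep$cell_id[keep$compartment %in% p$subset_compartment &
                       keep$tissue %in% p$subset_tissue]
  keep <- intersect(keep, infil$cell_id[!is.na(infil$infiltrating)])
  y <- setNames(infil$infiltrating, infil$cell_id)[keep]
  x <- t(as.matrix(norm[, keep, drop = FALSE]))
  spec <- classifier_spec(reg_strength = p$reg_strength, folds = p$folds,
                          batch_size = p$batch_size, seed = cfg$seed)
  report <- train_eval(x, y, spec)
  imp <- feature_importance(report, top_k = 20L)
  kdir <- file.path(cfg$outdir, "classify")
  dir.create(kdir, showWarnings = FALSE)
  tsv_write(data.frame(auc = report$auc, auc_mean_fold = report$auc_mean_fold,
                       auprc = report$auprc,
                       auprc_mean_fold = report$auprc_mean_fold,
                       n_cells = length(y), n_positive = sum(y)),
            file.path(kdir, "metrics.tsv"))
  tsv_write(report$fold_metrics, file.path(kdir, "fold_metrics.tsv"))
  if (!is.null(report$batch_metrics))
    tsv_write(report$batch_metrics, file.path(kdir, "batch_metrics.tsv"))
  tsv_write(imp, file.path(kdir, "importance.tsv"))
  tsv_write(report$roc, file.path(kdir, "roc_points.tsv"))
  tsv_write(report$pr, file.path(kdir, "pr_points.tsv"))
  pipeline_log(cfg, "[classify] n=%d (%d infiltrating), AUC=%.3f",
               length(y), sum(y), report$auc)
}

stage_report <- function(cfg) {
  qdir <- file.path(cfg$outdir, "qc")
  summary <- list(
    seed = cfg$seed,
    qc = as.list(tsv_read(file.path(qdir, "qc_summary.tsv"))),
    attrition = tsv_read(file.path(qdir, "attrition.tsv")),
    compartments = tsv_read(file.path(cfg$outdir, "gate", "compartment_counts.tsv")),
    expansion = as.list(tsv_read(file.path(cfg$outdir, "clonotype",
                                           "expansion_summary.tsv"))),
    n_matching_clonotypes = nrow(tsv_read(file.path(cfg$outdir, "match",
                                                    "matched_clonotypes.tsv"))),
    fates = tsv_read(file.path(cfg$outdir, "transitions", "fate_counts.tsv")),
    classifier = as.list(tsv_read(file.path(cfg$outdir, "classify", "metrics.tsv")))
  )
  jsonlite::write_json(summary, file.path(cfg$outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  pipeline_log(cfg, "[report] run_summary.json written")
}
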