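COMPARTMENTS <- c("CD4", "CD8", "DN", "DP", "GD")
STATES <- c("naive", "effector", "memory", "SLEC", "Pexh", "Texh")

#' Default marker panel for the synthetic cohort
#'
#' One row per (gene, target) pair.  `level` says whether the target is a
#' compartment, a maturation state, or every cell (`"all"`); `log2_fold`
#' scales the expressed negative-binomial mean relative to the config's
#' `marker_base`.  Genes listed here are modelled as on/off: cells outside
#' every listed target express the gene at `off_factor * marker_base`
#' (zero by default), which is the biological situation for lineage markers
#' such as Cd4 or Trgv2.
#'
#' @return data.frame with columns `gene`, `level`, `target`, `log2_fold`.
#' @export
default_marker_panel <- function() {
  p <- function(gene, level, target, log2_fold = 1) {
    data.frame(gene = gene, level = level, target = target,
               log2_fold = log2_fold, stringsAsFactors = FALSE)
  }
  rbind(
    p("Cd3e",  "all", "*"),
    p("Cd4",   "compartment", c("CD4", "DP")),
    p("Cd8a",  "compartment", c("CD8", "DP")),
    p("Cd8b1", "compartment", c("CD8", "DP")),
    p("Trgv2", "compartment", "GD"),
    p("Klrg1", "state", "SLEC"),
    p("Gzma",  "state", "SLEC"),
    p("Il7r",  "state", c("naive", "effector", "memory")),
    p("Sell",  "state", c("naive", "memory")),
    p("Ccr7",  "state", c("naive", "memory")),
    p("Ifng",  "state", "effector"),
    p("Tnf",   "state", "effector"),
    p("Pdcd1", "state", c("Pexh", "Texh")),
    p("Tigit", "state", c("Pexh", "Texh")),
    p("Ctla4", "state", "Texh"),
    p("Lag3",  "state", "Texh"),
    p("Havcr2","state", "Texh"),
    p("Actb",  "all", "*", 2),
    p("B2m",   "all", "*", 2),
    p("Gapdh", "all", "*", 2),
    p("mt-Co1","all", "*", 1),
    p("mt-Nd1","all", "*", 1),
    p("mt-Cytb","all","*", 1)
  )
}

#' Default maturation-state mix per compartment
#'
#' Row-stochastic compartment x state matrix.  SLEC is reachable only from
#' the CD8 compartment; DP and GD cells carry no exhausted states.
#' @return numeric matrix, rows CD4/CD8/DN/DP/GD, columns the six states.
#' @export
default_state_fractions <- function() {
  m <- rbind(
    CD4 = c(0.30, 0.35, 0.20, 0.00, 0.08, 0.07),
    CD8 = c(0.25, 0.30, 0.15, 0.15, 0.08, 0.07),
    DN  = c(0.30, 0.30, 0.20, 0.00, 0.10, 0.10),
    DP  = c(0.60, 0.20, 0.20, 0.00, 0.00, 0.00),
    GD  = c(0.40, 0.40, 0.20, 0.00, 0.00, 0.00)
  )
  colnames(m) <- STATES
  m
}

#' Simulation configuration for a paired expression + repertoire cohort
#'
#' Builds and validates the configuration consumed by [generate_cohort()].
#' Defaults describe a four-library pooled cohort (diabetic and non-diabetic
#' mice, blood and islet tissue each) with a double-negative-rich
#' compartment mix, two-fold marker effects on an on/off panel, moderately
#' overdispersed counts with independent dropout, a heavy-tailed clone-size
#' distribution, and 50 clones planted in both tissues.
#'
#' @param n_samples number of pooled libraries.
#' @param cells_per_sample cells per library.
#' @param tissue_of_sample named character map sample -> "blood"/"islet".
#' @param disease_of_sample named character map sample -> "diabetic"/"nondiabetic".
#' @param compartment_fractions simplex over CD4/CD8/DN/DP/GD.
#' @param state_fractions compartment x state row-simplex matrix.
#' @param marker_panel data.frame as [default_marker_panel()].
#' @param marker_base expressed NB mean of a panel gene before fold scaling.
#' @param off_factor multiplier of `marker_base` for panel genes outside
#'   their targets (0 = structural off).
#' @param baseline_mean NB mean of background (non-panel) genes.
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param dropout_rate independent probability of zeroing any count.
#' @param n_genes total genes including panel genes.
#' @param clone_size_alpha power-law tail exponent of clone sizes.
#' @param shared_clone_count clones planted with members in both tissues.
#' @param paired_chain_rate probability a non-GD cell carries both an alpha
#'   and a beta chain.
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 4L,
                       cells_per_sample = 500L,
                       tissue_of_sample = NULL,
                       disease_of_sample = NULL,
                       compartment_fractions = c(CD4 = 0.30, CD8 = 0.27,
                                                 DN = 0.33, DP = 0.05, GD = 0.05),
                       state_fractions = default_state_fractions(),
                       marker_panel = default_marker_panel(),
                       marker_base = 6,
                       off_factor = 0,
                       baseline_mean = 1.5,
                       dispersion = 2,
                       dropout_rate = 0.05,
                       n_genes = 500L,
                       clone_size_alpha = 2.5,
                       shared_clone_count = 50L,
                       paired_chain_rate = 0.9,
                       seed = 1L) {
  samples <- sprintf("S%d", seq_len(n_samples))
  if (is.null(tissue_of_sample)) {
    tissue_of_sample <- setNames(rep(c("blood", "islet"), length.out = n_samples), samples)
  }
  if (is.null(disease_of_sample)) {
    half <- ceiling(n_samples / 2)
    disease_of_sample <- setNames(
      rep(c("diabetic", "nondiabetic"), times = c(half, n_samples - half)), samples)
  }
  cfg <- list(
    n_samples = as.integer(n_samples),
    cells_per_sample = as.integer(cells_per_sample),
    samples = samples,
    tissue_of_sample = tissue_of_sample,
    disease_of_sample = disease_of_sample,
    compartment_fractions = compartment_fractions,
    state_fractions = state_fractions,
    marker_panel = marker_panel,
    marker_base = marker_base,
    off_factor = off_factor,
    baseline_mean = baseline_mean,
    dispersion = dispersion,
    dropout_rate = dropout_rate,
    n_genes = as.integer(n_genes),
    clone_size_alpha = clone_size_alpha,
    shared_clone_count = as.integer(shared_clone_count),
    paired_chain_rate = paired_chain_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  f <- cfg$compartment_fractions
  if (!setequal(names(f), COMPARTMENTS) || any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop_config("compartment_fractions must be a simplex over %s",
                paste(COMPARTMENTS, collapse = "/"))
  sf <- cfg$state_fractions
  if (!identical(colnames(sf), STATES) || !setequal(rownames(sf), COMPARTMENTS))
    stop_config("state_fractions must be a %d x %d compartment-by-state matrix",
                length(COMPARTMENTS), length(STATES))
  if (any(sf < 0) || any(abs(rowSums(sf) - 1) > 1e-9))
    stop_config("each state_fractions row must be a simplex")
  for (p in c("dropout_rate", "paired_chain_rate")) {
    v <- cfg[[p]]
    if (v < 0 || v > 1) stop_config("%s must lie in [0, 1]", p)
  }
  for (p in c("marker_base", "baseline_mean", "dispersion", "clone_size_alpha")) {
    if (cfg[[p]] <= 0) stop_config("%s must be positive", p)
  }
  if (cfg$off_factor < 0) stop_config("off_factor must be non-negative")
  panel_genes <- unique(cfg$marker_panel$gene)
  if (cfg$n_genes < length(panel_genes))
    stop_config("n_genes (%d) is smaller than the marker panel (%d genes)",
                cfg$n_genes, length(panel_genes))
  if (cfg$shared_clone_count < 0)
    stop_config("shared_clone_count must be non-negative")
  if (!all(cfg$tissue_of_sample %in% c("blood", "islet")))
    stop_config("tissue_of_sample values must be 'blood' or 'islet'")
  invisible(cfg)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Canonical C...F framed CDR3 amino-acid string.
random_cdr3 <- function(n = 1, min_inner = 7, max_inner = 13) {
  vapply(seq_len(n), function(i) {
    len <- sample(min_inner:max_inner, 1)
    paste0("C", paste(sample(AA20, len, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

random_nt <- function(n_aa) {
  paste(sample(c("A", "C", "G", "T"), 3 * n_aa, replace = TRUE), collapse = "")
}

# Draw CDR3 strings guaranteed unique against (and then added to) `seen`,
# an environment used as a string set.  Clone identity <=> CDR3 identity.
draw_unique_cdr3 <- function(n, seen) {
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      s <- random_cdr3(1)
      if (is.null(seen[[s]])) {
        seen[[s]] <- TRUE
        out[i] <- s
        break
      }
    }
  }
  out
}

# Truncated discrete power-law clone sizes, P(s) proportional to s^-alpha.
draw_clone_sizes <- function(n, alpha, s_max) {
  s <- seq_len(s_max)
  sample(s, n, replace = TRUE, prob = s^(-alpha))
}

#' Generate a paired expression + TCR repertoire cohort with ground truth
#'
#' Draws per-cell compartment and maturation-state labels, simulates
#' negative-binomial counts (gamma-Poisson, one global dispersion) with
#' marker effects and independent dropout, plants a heavy-tailed clone
#' structure with a fixed number of clones spanning blood and islets, and
#' emits productive TCR chain records in which every member of a clone
#' carries the identical CDR3 amino-acid sequences.  Fully deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `sc_cohort` with elements `counts` (genes x cells
#'   sparse dgCMatrix), `meta` (per-cell sample/tissue/disease), `chains`
#'   (productive chain records, 10x contig dialect fields), and `truth`
#'   (list with per-cell and per-clone ground truth).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  samples <- config$samples
  n_cells <- config$n_samples * config$cells_per_sample
  sample_of <- rep(samples, each = config$cells_per_sample)
  tissue_of <- unname(config$tissue_of_sample[sample_of])
  disease_of <- unname(config$disease_of_sample[sample_of])

  # 10x-style barcodes, unique within a sample (collisions across samples are
  # possible and left to the pooling step to disambiguate).
  barcodes <- character(n_cells)
  for (s in samples) {
    idx <- which(sample_of == s)
    repeat {
      bc <- vapply(idx, function(i)
        paste0(paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE),
                     collapse = ""), "-1"), character(1))
      if (!anyDuplicated(bc)) break
    }
    barcodes[idx] <- bc
  }
  cell_id <- paste0(barcodes, "_", sample_of)

  compartment <- sample(COMPARTMENTS, n_cells, replace = TRUE,
                        prob = config$compartment_fractions[COMPARTMENTS])
  state <- character(n_cells)
  for (cp in COMPARTMENTS) {
    idx <- which(compartment == cp)
    if (length(idx))
      state[idx] <- sample(STATES, length(idx), replace = TRUE,
                           prob = config$state_fractions[cp, ])
  }

  counts <- simulate_counts(config, compartment, state, cell_id)
  clones <- simulate_clones(config, cell_id, compartment, tissue_of, disease_of, sample_of)

  meta <- data.frame(
    cell_id = cell_id, barcode = barcodes, sample = sample_of,
    tissue = tissue_of, disease = disease_of, stringsAsFactors = FALSE
  )
  truth_cells <- data.frame(
    cell_id = cell_id, sample = sample_of, tissue = tissue_of,
    disease = disease_of, compartment = compartment, state = state,
    clone_id = clones$clone_of_cell[cell_id],
    infiltrating = clones$infiltrating[cell_id],
    stringsAsFactors = FALSE
  )
  structure(list(
    counts = counts, meta = meta, chains = clones$chains,
    truth = list(cells = truth_cells, clones = clones$clone_table),
    config = config
  ), class = "sc_cohort")
}

simulate_counts <- function(config, compartment, state, cell_id) {
  panel <- config$marker_panel
  panel_genes <- unique(panel$gene)
  extra <- setdiff(c("Il4", "Il10", "Il17a", "Il22", "Foxp3", "Klrb1c"), panel_genes)
  n_fill <- config$n_genes - length(panel_genes) - length(extra)
  if (n_fill < 0) {
    extra <- head(extra, max(0, config$n_genes - length(panel_genes)))
    n_fill <- config$n_genes - length(panel_genes) - length(extra)
  }
  genes <- c(panel_genes, extra,
             if (n_fill > 0) sprintf("Gene%04d", seq_len(n_fill)))
  n_cells <- length(cell_id)

  mu <- matrix(config$baseline_mean, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, cell_id))
  mu[panel_genes, ] <- config$off_factor * config$marker_base
  for (g in panel_genes) {
    rows <- panel[panel$gene == g, , drop = FALSE]
    m <- rep(NA_real_, n_cells)
    for (k in seq_len(nrow(rows))) {
      hit <- switch(rows$level[k],
        all = rep(TRUE, n_cells),
        compartment = compartment == rows$target[k],
        state = state == rows$target[k],
        stop_config("unknown marker panel level '%s'", rows$level[k]))
      val <- config$marker_base * 2^rows$log2_fold[k]
      m[hit] <- pmax(m[hit], val, na.rm = TRUE)
    }
    on <- !is.na(m)
    if (any(on)) mu[g, on] <- m[on]
  }

  x <- rnbinom(length(mu), mu = as.vector(mu), size = config$dispersion)
  if (config$dropout_rate > 0)
    x <- x * (runif(length(x)) >= config$dropout_rate)
  m <- matrix(x, nrow = length(genes), dimnames = dimnames(mu))
  methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
}

simulate_clones <- function(config, cell_id, compartment, tissue_of, disease_of, sample_of) {
  n_cells <- length(cell_id)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  clone_of_cell <- setNames(rep(NA_character_, n_cells), cell_id)

  is_gd <- compartment == "GD"
  paired <- !is_gd & (runif(n_cells) < config$paired_chain_rate)
  single <- !is_gd & !paired

  clone_rows <- list()
  chain_rows <- list()
  next_clone <- 1L
  new_clone_id <- function() {
    id <- sprintf("clone%05d", next_clone)
    next_clone <<- next_clone + 1L
    id
  }

  vgenes <- list(TRA = sprintf("TRAV%d", 1:15), TRB = sprintf("TRBV%d", 1:15),
                 TRG = sprintf("TRGV%d", 1:4),  TRD = sprintf("TRDV%d", 1:4))
  jgenes <- list(TRA = sprintf("TRAJ%d", 1:20), TRB = sprintf("TRBJ%d", 1:10),
                 TRG = sprintf("TRGJ%d", 1:2),  TRD = sprintf("TRDJ%d", 1:2))

  emit_clone <- function(members, loci) {
    id <- new_clone_id()
    clone_of_cell[members] <<- id
    cdr3 <- setNames(draw_unique_cdr3(length(loci), seen), loci)
    nts <- setNames(vapply(cdr3, function(s) random_nt(nchar(s)), character(1)), loci)
    vg <- setNames(vapply(loci, function(l) sample(vgenes[[l]], 1), character(1)), loci)
    jg <- setNames(vapply(loci, function(l) sample(jgenes[[l]], 1), character(1)), loci)
    for (l in loci) {
      chain_rows[[length(chain_rows) + 1L]] <<- data.frame(
        cell_id = members, locus = l, cdr3_aa = cdr3[[l]], cdr3_nt = nts[[l]],
        v_gene = vg[[l]], j_gene = jg[[l]], productive = TRUE,
        stringsAsFactors = FALSE)
    }
    clone_rows[[length(clone_rows) + 1L]] <<- data.frame(
      clone_id = id, chain_type = if ("TRA" %in% loci) "ab" else "gd",
      alpha_cdr3 = if ("TRA" %in% loci) cdr3[["TRA"]] else NA_character_,
      beta_cdr3 = if ("TRB" %in% loci) cdr3[["TRB"]] else NA_character_,
      size = length(members),
      n_blood = sum(tissue_of[match(members, cell_id)] == "blood"),
      n_islet = sum(tissue_of[match(members, cell_id)] == "islet"),
      stringsAsFactors = FALSE)
    id
  }

  # Pools of paired alpha/beta cells by (disease, tissue), shuffled once.
  pool <- list()
  for (d in unique(disease_of)) for (t in c("blood", "islet")) {
    idx <- which(paired & disease_of == d & tissue_of == t)
    pool[[paste(d, t)]] <- cell_id[idx[sample.int(length(idx))]]
  }
  take <- function(key, k) {
    got <- head(pool[[key]], k)
    pool[[key]] <<- pool[[key]][-seq_len(length(got))]
    got
  }

  # Shared (infiltrating) clones: planted with >=1 paired member in each
  # tissue, within a single disease group where possible.
  groups <- unique(disease_of)
  both <- groups[vapply(groups, function(d)
    length(pool[[paste(d, "blood")]]) > 0 && length(pool[[paste(d, "islet")]]) > 0,
    logical(1))]
  if (config$shared_clone_count > 0 && length(both) == 0)
    stop_config("shared clones requested but no disease group has paired cells in both tissues")
  gi <- 0L
  for (k in seq_len(config$shared_clone_count)) {
    d <- both[(gi %% length(both)) + 1L]; gi <- gi + 1L
    repeat {
      s <- draw_clone_sizes(1, config$clone_size_alpha, config$cells_per_sample)
      if (s >= 2) break
    }
    s_b <- 1L + rbinom(1, s - 2L, 0.5)
    mb <- take(paste(d, "blood"), s_b)
    mi <- take(paste(d, "islet"), s - s_b)
    if (length(mb) == 0) mb <- take(paste(d, "blood"), 1L)
    if (length(mi) == 0) mi <- take(paste(d, "islet"), 1L)
    if (length(mb) == 0 || length(mi) == 0)
      stop_config("not enough paired cells to plant %d shared clones", config$shared_clone_count)
    emit_clone(c(mb, mi), c("TRA", "TRB"))
  }

  # Tissue-private clones fill the remaining paired cells.
  for (key in names(pool)) {
    while (length(pool[[key]]) > 0) {
      s <- draw_clone_sizes(1, config$clone_size_alpha, config$cells_per_sample)
      emit_clone(take(key, s), c("TRA", "TRB"))
    }
  }

  # Single-chain cells: own singleton clone, one chain, unique CDR3.
  for (cid in cell_id[single]) {
    emit_clone(cid, sample(c("TRA", "TRB"), 1))
  }

  # GD cells: gamma+delta chains, tissue-private clones.
  for (t in c("blood", "islet")) {
    gd_pool <- cell_id[is_gd & tissue_of == t]
    gd_pool <- gd_pool[sample.int(length(gd_pool))]
    while (length(gd_pool) > 0) {
      s <- draw_clone_sizes(1, config$clone_size_alpha, config$cells_per_sample)
      members <- head(gd_pool, s)
      gd_pool <- gd_pool[-seq_len(length(members))]
      emit_clone(members, c("TRG", "TRD"))
    }
  }

  clone_table <- do.call(rbind, clone_rows)
  clone_table$shared <- clone_table$n_blood > 0 & clone_table$n_islet > 0
  chains <- do.call(rbind, chain_rows)
  chains <- chains[order(match(chains$cell_id, cell_id), chains$locus), ]
  rownames(chains) <- NULL
  spanning <- clone_table$clone_id[clone_table$shared]
  infiltrating <- setNames(clone_of_cell %in% spanning, cell_id)

  list(clone_of_cell = clone_of_cell, clone_table = clone_table,
       chains = chains, infiltrating = infiltrating)
}

#' Summarize planted ground truth
#'
#' Per-sample compartment and state tallies plus the clone-size histogram,
#' for recovery comparisons against pipeline output.
#'
#' @param truth the `truth` element of a [generate_cohort()] result (a list
#'   with `cells` and `clones` data frames).
#' @return list of data.frames: `compartments` (sample x compartment counts,
#'   long form), `states`, `clone_sizes` (size, n_clones).
#' @export
truth_report <- function(truth) {
  cells <- truth$cells
  if (is.null(cells) || nrow(cells) == 0) {
    empty <- data.frame()
    return(list(compartments = empty, states = empty, clone_sizes = empty))
  }
  comp <- as.data.frame(table(sample = cells$sample, compartment = cells$compartment),
                        stringsAsFactors = FALSE)
  names(comp)[3] <- "n_cells"
  st <- as.data.frame(table(sample = cells$sample, state = cells$state),
                      stringsAsFactors = FALSE)
  names(st)[3] <- "n_cells"
  cs <- as.data.frame(table(size = truth$clones$size), stringsAsFactors = FALSE)
  names(cs)[2] <- "n_clones"
  cs$size <- as.integer(cs$size)
  list(compartments = comp, states = st, clone_sizes = cs)
}
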