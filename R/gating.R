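#' Gate specification for compartment, Th-subset and phenotype calls
#'
#' Marker names and threshold policy for expression gating on the
#' log-normalized matrix.  The default threshold mode places a linear gate
#' midway between the median of the zero-expression population and the
#' median of the positive population of each marker, falling back to a
#' fixed value when fewer than `min_pos_frac` of cells are positive; the
#' alternative `"fixed"` mode uses `fixed_value` throughout.
#'
#' @param cd4,gd single marker gene names (CD4 co-receptor, gamma-delta TCR).
#' @param cd8 character vector of CD8 markers (both chains).
#' @param cd8_rule `"or"` (either CD8 chain above threshold, default) or
#'   `"and"` (both).
#' @param mode `"median_midpoint"` or `"fixed"`.
#' @param fixed_value fallback / fixed threshold on the normalized scale.
#' @param min_pos_frac minimum positive fraction for the midpoint gate.
#' @param th named list of Th-subset cytokine/TF markers.
#' @param slec named list of SLEC markers (klrg1, gzma, il7r).
#' @param exhaustion character vector of inhibitory-receptor markers.
#' @param exhaustion_min markers above threshold needed to call exhaustion.
#' @return list of class `gate_spec`.
#' @export
gate_spec <- function(cd4 = "Cd4",
                      cd8 = c("Cd8a", "Cd8b1"),
                      gd = "Trgv2",
                      cd8_rule = c("or", "and"),
                      mode = c("median_midpoint", "fixed"),
                      fixed_value = 0.5,
                      min_pos_frac = 0.01,
                      th = list(ifng = "Ifng", tnf = "Tnf", il4 = "Il4",
                                il10 = "Il10", il17 = "Il17a", il22 = "Il22",
                                foxp3 = "Foxp3"),
                      slec = list(klrg1 = "Klrg1", gzma = "Gzma", il7r = "Il7r"),
                      exhaustion = c("Pdcd1", "Tigit", "Ctla4", "Havcr2", "Lag3"),
                      exhaustion_min = 2L) {
  structure(list(cd4 = cd4, cd8 = cd8, gd = gd,
                 cd8_rule = match.arg(cd8_rule),
                 mode = match.arg(mode),
                 fixed_value = fixed_value, min_pos_frac = min_pos_frac,
                 th = th, slec = slec, exhaustion = exhaustion,
                 exhaustion_min = as.integer(exhaustion_min)),
            class = "gate_spec")
}

#' Threshold for one marker
#'
#' In `median_midpoint` mode the threshold is the midpoint between the
#' median of the zero-expression population and the median of the positive
#' population; if positives are fewer than `min_pos_frac` of cells (or
#' absent) the fixed fallback is used.  In `fixed` mode the fixed value is
#' returned regardless of the data.
#'
#' @param values per-cell normalized expression of one gene.
#' @param mode `"median_midpoint"` or `"fixed"`.
#' @param fixed_value fallback / fixed threshold.
#' @param min_pos_frac minimum positive fraction for the midpoint gate.
#' @return scalar threshold.
#' @export
gate_threshold <- function(values, mode = c("median_midpoint", "fixed"),
                           fixed_value = 0.5, min_pos_frac = 0.01) {
  mode <- match.arg(mode)
  stopifnot(length(values) >= 1)
  if (mode == "fixed") return(fixed_value)
  pos <- values[values > 0]
  if (length(pos) == 0 || length(pos) < min_pos_frac * length(values))
    return(fixed_value)
  zero <- values[values <= 0]
  med_zero <- if (length(zero)) median(zero) else 0
  (med_zero + median(pos)) / 2
}

gate_values <- function(normalized, genes) {
  miss <- setdiff(genes, rownames(normalized))
  if (length(miss))
    stop_config("gating marker(s) absent from the matrix: %s",
                paste(miss, collapse = ", "))
  as.matrix(normalized[genes, , drop = FALSE])
}

#' Compute thresholds for all gating markers
#'
#' @param normalized genes x cells normalized matrix.
#' @param spec a [gate_spec()].
#' @return named numeric vector of per-marker thresholds.
#' @export
compute_gates <- function(normalized, spec = gate_spec()) {
  genes <- unique(c(spec$cd4, spec$cd8, spec$gd, unlist(spec$th),
                    unlist(spec$slec), spec$exhaustion))
  x <- gate_values(normalized, genes)
  vapply(genes, function(g)
    gate_threshold(x[g, ], spec$mode, spec$fixed_value, spec$min_pos_frac),
    numeric(1))
}

above <- function(x, thresholds, gene) x[gene, ] > thresholds[[gene]]

#' Classify cells into T-cell compartments
#'
#' Gamma-delta cells are called first (exclusively) on the gamma-chain
#' marker; remaining cells are partitioned by CD4/CD8 positivity into CD4,
#' CD8, DP (both) and DN (neither).  CD8 positivity combines the two CD8
#' chain markers with `spec$cd8_rule`.
#'
#' @param normalized genes x cells normalized matrix.
#' @param spec a [gate_spec()].
#' @param thresholds optional precomputed [compute_gates()] result.
#' @return data.frame `cell_id`, `compartment`; thresholds as an attribute.
#' @export
classify_compartment <- function(normalized, spec = gate_spec(),
                                 thresholds = NULL) {
  thresholds <- thresholds %||% compute_gates(normalized, spec)
  x <- gate_values(normalized, unique(c(spec$cd4, spec$cd8, spec$gd)))
  gd_pos <- above(x, thresholds, spec$gd)
  cd4_pos <- above(x, thresholds, spec$cd4)
  cd8_each <- matrix(vapply(spec$cd8, function(g) above(x, thresholds, g),
                            logical(ncol(x))), nrow = ncol(x))
  cd8_pos <- if (spec$cd8_rule == "or") rowSums(cd8_each) > 0
             else rowSums(cd8_each) == length(spec$cd8)
  label <- ifelse(gd_pos, "GD",
           ifelse(cd4_pos & cd8_pos, "DP",
           ifelse(cd4_pos, "CD4",
           ifelse(cd8_pos, "CD8", "DN"))))
  out <- data.frame(cell_id = colnames(normalized), compartment = label,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}

#' Classify non-CD8 cells into Th-like subsets
#'
#' Marker combinations: Treg (Foxp3+ Il10+), Th17 (Il17+), Th22 (Il22+
#' Tnf+), Th1 (Ifng+ Tnf+), Tfh (Il4+ Il10+), Th2 (Il4+ without Il10),
#' Th9 (Il10+ without Ifng or Tnf).  Because the combinations are not
#' mutually exclusive, rules are applied in that fixed precedence order and
#' the first satisfied rule wins; cells matching none are `NA`.
#'
#' @param normalized genes x cells normalized matrix (the cells to call).
#' @param spec a [gate_spec()].
#' @param thresholds optional precomputed thresholds.
#' @param compartment optional per-cell compartment labels (named or aligned
#'   with columns); supplying any CD8 cell is an error, since these subsets
#'   are defined by lack of CD8 expression.
#' @return data.frame `cell_id`, `th_subset` (character, `NA` if no rule).
#' @export
classify_th_subset <- function(normalized, spec = gate_spec(),
                               thresholds = NULL, compartment = NULL) {
  if (!is.null(compartment)) {
    if (!is.null(names(compartment))) compartment <- compartment[colnames(normalized)]
    if (any(compartment %in% c("CD8", "DP")))
      stop("Th subset calls are defined for cells lacking CD8 expression",
           call. = FALSE)
  }
  thresholds <- thresholds %||% compute_gates(normalized, spec)
  m <- spec$th
  x <- gate_values(normalized, unlist(m))
  p <- lapply(m, function(g) above(x, thresholds, g))
  rules <- list(
    Treg = p$foxp3 & p$il10,
    Th17 = p$il17,
    Th22 = p$il22 & p$tnf,
    Th1  = p$ifng & p$tnf,
    Tfh  = p$il4 & p$il10,
    Th2  = p$il4 & !p$il10,
    Th9  = p$il10 & !p$ifng & !p$tnf
  )
  label <- rep(NA_character_, ncol(x))
  for (nm in names(rules)) {
    hit <- is.na(label) & rules[[nm]]
    label[hit] <- nm
  }
  data.frame(cell_id = colnames(normalized), th_subset = label,
             stringsAsFactors = FALSE)
}

#' SLEC-like and exhaustion phenotype flags
#'
#' SLEC-like: Klrg1 above threshold, Gzma above, Il7r not above.
#' Exhausted: at least `spec$exhaustion_min` inhibitory-receptor markers
#' above threshold.
#'
#' @inheritParams classify_th_subset
#' @return data.frame `cell_id`, `slec_like`, `exhausted` (logical).
#' @export
classify_phenotype <- function(normalized, spec = gate_spec(),
                               thresholds = NULL) {
  thresholds <- thresholds %||% compute_gates(normalized, spec)
  genes <- unique(c(unlist(spec$slec), spec$exhaustion))
  x <- gate_values(normalized, genes)
  slec <- above(x, thresholds, spec$slec$klrg1) &
          above(x, thresholds, spec$slec$gzma) &
          !above(x, thresholds, spec$slec$il7r)
  n_exh <- rowSums(matrix(vapply(spec$exhaustion,
                                 function(g) above(x, thresholds, g),
                                 logical(ncol(x))), nrow = ncol(x)))
  data.frame(cell_id = colnames(normalized),
             slec_like = unname(slec),
             exhausted = unname(n_exh >= spec$exhaustion_min),
             stringsAsFactors = FALSE)
}
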