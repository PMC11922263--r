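#' Assign cells to clonotypes from productive chain records
#'
#' Only cells carrying at least one alpha (TRA) and one beta (TRB) chain
#' enter the clonal analysis; gamma/delta chains are carried in the input
#' but never contribute to clonotype identity.  The clonotype key is the
#' pair (sorted set of alpha CDR3 amino-acid strings, sorted set of beta
#' CDR3 strings), so cells with multiple chains per locus match only on
#' full set equality.  Identical keys merge; clone size is the member-cell
#' count.
#'
#' @param chains data.frame of productive chain records with columns
#'   `cell_id` (or `barcode`), `locus`, `cdr3_aa`.
#' @return list of class `clonotype_set`: `clonotypes` (data.frame
#'   `clonotype_id`, `alpha_cdr3`, `beta_cdr3` — `;`-joined sets — and
#'   `n_cells`), `cells` (data.frame `cell_id`, `clonotype_id`), and
#'   `excluded` (cell ids lacking an alpha or a beta chain).
#' @export
assign_clonotypes <- function(chains) {
  cell <- chains$cell_id %||% chains$barcode
  stopifnot(!is.null(cell))
  dt <- data.table::data.table(cell_id = cell, locus = chains$locus,
                               cdr3 = toupper(chains$cdr3_aa))
  dt <- unique(dt[dt$locus %in% c("TRA", "TRB")])
  keys <- dt[, list(
    alpha = paste(sort(.SD$cdr3[.SD$locus == "TRA"]), collapse = ";"),
    beta  = paste(sort(.SD$cdr3[.SD$locus == "TRB"]), collapse = ";")
  ), by = "cell_id"]
  all_cells <- unique(cell)
  keep <- keys$alpha != "" & keys$beta != ""
  excluded <- union(setdiff(all_cells, keys$cell_id), keys$cell_id[!keep])
  keys <- keys[keep]
  if (nrow(keys) == 0) {
    return(structure(list(
      clonotypes = data.frame(clonotype_id = character(0),
                              alpha_cdr3 = character(0),
                              beta_cdr3 = character(0),
                              n_cells = integer(0)),
      cells = data.frame(cell_id = character(0), clonotype_id = character(0)),
      excluded = excluded), class = "clonotype_set"))
  }
  keys$key <- paste(keys$alpha, keys$beta, sep = "|")
  sizes <- keys[, list(n_cells = .N), by = c("key", "alpha", "beta")]
  sizes <- sizes[order(-sizes$n_cells, sizes$key)]
  sizes$clonotype_id <- sprintf("CT%05d", seq_len(nrow(sizes)))
  cells <- merge(keys[, c("cell_id", "key")],
                 sizes[, c("key", "clonotype_id")], by = "key")
  cells <- cells[order(cells$cell_id)]
  structure(list(
    clonotypes = data.frame(clonotype_id = sizes$clonotype_id,
                            alpha_cdr3 = sizes$alpha, beta_cdr3 = sizes$beta,
                            n_cells = sizes$n_cells, stringsAsFactors = FALSE),
    cells = data.frame(cell_id = cells$cell_id,
                       clonotype_id = cells$clonotype_id,
                       stringsAsFactors = FALSE),
    excluded = excluded
  ), class = "clonotype_set")
}

# Long table: one row per (clonotype, locus, cdr3 string).
clonotype_chains <- function(ct) {
  cl <- ct$clonotypes
  a <- strsplit(cl$alpha_cdr3, ";", fixed = TRUE)
  b <- strsplit(cl$beta_cdr3, ";", fixed = TRUE)
  data.frame(
    clonotype_id = c(rep(cl$clonotype_id, lengths(a)),
                     rep(cl$clonotype_id, lengths(b))),
    locus = c(rep("TRA", sum(lengths(a))), rep("TRB", sum(lengths(b)))),
    cdr3 = c(unlist(a), unlist(b)),
    stringsAsFactors = FALSE
  )
}

#' Clonal expansion summary
#'
#' Size-class counts over assigned clonotypes: singletons, clones in three
#' or more cells, clones in more than ten cells, and the maximum clone
#' size.  With per-cell metadata, also the number of clones seen in at
#' least two samples and the number spanning diabetic and non-diabetic
#' samples.
#'
#' @param ct a `clonotype_set`.
#' @param meta optional per-cell data.frame with `cell_id`, `sample`,
#'   `disease`.
#' @return one-row data.frame of summary counts.
#' @export
expansion_summary <- function(ct, meta = NULL) {
  sz <- ct$clonotypes$n_cells
  out <- data.frame(
    n_clonotypes = length(sz),
    n_cells = sum(sz),
    n_singletons = sum(sz == 1),
    n_ge3 = sum(sz >= 3),
    n_gt10 = sum(sz > 10),
    max_size = if (length(sz)) max(sz) else 0L
  )
  if (!is.null(meta) && nrow(ct$cells) > 0) {
    m <- merge(ct$cells, meta, by = "cell_id")
    bys <- tapply(m$sample, m$clonotype_id, function(x) length(unique(x)))
    byd <- tapply(m$disease, m$clonotype_id, function(x) length(unique(x)))
    out$n_in_ge2_samples <- sum(bys >= 2)
    out$n_spanning_disease <- sum(byd >= 2)
  } else if (!is.null(meta)) {
    out$n_in_ge2_samples <- 0L
    out$n_spanning_disease <- 0L
  }
  out
}

#' Match clones between blood and islets (infiltration calls)
#'
#' Two cells match if they share at least one identical alpha CDR3
#' amino-acid string or one identical beta CDR3 string.  A blood cell is
#' islet-matching (infiltrating) iff it matches at least one islet cell,
#' and symmetrically.  In strict mode a shared chain must also agree on
#' V and J gene, which requires `v_gene`/`j_gene` columns in `chains`.
#'
#' @param ct a `clonotype_set`.
#' @param tissue per-cell tissue labels (`"blood"`/`"islet"`), named by
#'   cell id or aligned with `ct$cells$cell_id`.
#' @return list: `cell_flags` (data.frame `cell_id`, `tissue`,
#'   `infiltrating`), `matched_chains` (each cross-tissue chain-sharing
#'   group with per-tissue cell counts), `matched_clonotypes` (clonotype
#'   ids containing at least one matching cell).
#' @export
match_tissues <- function(ct, tissue) {
  cells <- ct$cells
  tis <- if (!is.null(names(tissue))) unname(tissue[cells$cell_id])
         else tissue
  if (anyNA(tis)) stop_config("every clonotype member needs a tissue label")
  long <- merge(clonotype_chains(ct), cells, by = "clonotype_id",
                allow.cartesian = TRUE)
  long$tissue <- if (!is.null(names(tissue))) unname(tissue[long$cell_id])
                 else tis[match(long$cell_id, cells$cell_id)]
  key <- paste(long$locus, long$cdr3)
  span <- tapply(long$tissue, key, function(x) length(unique(x)) >= 2)
  long$spans <- unname(span[key])
  flag <- tapply(long$spans, long$cell_id, any)
  cell_flags <- data.frame(cell_id = cells$cell_id, tissue = tis,
                           infiltrating = unname(flag[cells$cell_id]),
                           stringsAsFactors = FALSE)
  mk <- long[long$spans, , drop = FALSE]
  if (nrow(mk)) {
    dtm <- data.table::data.table(locus = mk$locus, cdr3 = mk$cdr3,
                                  tissue = mk$tissue, cell_id = mk$cell_id)
    dtm <- unique(dtm)
    matched_chains <- as.data.frame(dtm[, list(
      n_blood = sum(.SD$tissue == "blood"),
      n_islet = sum(.SD$tissue == "islet")
    ), by = c("locus", "cdr3")])
    matched_chains <- matched_chains[order(matched_chains$locus,
                                           matched_chains$cdr3), ]
    rownames(matched_chains) <- NULL
  } else {
    matched_chains <- data.frame(locus = character(0), cdr3 = character(0),
                                 n_blood = integer(0), n_islet = integer(0))
  }
  matched_clonotypes <- sort(unique(mk$clonotype_id))
  list(cell_flags = cell_flags, matched_chains = matched_chains,
       matched_clonotypes = matched_clonotypes)
}

#' Classify the fate of each clone from member states
#'
#' A clone is `SLEC_only` if it has at least one member in a SLEC-like
#' state and none in an exhausted (Texh) state, `Texh_only` symmetrically,
#' `mixed` if it has members in both, `other` if in neither.
#'
#' @param ct a `clonotype_set`.
#' @param states per-cell state labels named by cell id.
#' @param slec_states state labels counting as SLEC-like.
#' @param texh_states state labels counting as terminally exhausted.
#' @return data.frame `clonotype_id`, `n_cells`, `fate`.
#' @export
classify_clone_fate <- function(ct, states, slec_states, texh_states) {
  m <- ct$cells
  st <- states[m$cell_id]
  if (anyNA(st)) stop_config("unlabeled clone member cell(s)")
  has_slec <- tapply(st %in% slec_states, m$clonotype_id, any)
  has_texh <- tapply(st %in% texh_states, m$clonotype_id, any)
  ids <- names(has_slec)
  fate <- ifelse(has_slec & has_texh, "mixed",
          ifelse(has_slec, "SLEC_only",
          ifelse(has_texh, "Texh_only", "other")))
  out <- data.frame(clonotype_id = ids, fate = unname(fate[ids]),
                    stringsAsFactors = FALSE)
  out <- merge(out, ct$clonotypes[, c("clonotype_id", "n_cells")],
               by = "clonotype_id")
  out[order(out$clonotype_id), c("clonotype_id", "n_cells", "fate")]
}

transition_aggregate <- function(per_clone, compartment_of) {
  if (length(per_clone) == 0) {
    warning("no clone exceeds the size threshold; empty transition graph")
    return(structure(list(
      edges = data.frame(state_a = character(0), state_b = character(0),
                         likelihood = numeric(0), edge_type = character(0),
                         n_clones_observed = integer(0)),
      n_clones = 0L), class = "transition_graph"))
  }
  all_pairs <- sort(unique(unlist(lapply(per_clone, names))))
  acc <- setNames(numeric(length(all_pairs)), all_pairs)
  nobs <- setNames(integer(length(all_pairs)), all_pairs)
  for (p in per_clone) {
    acc[names(p)] <- acc[names(p)] + p
    nobs[names(p)] <- nobs[names(p)] + (p > 0)
  }
  mean_lik <- acc / length(per_clone)
  sp <- strsplit(all_pairs, "\r", fixed = TRUE)
  a <- vapply(sp, `[`, character(1), 1)
  b <- vapply(sp, `[`, character(1), 2)
  edge_type <- rep(NA_character_, length(a))
  if (!is.null(compartment_of)) {
    edge_type <- ifelse(compartment_of[a] == compartment_of[b],
                        "within_compartment", "cross_compartment")
  }
  structure(list(
    edges = data.frame(state_a = a, state_b = b, likelihood = unname(mean_lik),
                       edge_type = unname(edge_type),
                       n_clones_observed = unname(nobs),
                       stringsAsFactors = FALSE),
    n_clones = length(per_clone)), class = "transition_graph")
}

eligible_clone_states <- function(ct, states, min_clone_size_exclusive) {
  m <- ct$cells
  st <- states[m$cell_id]
  if (anyNA(st)) stop_config("unlabeled clone member cell(s)")
  by_clone <- split(as.character(st), m$clonotype_id)
  by_clone[lengths(by_clone) > min_clone_size_exclusive]
}

pair_key <- function(s1, s2) {
  paste(pmin(s1, s2), pmax(s1, s2), sep = "\r")
}

#' Exact within-clone pair-transition likelihoods
#'
#' For every clone above the size threshold, the probability that a
#' uniformly drawn unordered pair of distinct member cells shows each
#' unordered state-label pair, computed by enumerating all C(n,2) pairs.
#' Edge weights are means over eligible clones (clones without a pair
#' contribute zero); per-clone likelihoods sum to one.
#'
#' @param ct a `clonotype_set`.
#' @param states per-cell state labels named by cell id.
#' @param min_clone_size_exclusive clones must be strictly larger than this.
#' @param compartment_of optional named map state -> compartment, used to
#'   color edges within vs. across compartments.
#' @return `transition_graph`: `edges` data.frame (`state_a`, `state_b`,
#'   `likelihood`, `edge_type`, `n_clones_observed`) and `n_clones`.
#' @export
exact_transitions <- function(ct, states, min_clone_size_exclusive = 3L,
                              compartment_of = NULL) {
  by_clone <- eligible_clone_states(ct, states, min_clone_size_exclusive)
  per_clone <- lapply(by_clone, function(st) {
    n <- length(st)
    tab <- table(st)
    labs <- names(tab)
    cnt <- as.integer(tab)
    keys <- character(0); w <- numeric(0)
    for (i in seq_along(labs)) {
      if (cnt[i] >= 2) {
        keys <- c(keys, pair_key(labs[i], labs[i]))
        w <- c(w, choose(cnt[i], 2))
      }
      if (i < length(labs)) for (j in (i + 1):length(labs)) {
        keys <- c(keys, pair_key(labs[i], labs[j]))
        w <- c(w, cnt[i] * cnt[j])
      }
    }
    setNames(w / choose(n, 2), keys)
  })
  transition_aggregate(per_clone, compartment_of)
}

#' Bootstrap within-clone pair-transition likelihoods
#'
#' For every clone above the size threshold, `n_reps` unordered pairs of
#' distinct member cells are drawn uniformly (with replacement across
#' draws); the per-clone likelihood of each unordered state pair is the
#' fraction of draws showing it.  Edge weights are means over eligible
#' clones.  [exact_transitions()] is the enumeration counterpart this
#' estimator converges to.
#'
#' @inheritParams exact_transitions
#' @param n_reps pair draws per clone.
#' @param seed RNG seed.
#' @return `transition_graph` (see [exact_transitions()]).
#' @export
bootstrap_transitions <- function(ct, states, n_reps = 100L,
                                  min_clone_size_exclusive = 3L, seed = 1L,
                                  compartment_of = NULL) {
  by_clone <- eligible_clone_states(ct, states, min_clone_size_exclusive)
  set.seed(seed)
  per_clone <- lapply(by_clone, function(st) {
    n <- length(st)
    keys <- vapply(seq_len(n_reps), function(r) {
      ij <- sample.int(n, 2L)
      pair_key(st[ij[1]], st[ij[2]])
    }, character(1))
    tab <- table(keys)
    setNames(as.numeric(tab) / n_reps, names(tab))
  })
  transition_aggregate(per_clone, compartment_of)
}

#' Annotate clonotypes with epitopes by exact CDR3 match
#'
#' A clonotype is annotated with every reference epitope whose CDR3
#' amino-acid string exactly equals (string identity after uppercasing)
#' any of the clonotype's alpha or beta CDR3s, honoring the reference
#' record's chain (TRA records match alpha chains, TRB records beta; rows
#' without a chain match either).
#'
#' @param ct a `clonotype_set`.
#' @param vdjdb reference table from [read_vdjdb()].
#' @param meta optional per-cell data.frame with `cell_id` and `tissue`,
#'   enabling per-epitope per-tissue cell counts.
#' @return list: `annotations` (clonotype_id, locus, cdr3, epitope,
#'   species) and, with `meta`, `epitope_counts` (epitope, tissue,
#'   n_cells).
#' @export
annotate_epitopes <- function(ct, vdjdb, meta = NULL) {
  chains <- clonotype_chains(ct)
  ref <- vdjdb
  ref$cdr3 <- toupper(ref$cdr3)
  hits <- merge(chains, ref, by = "cdr3", allow.cartesian = TRUE,
                suffixes = c("", ".ref"))
  if ("locus.ref" %in% names(hits)) {
    ok <- is.na(hits$locus.ref) | hits$locus.ref == "" |
      hits$locus.ref == hits$locus
    hits <- hits[ok, , drop = FALSE]
  }
  annotations <- unique(data.frame(
    clonotype_id = hits$clonotype_id, locus = hits$locus, cdr3 = hits$cdr3,
    epitope = hits$epitope, species = hits$species, stringsAsFactors = FALSE))
  annotations <- annotations[order(annotations$clonotype_id,
                                   annotations$locus, annotations$cdr3,
                                   annotations$epitope), , drop = FALSE]
  rownames(annotations) <- NULL
  out <- list(annotations = annotations)
  if (!is.null(meta) && nrow(annotations)) {
    mem <- merge(ct$cells, meta[, c("cell_id", "tissue")], by = "cell_id")
    ec <- merge(unique(annotations[, c("clonotype_id", "epitope")]), mem,
                by = "clonotype_id")
    tab <- as.data.frame(table(epitope = ec$epitope, tissue = ec$tissue),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "n_cells"
    out$epitope_counts <- tab[tab$n_cells > 0 | TRUE, , drop = FALSE]
  } else if (!is.null(meta)) {
    out$epitope_counts <- data.frame(epitope = character(0),
                                     tissue = character(0),
                                     n_cells = integer(0))
  }
  out
}
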