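test_that("clonotype keys merge equal chain sets and split unequal ones", {
  ch <- rbind(
    chain_row("x", "TRA", "CAVSAF"), chain_row("x", "TRB", "CASSLGF"),
    chain_row("y", "TRA", "CAVSAF"), chain_row("y", "TRB", "CASSLGF"),
    chain_row("z", "TRA", "CAVSAF"), chain_row("z", "TRB", "CASSQDF")
  )
  ct <- assign_clonotypes(ch)
  expect_identical(nrow(ct$clonotypes), 2L)
  map <- setNames(ct$cells$clonotype_id, ct$cells$cell_id)
  expect_identical(map[["x"]], map[["y"]])
  expect_false(map[["x"]] == map[["z"]])
  expect_identical(ct$clonotypes$n_cells[ct$clonotypes$clonotype_id == map[["x"]]], 2L)
})

test_that("cells lacking an alpha or beta chain are excluded", {
  ch <- rbind(
    chain_row("full", "TRA", "CAAF"), chain_row("full", "TRB", "CBBF"),
    chain_row("beta_only", "TRB", "CBBF"),
    chain_row("alpha_only", "TRA", "CAAF"),
    chain_row("gd_cell", "TRG", "CGGF"), chain_row("gd_cell", "TRD", "CDDF")
  )
  ct <- assign_clonotypes(ch)
  expect_identical(ct$cells$cell_id, "full")
  expect_setequal(ct$excluded, c("beta_only", "alpha_only", "gd_cell"))
})

test_that("multi-chain cells match only on full set equality", {
  ch <- rbind(
    chain_row("m1", "TRA", "CA1F"), chain_row("m1", "TRA", "CA2F"),
    chain_row("m1", "TRB", "CB1F"),
    chain_row("m2", "TRA", "CA2F"), chain_row("m2", "TRA", "CA1F"),
    chain_row("m2", "TRB", "CB1F"),
    chain_row("m3", "TRA", "CA1F"), chain_row("m3", "TRB", "CB1F")
  )
  ct <- assign_clonotypes(ch)
  map <- setNames(ct$cells$clonotype_id, ct$cells$cell_id)
  expect_identical(map[["m1"]], map[["m2"]])  # same sets, any order
  expect_false(map[["m1"]] == map[["m3"]])    # subset is not equality
  # assignment is independent of row order
  ct2 <- assign_clonotypes(ch[rev(seq_len(nrow(ch))), ])
  map2 <- setNames(ct2$cells$clonotype_id, ct2$cells$cell_id)
  expect_identical(map2[["m1"]], map2[["m2"]])
  expect_false(map2[["m1"]] == map2[["m3"]])
})

test_that("expansion summary counts size classes like a brute-force tally", {
  mk <- function(id, n) do.call(rbind, lapply(seq_len(n), function(i)
    rbind(chain_row(paste0(id, i), "TRA", paste0("CA", id, "F")),
          chain_row(paste0(id, i), "TRB", paste0("CB", id, "F")))))
  ch <- rbind(mk("a", 1), mk("b", 1), mk("c", 3), mk("d", 12))
  es <- expansion_summary(assign_clonotypes(ch))
  expect_identical(es$n_singletons, 2L)
  expect_identical(es$n_ge3, 2L)
  expect_identical(es$n_gt10, 1L)
  expect_identical(es$max_size, 12L)
  # empty input
  es0 <- expansion_summary(assign_clonotypes(chain_row("solo", "TRA", "CAF")))
  expect_identical(es0$n_clonotypes, 0L)
  expect_identical(es0$max_size, 0L)
})

test_that("expansion summary on a cohort equals an independent tally", {
  co <- generate_cohort(small_cohort_config(seed = 27, n_samples = 2,
                                            cells_per_sample = 300,
                                            shared_clone_count = 10,
                                            disease_of_sample = c(S1 = "diabetic",
                                                                  S2 = "diabetic")))
  ct <- assign_clonotypes(co$chains)
  es <- expansion_summary(ct, co$meta)
  # oracle: group truth cells by clone over alpha/beta-paired cells
  ab <- co$chains[co$chains$locus %in% c("TRA", "TRB"), ]
  paired <- intersect(ab$cell_id[ab$locus == "TRA"], ab$cell_id[ab$locus == "TRB"])
  truth <- co$truth$cells[co$truth$cells$cell_id %in% paired, ]
  sizes <- as.integer(table(truth$clone_id))
  expect_identical(es$n_clonotypes, length(sizes))
  expect_identical(es$n_singletons, sum(sizes == 1))
  expect_identical(es$n_ge3, sum(sizes >= 3))
  expect_identical(es$n_gt10, sum(sizes > 10))
  expect_identical(es$n_cells, length(paired))
})

test_that("tissue matching flags cells sharing one chain across tissues", {
  ch <- rbind(
    chain_row("b1", "TRA", "CAVSAF"), chain_row("b1", "TRB", "CBX1F"),
    chain_row("i1", "TRA", "CAVSAF"), chain_row("i1", "TRB", "CBX2F"),
    chain_row("b2", "TRA", "CAOTHERF"), chain_row("b2", "TRB", "CBX3F"),
    chain_row("i2", "TRA", "CANOPEF"), chain_row("i2", "TRB", "CBX4F")
  )
  tissue <- c(b1 = "blood", b2 = "blood", i1 = "islet", i2 = "islet")
  ct <- assign_clonotypes(ch)
  res <- match_tissues(ct, tissue)
  flags <- setNames(res$cell_flags$infiltrating, res$cell_flags$cell_id)
  expect_true(flags[["b1"]]); expect_true(flags[["i1"]])
  expect_false(flags[["b2"]]); expect_false(flags[["i2"]])
  expect_identical(res$matched_chains$cdr3, "CAVSAF")
  # symmetry: both sides of a match are flagged
  expect_identical(sum(flags), 2L)
  # single tissue: no matches, no error
  res1 <- match_tissues(ct, setNames(rep("blood", 4), names(tissue)))
  expect_identical(sum(res1$cell_flags$infiltrating), 0L)
})

test_that("matching equals the O(n^2) brute force on small cohorts", {
  for (seed in c(101, 102)) {
    co <- generate_cohort(small_cohort_config(seed = seed, n_samples = 2,
                                              cells_per_sample = 120,
                                              shared_clone_count = 8,
                                              disease_of_sample = c(S1 = "diabetic",
                                                                    S2 = "diabetic")))
    tissue <- setNames(co$meta$tissue, co$meta$cell_id)
    ct <- assign_clonotypes(co$chains)
    res <- match_tissues(ct, tissue)
    flagged <- sort(res$cell_flags$cell_id[res$cell_flags$infiltrating])
    oracle <- brute_force_matches(co$chains, tissue)
    expect_identical(flagged, oracle)
  }
})

test_that("clone fates classify SLEC-only, Texh-only, mixed and other", {
  mk <- function(id, n) do.call(rbind, lapply(seq_len(n), function(i)
    rbind(chain_row(paste0(id, i), "TRA", paste0("CA", id, "F")),
          chain_row(paste0(id, i), "TRB", paste0("CB", id, "F")))))
  ch <- rbind(mk("s", 3), mk("t", 2), mk("m", 2), mk("o", 2))
  ct <- assign_clonotypes(ch)
  states <- c(s1 = "Teff", s2 = "SLEC", s3 = "SLEC",
              t1 = "Texh", t2 = "Texh",
              m1 = "SLEC", m2 = "Texh",
              o1 = "naive", o2 = "Teff")
  fates <- classify_clone_fate(ct, states, "SLEC", "Texh")
  map <- setNames(ct$cells$clonotype_id, ct$cells$cell_id)
  got <- setNames(fates$fate, fates$clonotype_id)
  expect_identical(unname(got[map[c("s1", "t1", "m1", "o1")]]),
                   c("SLEC_only", "Texh_only", "mixed", "other"))
  expect_error(classify_clone_fate(ct, states[-1], "SLEC", "Texh"),
               "unlabeled")
})

make_single_clone <- function(states) {
  n <- length(states)
  ch <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(chain_row(paste0("c", i), "TRA", "CAAAF"),
          chain_row(paste0("c", i), "TRB", "CBBBF"))))
  list(ct = assign_clonotypes(ch),
       states = setNames(states, paste0("c", seq_len(n))))
}

test_that("exact transitions enumerate unordered pairs", {
  # clone {A,A,B}: 3 pairs -> A-A 1/3, A-B 2/3 (size threshold lowered)
  x <- make_single_clone(c("A", "A", "B"))
  g <- exact_transitions(x$ct, x$states, min_clone_size_exclusive = 2)
  lik <- setNames(g$edges$likelihood, paste(g$edges$state_a, g$edges$state_b))
  expect_equal(lik[["A A"]], 1 / 3)
  expect_equal(lik[["A B"]], 2 / 3)
  expect_equal(sum(g$edges$likelihood), 1)
  # homogeneous clone: self-pair likelihood 1
  h <- make_single_clone(rep("A", 5))
  gh <- exact_transitions(h$ct, h$states)
  expect_equal(gh$edges$likelihood, 1)
  expect_identical(gh$edges$state_a, "A")
})

test_that("clones at or below the size threshold are ineligible", {
  x <- make_single_clone(c("A", "B"))
  expect_warning(g <- exact_transitions(x$ct, x$states), "threshold")
  expect_identical(nrow(g$edges), 0L)
  y <- make_single_clone(c("A", "A", "B"))  # size 3 is not > 3
  expect_warning(exact_transitions(y$ct, y$states), "threshold")
})

test_that("bootstrap transitions are unbiased estimates of the exact values", {
  x <- make_single_clone(c("A", "A", "B", "B"))
  exact <- exact_transitions(x$ct, x$states)
  lik_ex <- setNames(exact$edges$likelihood,
                     paste(exact$edges$state_a, exact$edges$state_b))
  expect_equal(lik_ex[["A B"]], 4 / 6)
  ests <- vapply(1:200, function(s) {
    g <- bootstrap_transitions(x$ct, x$states, n_reps = 100, seed = s)
    lk <- setNames(g$edges$likelihood, paste(g$edges$state_a, g$edges$state_b))
    lk[["A B"]]
  }, numeric(1))
  p <- 4 / 6
  expect_lt(abs(mean(ests) - p), 0.01)
  # individual estimates concentrate within 3 binomial SEs
  expect_gt(mean(abs(ests - p) <= 3 * sqrt(p * (1 - p) / 100)), 0.98)
})

test_that("bootstrap converges to the exact enumeration as reps grow", {
  x <- make_single_clone(c("A", "A", "A", "B", "C"))
  exact <- exact_transitions(x$ct, x$states)
  boot <- bootstrap_transitions(x$ct, x$states, n_reps = 10000, seed = 2)
  m <- merge(exact$edges, boot$edges, by = c("state_a", "state_b"))
  expect_lt(max(abs(m$likelihood.x - m$likelihood.y)), 0.02)
})

test_that("edge colors separate within- from cross-compartment transitions", {
  mk <- function(id, n) do.call(rbind, lapply(seq_len(n), function(i)
    rbind(chain_row(paste0(id, i), "TRA", paste0("CA", id, "F")),
          chain_row(paste0(id, i), "TRB", paste0("CB", id, "F")))))
  ch <- rbind(mk("p", 5))
  ct <- assign_clonotypes(ch)
  states <- setNames(c("CD4.naive", "CD4.eff", "CD4.eff", "DN.eff", "DN.eff"),
                     paste0("p", 1:5))
  comp_of <- c(CD4.naive = "CD4", CD4.eff = "CD4", DN.eff = "DN")
  g <- exact_transitions(ct, states, compartment_of = comp_of)
  type <- setNames(g$edges$edge_type, paste(g$edges$state_a, g$edges$state_b))
  expect_identical(type[["CD4.eff CD4.naive"]], "within_compartment")
  expect_identical(type[["CD4.eff DN.eff"]], "cross_compartment")
})

test_that("epitope annotation is exact, chain-aware and case-canonical", {
  ch <- rbind(chain_row("c1", "TRA", "CAVSAF"),
              chain_row("c1", "TRB", "CASSIRSSYEQYF"),
              chain_row("c2", "TRA", "CAVSXF"),
              chain_row("c2", "TRB", "CASSIRSSYEQYG"))
  ct <- assign_clonotypes(ch)
  vdjdb <- data.frame(
    cdr3 = c("cassirssyeqyf", "CAVSAF", "CAVSAF"),
    locus = c("TRB", "TRB", "TRA"),
    epitope = c("M45", "wrong_chain", "NP"),
    species = "MusMusculus")
  ann <- annotate_epitopes(ct, vdjdb)$annotations
  map <- setNames(ct$cells$clonotype_id, ct$cells$cell_id)
  hits <- ann[ann$clonotype_id == map[["c1"]], ]
  expect_setequal(hits$epitope, c("M45", "NP"))   # lowercase ref matched
  expect_false("wrong_chain" %in% ann$epitope)    # TRB record vs alpha chain
  # off-by-one CDR3 (c2) finds nothing
  expect_false(map[["c2"]] %in% ann$clonotype_id)
  # per-tissue counts
  meta <- data.frame(cell_id = c("c1", "c2"), tissue = c("blood", "islet"))
  res <- annotate_epitopes(ct, vdjdb, meta)
  counts <- res$epitope_counts
  expect_identical(counts$n_cells[counts$epitope == "M45" &
                                  counts$tissue == "blood"], 1L)
})

test_that("clone sizes conserve the number of alpha+beta cells", {
  co <- generate_cohort(small_cohort_config(seed = 33, n_samples = 2,
                                            cells_per_sample = 250,
                                            shared_clone_count = 10,
                                            disease_of_sample = c(S1 = "diabetic",
                                                                  S2 = "diabetic")))
  ct <- assign_clonotypes(co$chains)
  ab <- co$chains[co$chains$locus %in% c("TRA", "TRB"), ]
  paired <- intersect(ab$cell_id[ab$locus == "TRA"],
                      ab$cell_id[ab$locus == "TRB"])
  expect_identical(sum(ct$clonotypes$n_cells), length(paired))
  expect_identical(nrow(ct$cells), length(paired))
})
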