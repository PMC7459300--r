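test_that("truncating percentage formatter reproduces printed summaries", {
  expect_equal(percent_floor(112, 1898, 1), 5.9)
  expect_equal(percent_floor(17, 1760, 2), 0.96)
  expect_equal(percent_floor(359, 1665, 0), 21)
  expect_equal(percent_floor(204, 1898, 1), 10.7)
  expect_equal(percent_floor(253, 2775, 1), 9.1)
  expect_equal(percent_floor(86, 100, 0), 86)
})

test_that("clonotype table counts cells per key and cluster", {
  chains <- chain_tbl(
    list("a-1", "TRA", "TRAV11", "TRAJ18", "TGTGCTTTT"),
    list("b-1", "TRA", "TRAV11", "TRAJ18", "TGTGCTTTT"),
    list("c-1", "TRA", "TRAV11", "TRAJ18", "TGTAAATTT")
  )
  cl <- c("a-1" = "N1", "b-1" = "N4", "c-1" = "N4")
  tab <- build_clonotype_table(chains, clusters = cl)
  expect_equal(nrow(tab), 2)
  expect_equal(sort(tab$n_cells), c(1, 2))
  # per-cluster counts sum to totals
  cols <- attr(tab, "cluster_cols")
  expect_equal(rowSums(tab[, cols]), tab$n_cells, ignore_attr = TRUE)
  expect_equal(sum(tab$n_cells), 3)
})

test_that("clonotype table equals a brute-force dictionary build", {
  co <- small_cohort(seed = 29, n = 80)
  chains <- cell_chains(usable_contigs(co$contigs))
  tab <- build_clonotype_table(chains)

  # oracle: hash map from per-cell sorted chain strings
  dict <- new.env()
  for (bc in unique(chains$barcode)) {
    sub <- chains[chains$barcode == bc, ]
    key <- paste(sort(paste(sub$chain, sub$v_gene, sub$j_gene, sub$cdr3_nt,
                            sep = ":")), collapse = ";")
    dict[[key]] <- (dict[[key]] %||% 0L) + 1L
  }
  oracle <- sort(unlist(as.list(dict)), decreasing = TRUE)
  expect_equal(nrow(tab), length(oracle))
  expect_equal(sum(tab$n_cells), sum(oracle))
  expect_identical(
    unname(oracle[tab$clonotype_key]),
    as.integer(tab$n_cells)
  )
})

test_that("repeat spectrum conserves clonotypes and cells", {
  tab <- tibble::tibble(
    clonotype_key = sprintf("k%03d", 1:100),
    n_cells = c(rep(1, 86), rep(2, 10), rep(4, 4))
  )
  spec <- repeat_spectrum(tab)
  expect_equal(sum(spec$n_clonotypes), 100)
  expect_equal(sum(spec$n_cells), 86 + 20 + 16)
  expect_equal(spec$norm_clonotypes, spec$n_clonotypes / 100)
  s <- spectrum_summary(spec)
  expect_equal(s$pct_singleton_clonotypes, 86)
  expect_equal(s$n_repeat_gt, 4)   # size > 3 means size 4 here
  expect_error(repeat_spectrum(tab[0, ]), "empty")
})

test_that("Shannon equitability matches hand computations and conventions", {
  expect_equal(shannon_equitability(c(5, 5, 5, 5)), 1.0)
  expect_equal(shannon_equitability(10), 0)
  expect_equal(shannon_equitability(c(2, 1, 1)), 0.9464, tolerance = 1e-4)
  expect_error(shannon_equitability(numeric(0)), "empty")
  expect_error(shannon_equitability(c(1, 0)), "positive")
})

test_that("equitability is permutation- and scale-invariant", {
  withr::with_seed(101, {
    for (i in 1:20) {
      counts <- sample(1:50, sample(2:15, 1), replace = TRUE)
      e <- shannon_equitability(counts)
      expect_gte(e, 0); expect_lte(e, 1 + 1e-12)
      expect_equal(shannon_equitability(sample(counts)), e)
      expect_equal(shannon_equitability(counts * 7), e)
    }
  })
})

test_that("cluster sharing finds cross-region clonotypes", {
  chains <- chain_tbl(
    list("a-1", "TRG", "TRGV6", "TRGJ1", "TGTGCTTTT"),
    list("b-1", "TRG", "TRGV6", "TRGJ1", "TGTGCTTTT"),
    list("c-1", "TRG", "TRGV6", "TRGJ1", "TGTGCTTTT"),
    list("d-1", "TRG", "TRGV6", "TRGJ1", "TGTGCTTTT"),
    list("e-1", "TRG", "TRGV6", "TRGJ1", "TGTGCTTTT"),
    list("f-1", "TRG", "TRGV4", "TRGJ1", "TGTAAATTT"),
    list("g-1", "TRG", "TRGV7", "TRGJ1", "TGTCCCTTT")
  )
  cl <- c("a-1" = "G4", "b-1" = "G4", "c-1" = "G6", "d-1" = "G6",
          "e-1" = "G6", "f-1" = "G4", "g-1" = "G6")
  tab <- build_clonotype_table(chains, clusters = cl)
  res <- cluster_sharing(tab, "G4", "G6")
  expect_equal(res$summary$n_shared, 1)
  expect_equal(res$summary$total_repeats, 5)  # 2 in G4 + 3 in G6
  # 5 shared-cells of 7 total = 71.4 -> 71 truncated
  expect_equal(res$summary$pct_total_cells, 71)
  # repetitive cells: only the size-5 clone, so 5/5 = 100
  expect_equal(res$summary$pct_repetitive_cells, 100)
  expect_error(cluster_sharing(tab, "G4", "nope"), "unknown")
  expect_error(cluster_sharing(tab, "G4", "G4"), "disjoint")

  disjoint <- cluster_sharing(
    build_clonotype_table(chains[6:7, ], clusters = cl), "G4", "G6")
  expect_equal(nrow(disjoint$shared), 0)
})

test_that("CDR3 length histogram partitions cells correctly", {
  chains <- chain_tbl(
    list("a-1", "TRA", "TRAV11", "TRAJ18", "TGTGCTTTT", "CVVGDRGSALGRLHF"),
    list("b-1", "TRA", "TRAV11", "TRAJ18", "TGTAAATTT", "CVVGDRGSALGRLHF"),
    list("c-1", "TRA", "TRAV10", "TRAJ50", "TGTCCCTTT", "CAMREGF"),
    list("d-1", "TRA", "TRAV13-1", "TRAJ25", "TGTCCCAAA", "CAMSNTF"),
    list("e-1", "TRA", "TRAV11", "TRAJ18", "TGTCCGTTT", "CVVGDRGSALGRLHF"),
    list("f-1", "TRB", "TRBV29", "TRBJ2-1", "TGTTTTAAA", "CASSF")
  )
  h <- cdr3_length_hist(chains, "TRA")
  # oracle: manual count of the five TRA sequences
  expect_equal(h$n[h$length == 15], 3)
  expect_equal(sum(h$n), 5)

  hc <- cdr3_length_hist(chains, "TRA", by = "canonical", type = "iNKT")
  expect_equal(sum(hc$n), 5)  # partition conserves cells
  expect_equal(sum(hc$n[hc$group == "canonical"]), 3)
  expect_equal(sum(hc$n[hc$group == "non_canonical"]), 2)

  one_len <- cdr3_length_hist(chains[1:2, ], "TRA")
  expect_equal(nrow(one_len), 1)
  expect_equal(one_len$n, 2)
})

test_that("composition logo uses the modal length and sums to one", {
  lg <- composition_logo(c("CAR", "CAK"))
  expect_equal(lg$modal_length, 3)
  expect_equal(unname(lg$freq[3, c("R", "K")]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(lg$freq) - 1) < 1e-9))

  same <- composition_logo(rep("CVVGDRGSALGRLHF", 4))
  expect_true(all(apply(same$freq, 1, max) == 1))

  expect_message(tie <- composition_logo(c("CAR", "CAKF")), "tie")
  expect_equal(tie$modal_length, 3)
  expect_error(composition_logo(character(0)), "no sequences")
})

test_that("hydropathy classes follow the WebLogo scheme", {
  expect_equal(hydropathy_class("D"), "hydrophilic")
  expect_equal(hydropathy_class(c("G", "W")), c("neutral", "hydrophobic"))
})

test_that("canonical classification flags alpha and beta usage", {
  chains <- chain_tbl(
    list("canon-1", "TRA", "TRAV11", "TRAJ18"),
    list("canon-1", "TRB", "TRBV29", "TRBJ2-1"),
    list("nca-1", "TRA", "TRAV10", "TRAJ50"),
    list("nca-1", "TRB", "TRBV13-1", "TRBJ2-1"),
    list("nob-1", "TRA", "TRAV11", "TRAJ18"),
    list("nob-1", "TRB", "TRBV3", "TRBJ2-1"),
    list("both-1", "TRA", "TRAV10", "TRAJ50"),
    list("both-1", "TRB", "TRBV3", "TRBJ2-1"),
    list("nobeta-1", "TRA", "TRAV11", "TRAJ18")
  )
  fl <- classify_canonical(chains, type = "iNKT")
  got <- stats::setNames(fl$class, fl$barcode)
  expect_equal(unname(got[c("canon-1", "nca-1", "nob-1", "both-1")]),
               c("canonical_only", "nc_alpha_only", "nob_beta_only", "both"))
  expect_equal(unname(got["nobeta-1"]), "canonical_only")
  expect_true(is.na(fl$oligoclonal_beta[fl$barcode == "nobeta-1"]))

  # Venn partition is exhaustive and disjoint over TRA-bearing cells
  v <- venn_counts(fl)
  expect_equal(v$canonical_only + v$nc_alpha_only + v$nob_beta_only + v$both,
               v$n_cells)

  cl <- stats::setNames(rep("M1", 5),
                        c("canon-1", "nca-1", "nob-1", "both-1", "nobeta-1"))
  frac <- noncanonical_fraction(fl, cl)
  expect_equal(frac$n_noncanonical[frac$cluster == "all"], 3)
  # exclusion re-analysis drops the dual non-canonical cells
  frac2 <- noncanonical_fraction(fl, cl, exclude_both = TRUE)
  expect_equal(frac2$n_cells[frac2$cluster == "all"], 4)
  expect_equal(frac2$n_noncanonical[frac2$cluster == "all"], 2)
})
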