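yv <- function(...) {
  x <- c(...)
  stats::setNames(as.numeric(x), names(x))
}

test_that("first-pass TCR rules assign the three lineages", {
  chains <- chain_tbl(
    list("inkt-1", "TRA", "TRAV11", "TRAJ18"),
    list("inktD-1", "TRA", "TRAV11D*01", "TRAJ18"),
    list("mait-1", "TRA", "TRAV1", "TRAJ33"),
    list("maleM-1", "TRA", "TRAV1", "TRAJ33"),
    list("gd-1", "TRG", "TRGV6", "TRGJ1"),
    list("gd-1", "TRD", "TRDV4", "TRDJ1"),
    list("gonly-1", "TRG", "TRGV6", "TRGJ1")
  )
  y <- yv("inkt-1" = 3, "inktD-1" = 5, "mait-1" = 0, "maleM-1" = 4,
          "gd-1" = 2, "gonly-1" = 0, "noctg-1" = 1)
  a <- assign_by_tcr(chains, y)
  got <- stats::setNames(a$assigned_type, a$barcode)
  expect_equal(unname(got[c("inkt-1", "inktD-1", "mait-1")]),
               c("iNKT", "iNKT", "MAIT"))
  # canonical MAIT alpha in a male (Y-positive) cell cannot be MAIT
  expect_equal(unname(got["maleM-1"]), "unassigned")
  expect_equal(unname(got[c("gd-1", "gonly-1", "noctg-1")]),
               c("gdT", "unassigned", "unassigned"))
  expect_true(all(a$pass_id[a$assigned_type != "unassigned"] == "1_tcr"))
})

test_that("contig barcodes missing from the matrix warn and stay unassigned", {
  chains <- chain_tbl(list("ghost-1", "TRA", "TRAV11", "TRAJ18"))
  expect_warning(a <- assign_by_tcr(chains, yv("other-1" = 0)), "absent")
  expect_equal(a$barcode, "other-1")
})

test_that("doublet rules remove TRA+TRD and dual-canonical droplets", {
  chains <- chain_tbl(
    list("d1-1", "TRA", "TRAV11", "TRAJ18"),
    list("d1-1", "TRD", "TRDV4", "TRDJ1"),
    list("d2-1", "TRA", "TRAV11", "TRAJ18", "TGTGCTTTT"),
    list("d2-1", "TRA", "TRAV1", "TRAJ33", "TGTAAATTT"),
    list("ok-1", "TRG", "TRGV6", "TRGJ1"),
    list("ok-1", "TRD", "TRDV4", "TRDJ1")
  )
  y <- yv("d1-1" = 2, "d2-1" = 2, "ok-1" = 0)
  a <- flag_doublets(assign_by_tcr(chains, y), chains)
  got <- stats::setNames(a$assigned_type, a$barcode)
  expect_equal(unname(got[c("d1-1", "d2-1")]),
               rep("removed_doublet", 2))
  expect_equal(unname(got["ok-1"]), "gdT")
  expect_equal(a$rule_trace[a$barcode == "d1-1"], "tra_plus_trd")
  expect_equal(a$rule_trace[a$barcode == "d2-1"], "dual_canonical_alpha")
})

test_that("cluster rescue reclassifies by strict majority", {
  # cluster A: 17 iNKT + 3 MAIT assigned (85%), 2 unassigned
  # cluster B: exactly 80% iNKT -> untouched
  mk <- function(n, type, cluster, prefix) {
    tibble::tibble(barcode = sprintf("%s%02d-1", prefix, seq_len(n)),
                   assigned_type = type, pass_id = "1_tcr",
                   rule_trace = "x", cluster = cluster)
  }
  a <- dplyr::bind_rows(
    mk(17, "iNKT", "A", "ai"), mk(3, "MAIT", "A", "am"),
    mk(2, "unassigned", "A", "au"),
    mk(8, "iNKT", "B", "bi"), mk(2, "MAIT", "B", "bm"),
    mk(1, "unassigned", "B", "bu")
  )
  cl <- stats::setNames(a$cluster, a$barcode)
  a$cluster <- NULL
  a$pass_id[a$assigned_type == "unassigned"] <- NA
  out <- cluster_rescue(a, cl)
  got <- stats::setNames(out$assigned_type, out$barcode)
  expect_true(all(got[startsWith(names(got), "au")] == "iNKT"))
  expect_true(all(got[startsWith(names(got), "am")] == "removed_doublet"))
  # 80% exactly: strict inequality means no rescue, cluster flagged mixed
  expect_true(all(got[startsWith(names(got), "bu")] == "unassigned"))
  expect_true(all(got[startsWith(names(got), "bm")] == "MAIT"))
  expect_identical(attr(out, "mixed_clusters"), "B")
  expect_true(all(out$pass_id[startsWith(out$barcode, "au")] ==
                    "2_cluster_rescue"))
})

test_that("TCR fallback annotates unassigned cells in mixed clusters", {
  chains <- chain_tbl(
    list("m-1", "TRA", "TRAV1", "TRAJ12"),
    list("g-1", "TRG", "TRGV4", "TRGJ1"),
    list("gd-1", "TRG", "TRGV4", "TRGJ1"),
    list("gd-1", "TRD", "TRDV5", "TRDJ1"),
    list("pure-1", "TRA", "TRAV1", "TRAJ12")
  )
  a <- tibble::tibble(
    barcode = c("m-1", "g-1", "gd-1", "pure-1"),
    assigned_type = "unassigned", pass_id = NA_character_, rule_trace = "x"
  )
  cl <- c("m-1" = "mix", "g-1" = "mix", "gd-1" = "mix", "pure-1" = "pure")
  out <- tcr_fallback(a, chains, cl, mixed_clusters = "mix")
  got <- stats::setNames(out$assigned_type, out$barcode)
  expect_equal(unname(got["m-1"]), "MAIT")      # TRAV1 even without TRAJ33
  expect_equal(unname(got["g-1"]), "unassigned") # TRG alone insufficient
  expect_equal(unname(got["gd-1"]), "gdT")
  expect_equal(unname(got["pure-1"]), "unassigned") # not in a mixed cluster
})

test_that("demultiplex partitions barcodes and ignores input order", {
  co <- small_cohort(seed = 23, n = 80)
  chains <- cell_chains(usable_contigs(co$contigs))
  y <- y_counts(co$matrix)
  cl <- truth_clusters(co)
  a <- demultiplex(chains, y, cl)

  expect_setequal(a$barcode, names(y))
  expect_equal(nrow(a), length(y))
  expect_true(all(a$assigned_type %in%
                    c("iNKT", "MAIT", "gdT", "unassigned", "removed_doublet")))

  perm <- sample(length(y))
  a2 <- demultiplex(chains[sample(nrow(chains)), ], y[perm], cl)
  m <- dplyr::inner_join(a, a2, by = "barcode", suffix = c("", ".2"))
  expect_equal(m$assigned_type, m$assigned_type.2)
})
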