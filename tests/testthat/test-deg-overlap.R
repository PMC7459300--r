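test_that("DEG extraction applies the padj and fold-change rules", {
  tab <- tibble::tibble(
    gene = sprintf("g%02d", 1:10),
    log2fc = c(2, -1.5, 0.3, -0.2, 1.1, -2.2, 0.9, -0.8, 1.7, -1.2),
    padj = c(0.04, 0.01, 0.2, 0.03, 0.06, 0.001, 0.049, 0.9, 0.05, 0.02)
  )
  sets <- extract_degs(tab)
  # row-by-row oracle
  oracle_up <- tab$gene[vapply(seq_len(10), function(i) {
    tab$padj[i] <= 0.05 && tab$log2fc[i] > 0
  }, logical(1))]
  oracle_down <- tab$gene[vapply(seq_len(10), function(i) {
    tab$padj[i] <= 0.05 && tab$log2fc[i] < 0
  }, logical(1))]
  expect_identical(sets$up, oracle_up)
  expect_identical(sets$down, oracle_down)
  expect_length(intersect(sets$up, sets$down), 0)
  expect_false("g05" %in% c(sets$up, sets$down))  # padj 0.06 excluded

  lfc <- extract_degs(tab, min_abs_lfc = 1)
  expect_false("g07" %in% lfc$up)  # |lfc| 0.9 below the floor
  expect_error(extract_degs(dplyr::bind_rows(tab, tab[1, ])), "duplicate")
})

test_that("overlap test matches the closed-form hypergeometric tail", {
  universe <- sprintf("u%03d", 1:20)
  res <- overlap_test(universe[1:5], universe[1:5], universe,
                      R = 2000, seed = 1)
  expect_equal(res$observed, 5)
  expect_equal(res$p_analytic, 1 / choose(20, 5), tolerance = 1e-12)

  # saturated case: both sets are the whole universe
  sat <- overlap_test(universe, universe, universe, R = 200, seed = 1)
  expect_equal(sat$p_empirical, 1)

  # disjoint small sets on a large universe
  big <- sprintf("g%04d", 1:2000)
  dis <- overlap_test(big[1:5], big[100:104], big, R = 500, seed = 2)
  expect_gt(dis$p_empirical, 0.9)

  expect_error(overlap_test(c(universe[1], "alien"), universe[1:3], universe),
               "alien")
  same <- overlap_test(universe[1:4], universe[3:8], universe,
                       R = 500, seed = 9)
  again <- overlap_test(universe[1:4], universe[3:8], universe,
                        R = 500, seed = 9)
  expect_identical(tidy(same), tidy(again))
})

test_that("empirical p tracks the analytic tail within Monte-Carlo error", {
  universe <- sprintf("g%03d", 1:200)
  withr::with_seed(7, {
    a <- sample(universe, 30)
    b <- c(sample(a, 8), sample(setdiff(universe, a), 22))
  })
  res <- overlap_test(a, b, universe, R = 4000, seed = 3)
  se <- sqrt(res$p_analytic * (1 - res$p_analytic) / res$R)
  expect_lt(abs(res$p_empirical - res$p_analytic), 3 * se + 2 / res$R)
})

test_that("direction-consistent overlap counts concordant genes", {
  u <- sprintf("g%02d", 1:30)
  up_a <- u[1:6]; down_a <- u[7:12]
  up_b <- u[c(1:3, 13:15)]; down_b <- u[c(7, 8, 16:18)]
  res <- direction_consistent_overlap(up_a, down_a, up_b, down_b, u,
                                      R = 1000, seed = 5)
  # brute-force set arithmetic
  expect_equal(res$observed,
               length(intersect(up_a, up_b)) +
                 length(intersect(down_a, down_b)))
  expect_equal(res$observed, 5)

  ident <- direction_consistent_overlap(up_a, down_a, up_a, down_a, u,
                                        R = 1000, seed = 5)
  expect_equal(ident$observed, 12)
  expect_lt(ident$p_empirical, 0.01)

  anti <- direction_consistent_overlap(up_a, down_a, down_a, up_a, u,
                                       R = 200, seed = 5)
  expect_equal(anti$observed, 0)

  expect_error(direction_consistent_overlap(u[1:3], u[3:5], u[1:2], u[4:5], u),
               "up_a and down_a")
})

test_that("direction-consistent analytic tail matches simulation", {
  u <- sprintf("g%03d", 1:100)
  res <- direction_consistent_overlap(u[1:10], u[11:25], u[5:18], u[20:31],
                                      u, R = 4000, seed = 11)
  se <- sqrt(res$p_analytic * (1 - res$p_analytic) / res$R)
  expect_lt(abs(res$p_empirical - res$p_analytic), 3 * se + 2 / res$R)
})

test_that("category correlation detects planted in-category structure", {
  withr::with_seed(19, {
    n <- 200
    in_cat <- rep(c(TRUE, FALSE), c(50, 150))
    base <- stats::rnorm(n)
    lfc_a <- base
    lfc_b <- ifelse(in_cat, 0.8 * base + 0.3 * stats::rnorm(n),
                    stats::rnorm(n))
    tab <- tibble::tibble(gene = sprintf("g%03d", 1:n),
                          lfc_a = lfc_a, lfc_b = lfc_b,
                          category = ifelse(in_cat, "cytokine", "other"))
  })
  res <- category_correlation(tab, "cytokine", R = 1000, seed = 2)
  expect_gt(res$delta_r, 0)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$r_in, res$r_out)

  all_cat <- dplyr::mutate(tab, category = "cytokine")
  expect_error(category_correlation(all_cat, "cytokine"), "at least 3")
  flat <- dplyr::mutate(tab, lfc_a = 0)
  expect_error(category_correlation(flat, "cytokine"), "degenerate")
})

test_that("tidiers expose the test fields", {
  u <- sprintf("g%02d", 1:20)
  res <- overlap_test(u[1:5], u[3:8], u, R = 200, seed = 1)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$observed, 3)
  expect_named(glance(res), names(td))
})
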