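#' Extract up/down DEG sets from a differential-expression table
#'
#' @param table Tibble with columns `gene`, `log2fc`, `padj` (no duplicate
#'   genes, padj in [0, 1]).
#' @param padj_max Adjusted-p cutoff (default 0.05).
#' @param min_abs_lfc Absolute log2 fold-change floor; 0 (default) keeps
#'   any gene with non-zero fold change in the significant set.
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
extract_degs <- function(table, padj_max = 0.05, min_abs_lfc = 0) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(table)))
  if (anyDuplicated(table$gene)) stop("duplicate genes in DEG table")
  sig <- table$padj <= padj_max
  if (min_abs_lfc > 0) {
    up <- table$gene[sig & table$log2fc >= min_abs_lfc]
    down <- table$gene[sig & table$log2fc <= -min_abs_lfc]
  } else {
    up <- table$gene[sig & table$log2fc > 0]
    down <- table$gene[sig & table$log2fc < 0]
  }
  list(up = up, down = down)
}

new_overlap_result <- function(n_universe, size_a, size_b, observed, null_k,
                               R, p_analytic, statistic) {
  structure(list(
    n_universe = n_universe, size_a = size_a, size_b = size_b,
    observed = observed,
    null_mean = mean(null_k), null_sd = stats::sd(null_k),
    p_empirical = (1 + sum(null_k >= observed)) / (R + 1),
    p_analytic = p_analytic, R = R, statistic = statistic
  ), class = "overlap_test")
}

#' Monte-Carlo test for gene-set overlap
#'
#' Tests whether the overlap between two gene sets drawn from a common
#' universe is larger than expected by chance. The null is simulated by
#' drawing R independent pairs of uniform without-replacement samples of
#' the observed sizes from the universe; the empirical p-value is
#' `(1 + #{null >= k}) / (R + 1)` (one-sided, greater). The analytic
#' hypergeometric upper tail `P(X >= k)` is reported alongside.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of testable genes (typically the
#'   intersection of the genes tested in both DE analyses).
#' @param R Monte-Carlo replicates (>= 100).
#' @param seed Optional integer seed for the null draws.
#' @return An `overlap_test` object; see [tidy.overlap_test()].
#' @export
overlap_test <- function(set_a, set_b, universe, R = 10000, seed = NULL) {
  stopifnot(R >= 100)
  check_subset(set_a, universe, "set_a")
  check_subset(set_b, universe, "set_b")
  n <- length(universe)
  a <- length(unique(set_a))
  b <- length(unique(set_b))
  k <- length(intersect(set_a, set_b))

  null_k <- withr::with_seed(seed %||% sample.int(1e6, 1), {
    vapply(seq_len(R), function(i) {
      ia <- sample.int(n, a)
      ib <- sample.int(n, b)
      sum(ib %in% ia)
    }, integer(1))
  })
  p_analytic <- stats::phyper(k - 1, a, n - a, b, lower.tail = FALSE)
  new_overlap_result(n, a, b, k, null_k, R, p_analytic, "overlap")
}

#' Direction-consistent DEG overlap test
#'
#' The statistic is the number of genes commonly upregulated plus commonly
#' downregulated in the two subsets, `k = |upA ∩ upB| + |downA ∩ downB|`.
#' The null preserves all four set sizes with independent uniform draws
#' from the universe. The analytic tail is the exact distribution of the
#' sum of the two independent hypergeometric overlap counts.
#'
#' @param up_a,down_a,up_b,down_b Character vectors; up/down must be
#'   disjoint within each subset.
#' @inheritParams overlap_test
#' @return An `overlap_test` object with `statistic = "direction_consistent"`.
#' @export
direction_consistent_overlap <- function(up_a, down_a, up_b, down_b,
                                         universe, R = 10000, seed = NULL) {
  stopifnot(R >= 100)
  if (length(intersect(up_a, down_a)) > 0) {
    stop("up_a and down_a overlap")
  }
  if (length(intersect(up_b, down_b)) > 0) {
    stop("up_b and down_b overlap")
  }
  for (s in list(up_a, down_a, up_b, down_b)) check_subset(s, universe, "set")
  n <- length(universe)
  sz <- vapply(list(up_a, down_a, up_b, down_b), length, integer(1))
  k <- length(intersect(up_a, up_b)) + length(intersect(down_a, down_b))

  null_k <- withr::with_seed(seed %||% sample.int(1e6, 1), {
    vapply(seq_len(R), function(i) {
      ua <- sample.int(n, sz[1]); da <- sample.int(n, sz[2])
      ub <- sample.int(n, sz[3]); db <- sample.int(n, sz[4])
      sum(ub %in% ua) + sum(db %in% da)
    }, integer(1))
  })
  # exact tail of X1 + X2, X1 ~ Hyper(up sizes), X2 ~ Hyper(down sizes)
  d1 <- stats::dhyper(0:min(sz[1], sz[3]), sz[1], n - sz[1], sz[3])
  d2 <- stats::dhyper(0:min(sz[2], sz[4]), sz[2], n - sz[2], sz[4])
  conv <- stats::convolve(d1, rev(d2), type = "open")
  p_analytic <- if (k <= 0) 1 else sum(conv[(k + 1):length(conv)])
  new_overlap_result(n, sz[1] + sz[2], sz[3] + sz[4], k,
                     null_k, R, p_analytic, "direction_consistent")
}

check_subset <- function(set, universe, label) {
  out <- setdiff(set, universe)
  if (length(out) > 0) {
    stop(label, " contains genes outside the universe: ",
         paste(utils::head(out, 10), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test> %s: observed k = %d (null %.2f +/- %.2f over R = %d)\n",
    x$statistic, x$observed, x$null_mean, x$null_sd, x$R))
  cat(sprintf("  empirical p = %.3g | analytic p = %.3g\n",
              x$p_empirical, x$p_analytic))
  invisible(x)
}

#' Tidy an overlap test
#'
#' @param x An `overlap_test` object.
#' @param ... Unused.
#' @return One-row tibble of the test's fields.
#' @method tidy overlap_test
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, n_universe = x$n_universe,
    size_a = x$size_a, size_b = x$size_b, observed = x$observed,
    null_mean = x$null_mean, null_sd = x$null_sd, R = x$R,
    p_empirical = x$p_empirical, p_analytic = x$p_analytic
  )
}

#' @rdname tidy.overlap_test
#' @method glance overlap_test
#' @export
glance.overlap_test <- function(x, ...) tidy.overlap_test(x)

#' Category-restricted fold-change correlation comparison
#'
#' Compares the correlation of per-gene log2 fold changes between two
#' subsets within a gene category (e.g. cytokines and receptors) against
#' the correlation outside it. Significance of `delta_r = r_in - r_out`
#' (one-sided, greater) comes from R permutations of the category labels.
#'
#' @param table Tibble with columns `gene`, `lfc_a`, `lfc_b`, `category`.
#' @param category_of_interest Category value defining the in-stratum.
#' @param R Permutations (default 1000).
#' @param seed Optional integer seed.
#' @param method Correlation method, `"spearman"` (default) or
#'   `"pearson"`.
#' @return Object of class `category_correlation` with fields `r_in`,
#'   `r_out`, `delta_r`, `p_value`, `n_in`, `n_out`; has a [tidy()] method.
#' @export
category_correlation <- function(table, category_of_interest, R = 1000,
                                 seed = NULL,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(all(c("gene", "lfc_a", "lfc_b", "category") %in% names(table)))
  in_cat <- table$category == category_of_interest
  n_in <- sum(in_cat)
  n_out <- sum(!in_cat)
  if (n_in < 3 || n_out < 3) {
    stop("need at least 3 genes both inside and outside the category")
  }
  if (stats::sd(table$lfc_a) == 0 || stats::sd(table$lfc_b) == 0) {
    stop("degenerate (constant) fold-change vector")
  }
  delta <- function(mask) {
    stats::cor(table$lfc_a[mask], table$lfc_b[mask], method = method) -
      stats::cor(table$lfc_a[!mask], table$lfc_b[!mask], method = method)
  }
  obs <- delta(in_cat)
  perm <- withr::with_seed(seed %||% sample.int(1e6, 1), {
    vapply(seq_len(R), function(i) delta(sample(in_cat)), numeric(1))
  })
  structure(list(
    r_in = stats::cor(table$lfc_a[in_cat], table$lfc_b[in_cat],
                      method = method),
    r_out = stats::cor(table$lfc_a[!in_cat], table$lfc_b[!in_cat],
                       method = method),
    delta_r = obs,
    p_value = (1 + sum(perm >= obs)) / (R + 1),
    n_in = n_in, n_out = n_out, R = R, method = method
  ), class = "category_correlation")
}

#' @export
print.category_correlation <- function(x, ...) {
  cat(sprintf(
    "<category_correlation> r_in = %.3f, r_out = %.3f, delta = %.3f, p = %.3g (%s, R = %d)\n",
    x$r_in, x$r_out, x$delta_r, x$p_value, x$method, x$R))
  invisible(x)
}

#' @rdname tidy.overlap_test
#' @method tidy category_correlation
#' @export
tidy.category_correlation <- function(x, ...) {
  tibble::tibble(r_in = x$r_in, r_out = x$r_out, delta_r = x$delta_r,
                 p_value = x$p_value, n_in = x$n_in, n_out = x$n_out,
                 method = x$method, R = x$R)
}
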