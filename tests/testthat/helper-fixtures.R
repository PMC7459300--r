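# Shared in-code fixtures for the suite.

# small raw gene_matrix with controllable totals and mito content;
# `totals` are the non-mito totals, `mito` the mito totals, per cell
toy_matrix <- function(totals, mito = rep(0, length(totals)),
                       n_genes = 4, y = rep(0, length(totals))) {
  n <- length(totals)
  barcodes <- sprintf("cell%02d-1", seq_len(n))
  genes <- c(sprintf("Gene%02d", seq_len(n_genes)), "mt-Nd1", "Ddx3y")
  m <- matrix(0L, nrow = length(genes), ncol = n,
              dimnames = list(genes, barcodes))
  for (i in seq_len(n)) {
    base <- rep(totals[i] %/% n_genes, n_genes)
    base[1] <- base[1] + totals[i] %% n_genes
    m[seq_len(n_genes), i] <- base
    m[n_genes + 1, i] <- mito[i]
    m[n_genes + 2, i] <- y[i]
  }
  gene_matrix(m, layer = "raw")
}

# chain tibble builder in the cell_chains() layout
chain_tbl <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(barcode = r[[1]], chain = r[[2]], v_gene = r[[3]],
                   j_gene = r[[4]],
                   cdr3_nt = if (length(r) >= 5) r[[5]] else "TGTGCTTTT",
                   cdr3 = if (length(r) >= 6) r[[6]] else "CAF")
  })
}

# deterministic small cohort shared by several test files
small_cohort <- function(seed = 42, n = 100, doublet_fraction = 0.05, ...) {
  generate_cohort(synth_config(
    n_cells_per_type = c(iNKT = n, MAIT = n, gdT = n),
    doublet_fraction = doublet_fraction,
    n_genes = 60, umi_depth_mean = 2000, seed = seed, ...))
}

truth_clusters <- function(cohort) {
  tibble::tibble(barcode = cohort$truth$barcode,
                 cluster = cohort$truth$true_cluster)
}
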