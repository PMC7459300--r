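#' Cell quality control on UMI depth and mitochondrial fraction
#'
#' Removes low-quality droplets using the two standard rules: cells with
#' fewer than `min_umi` total UMIs, and cells with more than `max_mito` of
#' their UMIs assigned to mitochondrial genes, are excluded. A cell failing
#' both rules is reported under `low_umi`.
#'
#' @param gm A raw-layer [gene_matrix()].
#' @param min_umi Minimum total UMIs per cell (default 1000; cells strictly
#'   below are removed).
#' @param max_mito Maximum mitochondrial UMI fraction (default 0.10; cells
#'   strictly above are removed).
#' @return List with `matrix` (the filtered `gene_matrix`, gene set
#'   unchanged) and `report`, a tibble with one row per input cell:
#'   `barcode`, `total_umi`, `mito_frac`, `kept`, `reason` (one of `pass`,
#'   `low_umi`, `high_mito`).
#' @export
qc_filter <- function(gm, min_umi = 1000, max_mito = 0.10) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (gm$layer != "raw") stop("qc_filter() requires the raw counts layer")
  if (ncol(gm$counts) == 0) stop("empty matrix: no cells to filter")

  totals <- Matrix::colSums(gm$counts)
  mito_idx <- which(gm$gene_info$is_mito)
  if (length(mito_idx) == 0) {
    warning("no mitochondrial genes flagged; mito fraction defined as 0")
    mito <- numeric(length(totals))
  } else {
    mito <- Matrix::colSums(gm$counts[mito_idx, , drop = FALSE])
  }
  mito_frac <- ifelse(totals > 0, mito / totals, 0)

  reason <- dplyr::case_when(
    totals < min_umi ~ "low_umi",
    mito_frac > max_mito ~ "high_mito",
    TRUE ~ "pass"
  )
  report <- tibble::tibble(
    barcode = colnames(gm$counts),
    total_umi = unname(totals),
    mito_frac = unname(mito_frac),
    kept = reason == "pass",
    reason = reason
  )
  kept_gm <- gene_matrix(gm$counts[, report$kept, drop = FALSE],
                         gene_info = gm$gene_info, layer = "raw")
  list(matrix = kept_gm, report = report)
}

#' Library-size cell-specific size factors
#'
#' Per-cell factors proportional to the cell's total UMI count, scaled so
#' the factor vector has mean 1. Externally computed factors (for example
#' pooled-deconvolution factors) can be passed straight to
#' [lognormalize()] instead.
#'
#' @param gm A raw-layer [gene_matrix()] of QC-passing cells.
#' @return Named numeric vector of positive factors with mean 1.
#' @export
size_factors <- function(gm) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (gm$layer != "raw") stop("size_factors() requires the raw counts layer")
  totals <- Matrix::colSums(gm$counts)
  zero <- totals == 0
  if (any(zero)) {
    stop("cells with zero total counts: ",
         paste(colnames(gm$counts)[zero], collapse = ", "))
  }
  totals / mean(totals)
}

#' Size-factor log2 normalization
#'
#' Divides each cell's raw counts by its size factor and log2-transforms
#' with a pseudocount of 1: `log2(raw/factor + 1)`. Zeros map to zero, so
#' the sparsity pattern is preserved.
#'
#' @param gm A raw-layer [gene_matrix()].
#' @param factors Optional per-cell positive factors (named or in column
#'   order); defaults to [size_factors()] of `gm`.
#' @return A `gene_matrix` with `layer = "lognorm"`.
#' @export
lognormalize <- function(gm, factors = NULL) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (gm$layer != "raw") stop("lognormalize() requires the raw counts layer")
  if (is.null(factors)) factors <- size_factors(gm)
  if (!is.null(names(factors))) {
    if (!setequal(names(factors), colnames(gm$counts))) {
      stop("factor names do not match matrix barcodes")
    }
    factors <- factors[colnames(gm$counts)]
  }
  if (length(factors) != ncol(gm$counts)) {
    stop("need one size factor per cell")
  }
  if (any(factors <= 0)) stop("size factors must be positive")

  x <- gm$counts
  # column index of every stored value in a CsparseMatrix
  col_of <- rep.int(seq_len(ncol(x)), diff(x@p))
  x@x <- log2(x@x / factors[col_of] + 1)
  gene_matrix(x, gene_info = gm$gene_info, layer = "lognorm")
}
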