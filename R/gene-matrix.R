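#' Gene-by-cell expression matrix with gene annotations
#'
#' A light container around a sparse [Matrix::dgCMatrix] holding either raw
#' UMI counts or log2 size-factor-normalized values, together with a gene
#' metadata tibble flagging mitochondrial genes, Y-chromosome genes and a
#' functional category (cytokine / receptor / TF / other).
#'
#' @param counts Numeric matrix or sparse Matrix, genes in rows, cells in
#'   columns. Dimnames are required: row names are gene identifiers, column
#'   names are cell barcodes, both unique.
#' @param gene_info Optional tibble with one row per gene (columns `gene`,
#'   `is_mito`, `is_ychrom`, `category`). When `NULL` it is built with
#'   [annotate_genes()] using the default mito prefix and Y gene list.
#' @param layer Either `"raw"` (non-negative integer counts) or `"lognorm"`.
#' @param mito_prefix,y_genes Passed to [annotate_genes()] when `gene_info`
#'   is `NULL`.
#'
#' @return An object of class `gene_matrix`: a list with elements `counts`
#'   (dgCMatrix), `gene_info` (tibble) and `layer`.
#' @export
gene_matrix <- function(counts, gene_info = NULL, layer = c("raw", "lognorm"),
                        mito_prefix = "mt-",
                        y_genes = c("Ddx3y", "Eif2s3y", "Uty", "Kdm5d")) {
  layer <- match.arg(layer)
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("`counts` must carry gene row names and barcode column names")
  }
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell barcodes")
  if (any(counts@x < 0)) stop("expression values must be non-negative")
  if (layer == "raw" && any(counts@x != floor(counts@x))) {
    stop("raw layer must contain integer counts")
  }
  if (is.null(gene_info)) {
    gene_info <- annotate_genes(rownames(counts), mito_prefix = mito_prefix,
                                y_genes = y_genes)
  } else {
    gene_info <- tibble::as_tibble(gene_info)
    stopifnot(identical(gene_info$gene, rownames(counts)))
  }
  structure(list(counts = counts, gene_info = gene_info, layer = layer),
            class = "gene_matrix")
}

#' Build gene annotation flags from identifiers
#'
#' Mitochondrial genes are identified by a name prefix (10x mouse references
#' use `mt-`); Y-chromosome genes by an explicit list of male-specific
#' transcripts detectable in droplet data.
#'
#' @param genes Character vector of gene identifiers.
#' @param mito_prefix Prefix marking mitochondrial genes.
#' @param y_genes Character vector of Y-chromosome gene names.
#' @param category Optional named character vector mapping gene ->
#'   `"cytokine"`, `"receptor"` or `"TF"`; unnamed genes become `"other"`.
#' @return Tibble with columns `gene`, `is_mito`, `is_ychrom`, `category`.
#' @export
annotate_genes <- function(genes, mito_prefix = "mt-",
                           y_genes = c("Ddx3y", "Eif2s3y", "Uty", "Kdm5d"),
                           category = NULL) {
  cat_vec <- rep("other", length(genes))
  if (!is.null(category)) {
    hit <- match(genes, names(category))
    cat_vec[!is.na(hit)] <- unname(category[hit[!is.na(hit)]])
  }
  tibble::tibble(
    gene = genes,
    is_mito = startsWith(genes, mito_prefix),
    is_ychrom = genes %in% y_genes,
    category = cat_vec
  )
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix> %d genes x %d cells, layer = %s\n",
              nrow(x$counts), ncol(x$counts), x$layer))
  cat(sprintf("  mito genes: %d | Y genes: %d\n",
              sum(x$gene_info$is_mito), sum(x$gene_info$is_ychrom)))
  invisible(x)
}

#' @export
dim.gene_matrix <- function(x) dim(x$counts)

#' Per-cell totals of Y-chromosome gene counts
#'
#' Used by the demultiplexer to operationalize "not expressing Y-chromosomal
#' genes": in droplet data Y transcripts are near-binary between sexes, so a
#' raw-count sum against a zero (or small) tolerance separates male from
#' female cells.
#'
#' @param gm A raw-layer [gene_matrix()].
#' @return Named numeric vector, one total per barcode.
#' @export
y_counts <- function(gm) {
  stopifnot(inherits(gm, "gene_matrix"))
  idx <- which(gm$gene_info$is_ychrom)
  if (length(idx) == 0) {
    warning("no Y-chromosome genes flagged; totals are all zero")
    return(stats::setNames(numeric(ncol(gm$counts)), colnames(gm$counts)))
  }
  Matrix::colSums(gm$counts[idx, , drop = FALSE])
}
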