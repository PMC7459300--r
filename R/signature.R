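#' Per-cell signature score
#'
#' The signature score of a gene set is the average Z-score of log2
#' normalized counts of the signature genes: each gene is standardized
#' across cells ((x - mean) / sd, population sd), and a cell's score is the
#' mean of the standardized values over the signature genes. Genes with
#' zero variance carry no information and contribute 0 (with a message).
#'
#' @param gm A lognorm-layer [gene_matrix()].
#' @param genes Character vector of signature gene identifiers; duplicates
#'   are removed and the set is intersected with the matrix genes.
#' @param name Signature name, used in messages and the output.
#' @return Tibble `barcode`, `score`, `signature`.
#' @export
signature_score <- function(gm, genes, name = "signature") {
  stopifnot(inherits(gm, "gene_matrix"))
  if (gm$layer != "lognorm") {
    stop("signature_score() requires the lognorm layer")
  }
  genes <- unique(genes)
  present <- intersect(genes, rownames(gm$counts))
  if (length(present) == 0) {
    stop("signature '", name, "' has no genes in the matrix")
  }
  x <- as.matrix(gm$counts[present, , drop = FALSE])
  mu <- rowMeans(x)
  sdev <- sqrt(rowMeans(x^2) - mu^2)
  sdev[sdev < 0] <- 0  # numerical guard
  z <- (x - mu) / ifelse(sdev > 0, sdev, 1)
  if (any(sdev == 0)) {
    message(sum(sdev == 0), " zero-variance gene(s) in '", name,
            "' contribute 0")
    z[sdev == 0, ] <- 0
  }
  tibble::tibble(
    barcode = colnames(gm$counts),
    score = unname(colMeans(z)),
    signature = name
  )
}

#' Select a trajectory start cell by maximal signature score
#'
#' Returns the barcode of the cell with the highest signature score within
#' one cluster (the progenitor cluster of a differentiation trajectory).
#' Ties are broken toward the lexicographically smallest barcode, with a
#' message.
#'
#' @param scores Tibble from [signature_score()] (`barcode`, `score`).
#' @param clusters Cluster labels (tibble or named vector).
#' @param cluster_id Cluster to search in.
#' @return A single barcode.
#' @export
select_start_cell <- function(scores, clusters, cluster_id) {
  cl <- as_cluster_tbl(clusters)
  members <- cl$barcode[cl$cluster == cluster_id]
  if (length(members) == 0) stop("unknown or empty cluster: ", cluster_id)
  x <- dplyr::filter(scores, .data$barcode %in% members)
  if (nrow(x) == 0) stop("no scored cells in cluster ", cluster_id)
  best <- x$barcode[x$score == max(x$score)]
  if (length(best) > 1) {
    message("score tie among ", length(best),
            " cells; using the lexicographically smallest barcode")
    best <- sort(best)
  }
  best[1]
}
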