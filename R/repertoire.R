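#' Truncating percentage formatter
#'
#' Formats `100 * x / n` truncated (floored) at `digits` decimal places,
#' matching how repertoire summaries are conventionally printed (e.g.
#' 17/1760 -> 0.96 at two decimals, 359/1665 -> 21 at zero decimals). A
#' tiny epsilon guards against floating-point representation pushing an
#' exact value below the truncation boundary.
#'
#' @param x Numerator count.
#' @param n Denominator count (> 0).
#' @param digits Decimal places to keep.
#' @return Numeric percentage, truncated.
#' @export
percent_floor <- function(x, n, digits = 1) {
  stopifnot(n > 0)
  f <- 10^digits
  floor(x / n * 100 * f + 1e-9) / f
}

#' Build a clonotype table for one assigned cell type
#'
#' One row per distinct clonotype among the cells of one assigned type,
#' with total cell counts and per-cluster cell counts. Cell counts are
#' conserved: the totals sum to the number of keyed cells.
#'
#' @param chains Tibble from [cell_chains()].
#' @param assignments Assignments tibble (from [demultiplex()]); only
#'   barcodes of `type` are used. Pass `NULL` to use all barcodes in
#'   `chains`.
#' @param clusters Cluster labels (`barcode`/`cluster` tibble or named
#'   vector).
#' @param type Assigned type to restrict to (e.g. `"iNKT"`), ignored when
#'   `assignments` is `NULL`.
#' @param level CDR3 comparison level, see [clonotype_key()].
#' @return Tibble of class `clonotype_table`: `clonotype_key`, `n_cells`,
#'   then one `n_<cluster>` column per cluster, plus a `chains` attribute
#'   mapping keys to representative chain tibbles is not stored; keys are
#'   self-describing (`chain:V:J:CDR3nt` tuples).
#' @export
build_clonotype_table <- function(chains, assignments = NULL, clusters = NULL,
                                  type = NULL, level = c("nt", "aa")) {
  level <- match.arg(level)
  keep <- unique(chains$barcode)
  if (!is.null(assignments)) {
    stopifnot(!is.null(type))
    keep <- assignments$barcode[assignments$assigned_type == type]
  }
  keyed <- clonotype_keys(dplyr::filter(chains, .data$barcode %in% keep),
                          level = level)
  if (is.null(clusters)) {
    cl <- tibble::tibble(barcode = keyed$barcode, cluster = "all")
  } else {
    cl <- as_cluster_tbl(clusters)
  }
  long <- keyed |>
    dplyr::left_join(cl, by = "barcode") |>
    dplyr::mutate(cluster = tidyr::replace_na(.data$cluster, "unlabelled")) |>
    dplyr::count(.data$clonotype_key, .data$cluster, name = "n")
  wide <- long |>
    tidyr::pivot_wider(names_from = "cluster", values_from = "n",
                       values_fill = 0L, names_prefix = "n_",
                       names_sort = TRUE)
  cluster_cols <- setdiff(names(wide), "clonotype_key")
  out <- wide |>
    dplyr::mutate(n_cells = rowSums(dplyr::pick(dplyr::all_of(cluster_cols)))) |>
    dplyr::select(dplyr::all_of(c("clonotype_key", "n_cells", cluster_cols))) |>
    dplyr::arrange(dplyr::desc(.data$n_cells), .data$clonotype_key)
  attr(out, "cluster_cols") <- cluster_cols
  class(out) <- c("clonotype_table", class(out))
  out
}

#' Clonal repeat spectrum
#'
#' Tabulates, for each clone size s, the number of clonotypes repeated
#' exactly s times and the number of cells they account for, together with
#' the normalized clonotype curve (share of clonotypes at each size) used
#' for cumulative repeat comparisons between cell types.
#'
#' @param table A [build_clonotype_table()] result (or any tibble with
#'   `n_cells` per clonotype).
#' @return Tibble of class `repeat_spectrum` with columns `size`,
#'   `n_clonotypes`, `n_cells`, `frac_clonotypes`, `frac_cells`,
#'   `norm_clonotypes` (identical to `frac_clonotypes`, kept under the
#'   plotting name) and attributes `total_clonotypes`, `total_cells`.
#' @export
repeat_spectrum <- function(table) {
  if (nrow(table) == 0) stop("empty clonotype table")
  spec <- table |>
    dplyr::count(size = .data$n_cells, name = "n_clonotypes") |>
    dplyr::arrange(.data$size) |>
    dplyr::mutate(
      n_cells = .data$size * .data$n_clonotypes,
      frac_clonotypes = .data$n_clonotypes / sum(.data$n_clonotypes),
      frac_cells = .data$n_cells / sum(.data$n_cells),
      norm_clonotypes = .data$frac_clonotypes
    )
  stopifnot(sum(spec$n_clonotypes) == nrow(table),
            sum(spec$n_cells) == sum(table$n_cells))
  attr(spec, "total_clonotypes") <- nrow(table)
  attr(spec, "total_cells") <- sum(table$n_cells)
  class(spec) <- c("repeat_spectrum", class(spec))
  spec
}

#' Summary shares of a repeat spectrum
#'
#' Convenience summary of the quantities usually reported alongside the
#' spectrum: singleton shares and the share of clonotypes repeated more
#' than `repeat_gt` times. Percentages are truncated with
#' [percent_floor()]; full-precision fractions are included.
#'
#' @param spectrum A [repeat_spectrum()] result.
#' @param repeat_gt Clone-size threshold; "repeated more than three times"
#'   means size > 3 (default).
#' @param digits Decimal places for the truncated percentages.
#' @return One-row tibble.
#' @export
spectrum_summary <- function(spectrum, repeat_gt = 3, digits = 1) {
  tc <- attr(spectrum, "total_clonotypes")
  tcell <- attr(spectrum, "total_cells")
  single_cl <- sum(spectrum$n_clonotypes[spectrum$size == 1])
  single_cells <- sum(spectrum$n_cells[spectrum$size == 1])
  rep_cl <- sum(spectrum$n_clonotypes[spectrum$size > repeat_gt])
  tibble::tibble(
    total_clonotypes = tc,
    total_cells = tcell,
    singleton_clonotypes = single_cl,
    singleton_cells = single_cells,
    pct_singleton_clonotypes = percent_floor(single_cl, tc, 0),
    pct_singleton_cells = percent_floor(single_cells, tcell, 0),
    n_repeat_gt = rep_cl,
    pct_repeat_gt = percent_floor(rep_cl, tc, digits),
    frac_repeat_gt = rep_cl / tc
  )
}

#' Shannon equitability of a clonotype distribution
#'
#' Shannon entropy of the clonotype frequencies normalized by its maximum,
#' `E = (-sum p_i ln p_i) / ln S`, lying in [0, 1] with 1 for a perfectly
#' even repertoire. A single clonotype (S = 1) is defined as 0 (maximally
#' uneven, by convention).
#'
#' @param counts Positive integer cell counts, one per clonotype.
#' @return Numeric in [0, 1].
#' @export
shannon_equitability <- function(counts) {
  if (length(counts) == 0) stop("empty count vector")
  if (any(counts <= 0)) stop("clonotype counts must be positive")
  s <- length(counts)
  if (s == 1) return(0)
  p <- counts / sum(counts)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Per-cluster Shannon equitability
#'
#' @param table A [build_clonotype_table()] result with per-cluster counts.
#' @return Tibble `cluster`, `n_clonotypes`, `n_cells`, `equitability`.
#' @export
cluster_equitability <- function(table) {
  cols <- attr(table, "cluster_cols")
  purrr::map_dfr(cols, function(cc) {
    cnt <- table[[cc]][table[[cc]] > 0]
    tibble::tibble(
      cluster = sub("^n_", "", cc),
      n_clonotypes = length(cnt),
      n_cells = sum(cnt),
      equitability = if (length(cnt) > 0) shannon_equitability(cnt) else NA_real_
    )
  })
}

#' Clonotypes shared between two cluster regions
#'
#' Finds clonotypes present in both of two disjoint cluster groupings (for
#' example immature type-1 vs type-17 regions of the gamma-delta UMAP) and
#' summarizes how many cells they account for: total repeats (cells
#' carrying a shared clonotype within the two regions), their share of all
#' cells in the table, and their share of cells belonging to repetitive
#' clones (clonotype size >= 2).
#'
#' @param table A [build_clonotype_table()] result.
#' @param region_a,region_b Character vectors of cluster ids (as in the
#'   cluster label input, without the `n_` prefix); must be disjoint and
#'   known.
#' @return List with `shared` (tibble of shared clonotypes and their
#'   per-region counts) and `summary` (one-row tibble: `n_shared`,
#'   `total_repeats`, `pct_total_cells`, `pct_repetitive_cells`).
#' @export
cluster_sharing <- function(table, region_a, region_b) {
  cols <- attr(table, "cluster_cols")
  known <- sub("^n_", "", cols)
  unknown <- setdiff(c(region_a, region_b), known)
  if (length(unknown) > 0) {
    stop("unknown cluster id(s): ", paste(unknown, collapse = ", "))
  }
  if (length(intersect(region_a, region_b)) > 0) {
    stop("regions must be disjoint")
  }
  ca <- paste0("n_", region_a)
  cb <- paste0("n_", region_b)
  n_a <- rowSums(table[, ca, drop = FALSE])
  n_b <- rowSums(table[, cb, drop = FALSE])
  shared_idx <- which(n_a > 0 & n_b > 0)
  shared <- tibble::tibble(
    clonotype_key = table$clonotype_key[shared_idx],
    n_region_a = n_a[shared_idx],
    n_region_b = n_b[shared_idx],
    n_cells = table$n_cells[shared_idx]
  )
  total_repeats <- sum(shared$n_region_a + shared$n_region_b)
  total_cells <- sum(table$n_cells)
  repetitive_cells <- sum(table$n_cells[table$n_cells >= 2])
  summary <- tibble::tibble(
    n_shared = nrow(shared),
    total_repeats = total_repeats,
    pct_total_cells = percent_floor(total_repeats, total_cells, 0),
    pct_repetitive_cells = if (repetitive_cells > 0)
      percent_floor(total_repeats, repetitive_cells, 0) else NA_real_
  )
  list(shared = shared, summary = summary)
}

#' CDR3 length histogram
#'
#' Counts cells per amino-acid CDR3 length for one TCR locus, optionally
#' partitioned into canonical vs non-canonical chains (for alpha loci of
#' iNKT/MAIT cells) or by V gene (for gamma chains). Cells carrying several
#' distinct chains of the locus contribute each chain once.
#'
#' @param chains Tibble from [cell_chains()].
#' @param locus One of `"TRA"`, `"TRB"`, `"TRG"`, `"TRD"`.
#' @param by Partition: `"none"`, `"canonical"` (requires `rules` and
#'   `type`) or `"v_gene"`.
#' @param rules A [demux_rules()] object (for `by = "canonical"`).
#' @param type `"iNKT"` or `"MAIT"` — which canonical alpha pair applies.
#' @return Tibble `group`, `length`, `n` (cells-with-chain counts).
#' @export
cdr3_length_hist <- function(chains, locus, by = c("none", "canonical", "v_gene"),
                             rules = demux_rules(), type = c("iNKT", "MAIT")) {
  by <- match.arg(by)
  x <- dplyr::filter(chains, .data$chain == locus)
  if (by == "canonical") {
    type <- match.arg(type)
    canon <- if (type == "iNKT") {
      is_canonical_inkt_chain(x$chain, x$v_gene, x$j_gene, rules)
    } else {
      is_canonical_mait_chain(x$chain, x$v_gene, x$j_gene, rules)
    }
    x$group <- ifelse(canon, "canonical", "non_canonical")
  } else if (by == "v_gene") {
    x$group <- x$v_gene
  } else {
    x$group <- "all"
  }
  x |>
    dplyr::mutate(length = nchar(.data$cdr3)) |>
    dplyr::count(.data$group, .data$length, name = "n") |>
    dplyr::arrange(.data$group, .data$length)
}

# WebLogo-style hydropathy classes
HYDROPATHY <- c(
  R = "hydrophilic", K = "hydrophilic", D = "hydrophilic", E = "hydrophilic",
  N = "hydrophilic", Q = "hydrophilic",
  S = "neutral", G = "neutral", H = "neutral", T = "neutral", A = "neutral",
  P = "neutral",
  C = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
  M = "hydrophobic", F = "hydrophobic", W = "hydrophobic", Y = "hydrophobic"
)

#' Hydropathy class of amino-acid residues
#'
#' @param residue Character vector of one-letter residues.
#' @return Character vector: `hydrophilic`, `neutral` or `hydrophobic`.
#' @export
hydropathy_class <- function(residue) {
  unname(HYDROPATHY[residue])
}

#' Positional amino-acid composition at the modal CDR3 length
#'
#' Restricts a set of amino-acid CDR3 sequences to the most common length
#' (ties broken toward the shorter length, with a message) and computes the
#' relative amino-acid frequency at each position, the matrix a sequence
#' logo displays.
#'
#' @param seqs Character vector of amino-acid CDR3 sequences.
#' @return Object of class `logo_matrix`: list with `modal_length`,
#'   `n_seqs` (sequences at that length), `freq` (modal_length x 20 matrix,
#'   rows sum to 1) and `tidy`, a long tibble `position`, `residue`,
#'   `freq`, `hydropathy`.
#' @export
composition_logo <- function(seqs) {
  seqs <- seqs[!is.na(seqs) & nzchar(seqs)]
  if (length(seqs) == 0) stop("no sequences supplied")
  len <- nchar(seqs)
  tab <- table(len)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) > 1) {
    message("modal-length tie (", paste(top, collapse = ", "),
            "); using the shorter length ", min(top))
  }
  modal <- min(top)
  use <- seqs[len == modal]
  residues <- names(HYDROPATHY)
  mat <- matrix(0, nrow = modal, ncol = length(residues),
                dimnames = list(position = seq_len(modal), residue = residues))
  split_mat <- do.call(rbind, strsplit(use, ""))
  for (p in seq_len(modal)) {
    cnt <- table(factor(split_mat[, p], levels = residues))
    mat[p, ] <- as.numeric(cnt) / length(use)
  }
  stopifnot(all(abs(rowSums(mat) - 1) < 1e-9))
  tidy <- tibble::as_tibble(as.data.frame.table(mat, responseName = "freq")) |>
    dplyr::mutate(position = as.integer(as.character(.data$position)),
                  residue = as.character(.data$residue),
                  hydropathy = hydropathy_class(.data$residue)) |>
    dplyr::filter(.data$freq > 0)
  structure(list(modal_length = modal, n_seqs = length(use), freq = mat,
                 tidy = tidy),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("<logo_matrix> modal length %d, %d sequences\n",
              x$modal_length, x$n_seqs))
  invisible(x)
}

#' Default oligoclonal V-beta gene sets
#'
#' The restricted V-beta usage characteristic of each invariant lineage
#' (iNKT: Vbeta8.1/8.2/8.3 (TRBV13-1/2/3), Vbeta7 (TRBV29), Vbeta2 (TRBV1);
#' MAIT: Vbeta6 (TRBV19) and Vbeta8 (TRBV13 family)). These are defaults and
#' should be overridden when a study defines its own oligoclonal sets.
#'
#' @param type `"iNKT"` or `"MAIT"`.
#' @return Character vector of TRBV gene names.
#' @export
oligoclonal_vb <- function(type = c("iNKT", "MAIT")) {
  type <- match.arg(type)
  switch(type,
         iNKT = c("TRBV13-1", "TRBV13-2", "TRBV13-3", "TRBV29", "TRBV1"),
         MAIT = c("TRBV19", "TRBV13-1", "TRBV13-2", "TRBV13-3"))
}

#' Classify cells by canonical alpha and oligoclonal beta usage
#'
#' For each cell with at least one TRA chain: the cell is
#' non-canonical-alpha if no TRA chain matches the lineage's canonical V/J
#' pair, and non-oligoclonal-beta if it has at least one TRB chain and none
#' uses a configured oligoclonal V gene. Cells without a TRB have an
#' undefined beta flag (`NA`) and are excluded from beta denominators. The
#' four-way class feeds the Venn partition of non-canonical TCR usage.
#'
#' @param chains Tibble from [cell_chains()], restricted to one cell type.
#' @param type `"iNKT"` or `"MAIT"`.
#' @param rules A [demux_rules()] object (canonical alpha definitions).
#' @param vb_set Oligoclonal V-beta gene set; default [oligoclonal_vb()].
#' @return Tibble of class `canonical_flags`: `barcode`, `canonical_alpha`,
#'   `oligoclonal_beta` (logical, `NA` when no TRB), `class` in
#'   {`canonical_only`, `nc_alpha_only`, `nob_beta_only`, `both`}.
#' @export
classify_canonical <- function(chains, type = c("iNKT", "MAIT"),
                               rules = demux_rules(), vb_set = NULL) {
  type <- match.arg(type)
  if (is.null(vb_set)) vb_set <- oligoclonal_vb(type)
  canon_fun <- if (type == "iNKT") is_canonical_inkt_chain else
    is_canonical_mait_chain
  out <- chains |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      n_tra = sum(.data$chain == "TRA"),
      n_trb = sum(.data$chain == "TRB"),
      canonical_alpha = any(canon_fun(.data$chain, .data$v_gene,
                                      .data$j_gene, rules)),
      oligoclonal_beta = if (sum(.data$chain == "TRB") == 0) NA else
        any(.data$chain == "TRB" &
              normalize_gene(.data$v_gene) %in% vb_set),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_tra >= 1) |>
    dplyr::mutate(
      nc_alpha = !.data$canonical_alpha,
      nob_beta = !is.na(.data$oligoclonal_beta) & !.data$oligoclonal_beta,
      class = dplyr::case_when(
        .data$nc_alpha & .data$nob_beta ~ "both",
        .data$nc_alpha ~ "nc_alpha_only",
        .data$nob_beta ~ "nob_beta_only",
        TRUE ~ "canonical_only"
      )
    ) |>
    dplyr::select(dplyr::all_of(c("barcode", "canonical_alpha",
                                  "oligoclonal_beta", "class")))
  class(out) <- c("canonical_flags", class(out))
  out
}

#' Venn partition counts of non-canonical TCR usage
#'
#' @param flags A [classify_canonical()] result.
#' @return One-row tibble with counts per class and the total.
#' @export
venn_counts <- function(flags) {
  cnt <- table(factor(flags$class,
                      levels = c("canonical_only", "nc_alpha_only",
                                 "nob_beta_only", "both")))
  tibble::tibble(
    canonical_only = as.integer(cnt[["canonical_only"]]),
    nc_alpha_only = as.integer(cnt[["nc_alpha_only"]]),
    nob_beta_only = as.integer(cnt[["nob_beta_only"]]),
    both = as.integer(cnt[["both"]]),
    n_cells = nrow(flags)
  )
}

#' Per-cluster fraction of cells with non-canonical TCR usage
#'
#' Share of cells having at least one non-canonical alpha and/or
#' non-oligoclonal beta chain, per cluster and overall. Supports the
#' exclusion re-analysis in which cells non-canonical on both chains
#' (`class == "both"`) are dropped before recomputing.
#'
#' @param flags A [classify_canonical()] result.
#' @param clusters Cluster labels (tibble or named vector).
#' @param exclude_both Drop `class == "both"` cells first.
#' @param digits Decimal places for the truncated percentage.
#' @return Tibble `cluster`, `n_cells`, `n_noncanonical`,
#'   `pct_noncanonical`; the last row (`cluster == "all"`) is the overall
#'   figure.
#' @export
noncanonical_fraction <- function(flags, clusters, exclude_both = FALSE,
                                  digits = 1) {
  cl <- as_cluster_tbl(clusters)
  x <- flags
  if (exclude_both) x <- dplyr::filter(x, .data$class != "both")
  x <- dplyr::left_join(x, cl, by = "barcode") |>
    dplyr::mutate(cluster = tidyr::replace_na(.data$cluster, "unlabelled"),
                  noncanon = .data$class != "canonical_only")
  per <- x |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_noncanonical = sum(.data$noncanon), .groups = "drop")
  all_row <- tibble::tibble(cluster = "all", n_cells = nrow(x),
                            n_noncanonical = sum(x$noncanon))
  dplyr::bind_rows(per, all_row) |>
    dplyr::mutate(pct_noncanonical = percent_floor(.data$n_noncanonical,
                                                   pmax(.data$n_cells, 1),
                                                   digits))
}
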