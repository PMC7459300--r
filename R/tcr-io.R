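#' @importFrom rlang .data
NULL

# 10x filtered_contig_annotations.csv column set (v2/v3 dialect)
CONTIG_COLUMNS <- c("barcode", "is_cell", "high_confidence", "chain",
                    "v_gene", "d_gene", "j_gene", "c_gene", "full_length",
                    "productive", "cdr3", "cdr3_nt", "reads", "umis",
                    "raw_clonotype_id")

# 10x boolean columns carry "True"/"False"/"None"; "None" (ambiguous call)
# is treated as FALSE.
parse_10x_flag <- function(x) {
  tolower(as.character(x)) %in% "true"
}

#' Read a 10x-style contig annotation table
#'
#' Parses a `filtered_contig_annotations.csv` (10x Cell Ranger VDJ dialect)
#' into a typed tibble. Boolean columns accept `True`/`False`/`true`/`false`
#' and `None` (parsed as `FALSE`). Rows whose chain is not one of
#' TRA/TRB/TRG/TRD are rejected with their row numbers.
#'
#' @param path Path to the CSV file.
#' @return Tibble with one row per contig: `barcode`, `chain`, `v_gene`,
#'   `d_gene`, `j_gene`, `c_gene`, `cdr3` (amino acid), `cdr3_nt`,
#'   `productive`, `high_confidence`, `umis`, `reads`, `raw_clonotype_id`.
#' @export
read_contigs <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  mandatory <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "cdr3_nt",
                 "productive", "high_confidence", "umis")
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0) {
    stop("contig table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!df$chain %in% c("TRA", "TRB", "TRG", "TRD"))
  if (length(bad) > 0) {
    stop("malformed contig rows (unknown chain) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  tibble::tibble(
    barcode = df$barcode,
    chain = df$chain,
    v_gene = df$v_gene,
    d_gene = if ("d_gene" %in% names(df)) df$d_gene else NA_character_,
    j_gene = df$j_gene,
    c_gene = if ("c_gene" %in% names(df)) df$c_gene else NA_character_,
    cdr3 = df$cdr3,
    cdr3_nt = df$cdr3_nt,
    productive = parse_10x_flag(df$productive),
    high_confidence = parse_10x_flag(df$high_confidence),
    umis = as.integer(df$umis),
    reads = if ("reads" %in% names(df)) as.integer(df$reads) else NA_integer_,
    raw_clonotype_id = if ("raw_clonotype_id" %in% names(df))
      df$raw_clonotype_id else NA_character_
  )
}

#' Keep contigs usable for repertoire analysis
#'
#' Retains exactly the contigs called both productive and high-confidence;
#' everything downstream (chain summaries, clonotypes, demultiplexing) is
#' built from these.
#'
#' @param contigs Tibble from [read_contigs()] (or the same columns).
#' @return Filtered tibble.
#' @export
usable_contigs <- function(contigs) {
  dplyr::filter(contigs, .data$productive, .data$high_confidence)
}

#' Normalize a V/J gene name for clonotype comparison
#'
#' Strips IMGT allele suffixes (`*01`) and merges `TRAV11D` into `TRAV11`
#' (the duplicated iNKT V segment, treated as one gene).
#'
#' @param gene Character vector of gene names.
#' @return Normalized character vector.
#' @export
normalize_gene <- function(gene) {
  g <- sub("\\*.*$", "", gene)
  g[!is.na(g) & g == "TRAV11D"] <- "TRAV11"
  g
}

#' Per-cell chain summaries
#'
#' Groups usable contigs by barcode into the set of distinct chains each
#' cell carries. Duplicate identical (chain, V, J, CDR3nt) tuples collapse
#' to one; multiple distinct chains of the same locus are all retained.
#'
#' @param contigs Tibble of usable contigs (see [usable_contigs()]).
#' @return Tibble with columns `barcode`, `chain`, `v_gene` (normalized),
#'   `j_gene` (normalized), `cdr3_nt`, `cdr3`, one row per distinct chain
#'   per cell.
#' @export
cell_chains <- function(contigs) {
  contigs |>
    dplyr::mutate(v_gene = normalize_gene(.data$v_gene),
                  j_gene = normalize_gene(.data$j_gene)) |>
    dplyr::distinct(.data$barcode, .data$chain, .data$v_gene, .data$j_gene,
                    .data$cdr3_nt, .data$cdr3) |>
    dplyr::arrange(.data$barcode, .data$chain, .data$v_gene, .data$j_gene,
                   .data$cdr3_nt)
}

#' Clonotype key for one cell's chain set
#'
#' A clonotype is the set of a cell's productive chains identified by V
#' gene, J gene and CDR3 sequence; two cells with identical chain sets share
#' one rearrangement history. The key is the lexicographically sorted
#' `chain:V:J:CDR3` tuples joined with `";"`, so it is deterministic and
#' invariant to chain order. By default CDR3 identity is at the nucleotide
#' level (the 10x clonotype convention); set `level = "aa"` for amino-acid
#' identity.
#'
#' @param chains Tibble of chains for a single cell (columns `chain`,
#'   `v_gene`, `j_gene`, `cdr3_nt`, `cdr3`), already normalized as in
#'   [cell_chains()].
#' @param level `"nt"` (default) or `"aa"`.
#' @return Single character key.
#' @export
clonotype_key <- function(chains, level = c("nt", "aa")) {
  level <- match.arg(level)
  if (nrow(chains) == 0) stop("cannot build a clonotype key from an empty chain set")
  cdr3 <- if (level == "nt") chains$cdr3_nt else chains$cdr3
  parts <- paste(chains$chain, normalize_gene(chains$v_gene),
                 normalize_gene(chains$j_gene), cdr3, sep = ":")
  paste(sort(parts), collapse = ";")
}

#' Clonotype keys for every cell in a chain table
#'
#' @param chains Tibble from [cell_chains()].
#' @param level CDR3 comparison level, see [clonotype_key()].
#' @return Tibble `barcode`, `clonotype_key`.
#' @export
clonotype_keys <- function(chains, level = c("nt", "aa")) {
  level <- match.arg(level)
  cdr3 <- if (level == "nt") chains$cdr3_nt else chains$cdr3
  tibble::tibble(
    barcode = chains$barcode,
    part = paste(chains$chain, chains$v_gene, chains$j_gene, cdr3,
                 sep = ":")
  ) |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      clonotype_key = paste(sort(.data$part), collapse = ";"),
      .groups = "drop"
    )
}

#' Write contigs in the 10x CSV dialect
#'
#' @param contigs Contig tibble (as from [read_contigs()] or the synthetic
#'   generator).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  out <- tibble::tibble(
    barcode = contigs$barcode,
    is_cell = "True",
    high_confidence = ifelse(contigs$high_confidence, "True", "False"),
    chain = contigs$chain,
    v_gene = contigs$v_gene,
    d_gene = ifelse(is.na(contigs$d_gene), "None", contigs$d_gene),
    j_gene = contigs$j_gene,
    c_gene = ifelse(is.na(contigs$c_gene), "None", contigs$c_gene),
    full_length = "True",
    productive = ifelse(contigs$productive, "True", "None"),
    cdr3 = contigs$cdr3,
    cdr3_nt = contigs$cdr3_nt,
    reads = ifelse(is.na(contigs$reads), contigs$umis * 10L, contigs$reads),
    umis = contigs$umis,
    raw_clonotype_id = ifelse(is.na(contigs$raw_clonotype_id), "None",
                              contigs$raw_clonotype_id)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
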