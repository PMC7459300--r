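#' Demultiplexing rules for a pooled iNKT/MAIT/gamma-delta run
#'
#' Encodes the TCR- and sex-based assignment rules for a pooled cohort in
#' which iNKT cells come from male mice and MAIT cells from female mice:
#' iNKT cells carry the canonical Valpha14-Jalpha18 rearrangement
#' (TRAV11/TRAV11D-TRAJ18), MAIT cells the canonical Valpha19-Jalpha33
#' rearrangement (TRAV1-TRAJ33) and no Y-chromosome expression, and
#' gamma-delta T cells productive TRG plus TRD rearrangements.
#'
#' @param inkt_v,inkt_j Canonical iNKT alpha V set (after TRAV11D merge) and J.
#' @param mait_v_family MAIT V family prefix; any `TRAV1` or `TRAV1-x` gene
#'   matches after allele stripping.
#' @param mait_j Canonical MAIT alpha J.
#' @param y_tolerance Maximum Y-gene UMI total still counted as "not
#'   expressing Y-chromosomal genes" (default 0: Y transcripts are
#'   near-binary in droplet data).
#' @param majority_threshold Cluster-majority fraction above which a cluster
#'   is considered pure (strict `>`; default 0.80). Must lie in (0.5, 1].
#' @param male_only_inkt When `TRUE`, additionally require Y-gene expression
#'   for an iNKT call (strict reading of the male-iNKT pooling).
#' @return A list of class `demux_rules`.
#' @export
demux_rules <- function(inkt_v = "TRAV11", inkt_j = "TRAJ18",
                        mait_v_family = "TRAV1", mait_j = "TRAJ33",
                        y_tolerance = 0, majority_threshold = 0.80,
                        male_only_inkt = FALSE) {
  if (majority_threshold <= 0.5 || majority_threshold > 1) {
    stop("majority_threshold must lie in (0.5, 1]")
  }
  structure(list(inkt_v = inkt_v, inkt_j = inkt_j,
                 mait_v_family = mait_v_family, mait_j = mait_j,
                 y_tolerance = y_tolerance,
                 majority_threshold = majority_threshold,
                 male_only_inkt = male_only_inkt),
            class = "demux_rules")
}

is_canonical_inkt_chain <- function(chain, v, j, rules) {
  chain == "TRA" & normalize_gene(v) %in% rules$inkt_v &
    normalize_gene(j) %in% rules$inkt_j
}

is_mait_v <- function(v, rules) {
  vn <- normalize_gene(v)
  vn == rules$mait_v_family | startsWith(vn, paste0(rules$mait_v_family, "-"))
}

is_canonical_mait_chain <- function(chain, v, j, rules) {
  chain == "TRA" & is_mait_v(v, rules) & normalize_gene(j) %in% rules$mait_j
}

# per-barcode chain-feature summary used by several passes
chain_features <- function(chains, rules) {
  chains |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      has_tra = any(.data$chain == "TRA"),
      has_trb = any(.data$chain == "TRB"),
      has_trg = any(.data$chain == "TRG"),
      has_trd = any(.data$chain == "TRD"),
      inkt_canonical = any(is_canonical_inkt_chain(.data$chain, .data$v_gene,
                                                   .data$j_gene, rules)),
      mait_canonical = any(is_canonical_mait_chain(.data$chain, .data$v_gene,
                                                   .data$j_gene, rules)),
      trav1_bearing = any(.data$chain == "TRA" & is_mait_v(.data$v_gene, rules)),
      .groups = "drop"
    )
}

#' First-pass assignment by TCR genotype and sex
#'
#' Assigns each barcode to iNKT (canonical iNKT alpha), MAIT (canonical MAIT
#' alpha and Y-gene total at or below the tolerance), or gamma-delta T
#' (productive TRG and TRD); all other cells, including barcodes with no
#' usable contigs, are left unassigned.
#'
#' @param chains Tibble from [cell_chains()] (usable contigs only).
#' @param y_totals Named numeric vector of per-cell Y-chromosome UMI totals
#'   for every barcode in the expression matrix (see [y_counts()]); its
#'   names define the barcode universe.
#' @param rules A [demux_rules()] object.
#' @return Tibble `barcode`, `assigned_type`, `pass_id`, `rule_trace`, one
#'   row per barcode in the universe.
#' @export
assign_by_tcr <- function(chains, y_totals, rules = demux_rules()) {
  stopifnot(inherits(rules, "demux_rules"))
  universe <- names(y_totals)
  orphan <- setdiff(unique(chains$barcode), universe)
  if (length(orphan) > 0) {
    warning(length(orphan),
            " barcode(s) present in contigs but absent from the expression",
            " matrix; treated as unassigned")
    chains <- dplyr::filter(chains, .data$barcode %in% universe)
  }
  feats <- chain_features(chains, rules)
  out <- tibble::tibble(barcode = universe) |>
    dplyr::left_join(feats, by = "barcode") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.logical),
                                ~ tidyr::replace_na(.x, FALSE))) |>
    dplyr::mutate(
      y_total = unname(y_totals[.data$barcode]),
      male = .data$y_total > rules$y_tolerance,
      inkt_ok = .data$inkt_canonical &
        (!rules$male_only_inkt | .data$male),
      mait_ok = .data$mait_canonical & !.data$male,
      gd_ok = .data$has_trg & .data$has_trd,
      assigned_type = dplyr::case_when(
        .data$inkt_ok ~ "iNKT",
        .data$mait_ok ~ "MAIT",
        .data$gd_ok ~ "gdT",
        TRUE ~ "unassigned"
      ),
      pass_id = ifelse(.data$assigned_type == "unassigned", NA_character_,
                       "1_tcr"),
      rule_trace = dplyr::case_when(
        .data$inkt_ok ~ "canonical_inkt_alpha",
        .data$mait_canonical & .data$male ~ "mait_alpha_but_male",
        .data$mait_ok ~ "canonical_mait_alpha_female",
        .data$gd_ok ~ "productive_trg_trd",
        !.data$has_tra & !.data$has_trg & !.data$has_trd ~ "no_usable_contigs",
        TRUE ~ "no_rule_matched"
      )
    ) |>
    dplyr::select(dplyr::all_of(c("barcode", "assigned_type", "pass_id",
                                  "rule_trace")))
  out
}

#' Remove putative doublets by mutually exclusive TCR rearrangements
#'
#' A droplet containing both a productive TRA and a productive TRD
#' rearrangement, or both the canonical iNKT and the canonical MAIT alpha
#' rearrangements, must hold two cells; such barcodes are marked
#' `removed_doublet` regardless of any prior label.
#'
#' @param assignments Tibble from [assign_by_tcr()].
#' @param chains Tibble from [cell_chains()].
#' @param rules A [demux_rules()] object.
#' @return Updated assignments tibble.
#' @export
flag_doublets <- function(assignments, chains, rules = demux_rules()) {
  feats <- chain_features(chains, rules)
  tra_trd <- feats$barcode[feats$has_tra & feats$has_trd]
  dual_can <- feats$barcode[feats$inkt_canonical & feats$mait_canonical]
  assignments |>
    dplyr::mutate(
      trace_new = dplyr::case_when(
        .data$barcode %in% tra_trd ~ "tra_plus_trd",
        .data$barcode %in% dual_can ~ "dual_canonical_alpha",
        TRUE ~ NA_character_
      ),
      assigned_type = ifelse(is.na(.data$trace_new), .data$assigned_type,
                             "removed_doublet"),
      pass_id = ifelse(is.na(.data$trace_new), .data$pass_id, "doublet"),
      rule_trace = ifelse(is.na(.data$trace_new), .data$rule_trace,
                          .data$trace_new)
    ) |>
    dplyr::select(-dplyr::all_of("trace_new"))
}

#' Rescue unassigned cells by cluster majority
#'
#' In every cluster in which one assigned cell type exceeds the majority
#' threshold (strict `>`, fraction computed among assigned cells only),
#' unassigned members are reclassified to the majority type and members
#' assigned to a minority type are removed as putative doublets. Clusters at
#' or below the threshold are left untouched and returned as "mixed" for
#' the TCR fallback pass.
#'
#' @param assignments Tibble from [flag_doublets()].
#' @param clusters Tibble `barcode`, `cluster` (or a named character
#'   vector) covering all non-removed cells.
#' @param rules A [demux_rules()] object.
#' @return Updated assignments tibble, with attribute `mixed_clusters`
#'   (character vector of cluster ids not passing the majority rule).
#' @export
cluster_rescue <- function(assignments, clusters, rules = demux_rules()) {
  clusters <- as_cluster_tbl(clusters)
  lab <- stats::setNames(clusters$cluster, clusters$barcode)
  a <- assignments |>
    dplyr::mutate(cluster = unname(lab[.data$barcode]))

  assigned <- a |>
    dplyr::filter(.data$assigned_type %in% c("iNKT", "MAIT", "gdT"),
                  !is.na(.data$cluster))
  maj <- assigned |>
    dplyr::count(.data$cluster, .data$assigned_type) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(frac = .data$n / sum(.data$n)) |>
    dplyr::slice_max(.data$frac, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  empty <- setdiff(unique(stats::na.omit(a$cluster)), maj$cluster)
  if (length(empty) > 0) {
    warning("cluster(s) with zero assigned cells skipped: ",
            paste(empty, collapse = ", "))
  }
  pure <- maj |> dplyr::filter(.data$frac > rules$majority_threshold)
  mixed <- sort(unique(c(empty,
                         setdiff(maj$cluster, pure$cluster))))
  major_of <- stats::setNames(pure$assigned_type, pure$cluster)

  out <- a |>
    dplyr::mutate(
      major = unname(major_of[.data$cluster]),
      rescue = !is.na(.data$major) & .data$assigned_type == "unassigned",
      minority = !is.na(.data$major) &
        .data$assigned_type %in% c("iNKT", "MAIT", "gdT") &
        .data$assigned_type != .data$major,
      assigned_type = dplyr::case_when(
        .data$rescue ~ .data$major,
        .data$minority ~ "removed_doublet",
        TRUE ~ .data$assigned_type
      ),
      pass_id = dplyr::case_when(
        .data$rescue ~ "2_cluster_rescue",
        .data$minority ~ "doublet",
        TRUE ~ .data$pass_id
      ),
      rule_trace = dplyr::case_when(
        .data$rescue ~ paste0("majority_", .data$major, "_in_", .data$cluster),
        .data$minority ~ paste0("minority_in_", .data$cluster),
        TRUE ~ .data$rule_trace
      )
    ) |>
    dplyr::select(dplyr::all_of(c("barcode", "assigned_type", "pass_id",
                                  "rule_trace")))
  attr(out, "mixed_clusters") <- mixed
  out
}

#' Fallback assignment by TCR V-segment expression in mixed clusters
#'
#' For cells still unassigned after cluster rescue, in clusters not passing
#' the majority rule: cells bearing a TRAV1-family alpha chain become MAIT;
#' cells bearing V segments of both TRG and TRD become gamma-delta T.
#'
#' @param assignments Tibble from [cluster_rescue()] (the `mixed_clusters`
#'   attribute is used unless `mixed_clusters` is given).
#' @param chains Tibble from [cell_chains()].
#' @param clusters Cluster labels as in [cluster_rescue()].
#' @param rules A [demux_rules()] object.
#' @param mixed_clusters Optional explicit character vector of mixed
#'   cluster ids.
#' @return Updated assignments tibble.
#' @export
tcr_fallback <- function(assignments, chains, clusters,
                         rules = demux_rules(), mixed_clusters = NULL) {
  if (is.null(mixed_clusters)) {
    mixed_clusters <- attr(assignments, "mixed_clusters")
  }
  if (is.null(mixed_clusters) || length(mixed_clusters) == 0) {
    return(assignments)
  }
  clusters <- as_cluster_tbl(clusters)
  lab <- stats::setNames(clusters$cluster, clusters$barcode)
  feats <- chain_features(chains, rules)
  mait_bc <- feats$barcode[feats$trav1_bearing]
  gd_bc <- feats$barcode[feats$has_trg & feats$has_trd]

  assignments |>
    dplyr::mutate(
      in_mixed = unname(lab[.data$barcode]) %in% mixed_clusters,
      eligible = .data$assigned_type == "unassigned" & .data$in_mixed,
      new_type = dplyr::case_when(
        .data$eligible & .data$barcode %in% mait_bc ~ "MAIT",
        .data$eligible & .data$barcode %in% gd_bc ~ "gdT",
        TRUE ~ NA_character_
      ),
      assigned_type = ifelse(is.na(.data$new_type), .data$assigned_type,
                             .data$new_type),
      pass_id = ifelse(is.na(.data$new_type), .data$pass_id, "3_tcr_fallback"),
      rule_trace = dplyr::case_when(
        is.na(.data$new_type) ~ .data$rule_trace,
        .data$new_type == "MAIT" ~ "fallback_trav1",
        TRUE ~ "fallback_trg_trd_v"
      )
    ) |>
    dplyr::select(dplyr::all_of(c("barcode", "assigned_type", "pass_id",
                                  "rule_trace")))
}

as_cluster_tbl <- function(clusters) {
  if (is.data.frame(clusters)) {
    stopifnot(all(c("barcode", "cluster") %in% names(clusters)))
    tibble::as_tibble(clusters[c("barcode", "cluster")])
  } else {
    tibble::tibble(barcode = names(clusters),
                   cluster = unname(as.character(clusters)))
  }
}

#' Full three-pass demultiplexing of a pooled cohort
#'
#' Runs [assign_by_tcr()], [flag_doublets()], [cluster_rescue()] and
#' [tcr_fallback()] in order and returns the final per-barcode assignment
#' with rule provenance. The result is a partition: every barcode in the
#' expression matrix appears exactly once as iNKT, MAIT, gdT, unassigned or
#' removed_doublet.
#'
#' @inheritParams assign_by_tcr
#' @inheritParams cluster_rescue
#' @return Assignments tibble with a `summary` attribute (counts per type
#'   and pass) retrievable with [glance()].
#' @export
demultiplex <- function(chains, y_totals, clusters, rules = demux_rules()) {
  out <- assign_by_tcr(chains, y_totals, rules) |>
    flag_doublets(chains, rules) |>
    cluster_rescue(clusters, rules)
  out <- tcr_fallback(out, chains, clusters, rules)
  summary <- out |>
    dplyr::count(.data$assigned_type, .data$pass_id, name = "n_cells") |>
    dplyr::arrange(.data$assigned_type, .data$pass_id)
  attr(out, "summary") <- summary
  class(out) <- c("demux_result", class(out))
  out
}

#' @rdname demultiplex
#' @param x A `demux_result`.
#' @param ... Unused.
#' @method glance demux_result
#' @export
glance.demux_result <- function(x, ...) {
  s <- attr(x, "summary")
  tot <- s |>
    dplyr::group_by(.data$assigned_type) |>
    dplyr::summarise(n = sum(.data$n_cells), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "assigned_type", values_from = "n")
  tot$n_barcodes <- nrow(x)
  tot
}
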