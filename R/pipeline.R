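#' Run the full pooled-cohort analysis pipeline
#'
#' Orchestrates simulate/load -> QC -> demultiplex -> repertoire ->
#' signature scoring (-> DEG overlap) with one configuration, writing
#' per-stage tables and a machine-readable run summary sufficient to
#' reproduce the run. Cell counts reconcile across stages: input barcodes
#' equal QC-kept plus QC-removed, and kept cells equal assigned plus
#' unassigned plus doublet-removed.
#'
#' @param config A configuration list, or the path of a YAML file holding
#'   one. Recognized fields:
#'   \describe{
#'     \item{out_dir}{Output directory (required).}
#'     \item{seed}{Integer seed for the synthetic stage (default 1).}
#'     \item{synth}{List of [synth_config()] arguments for a simulated
#'       cohort; ignored when `input_dir` is given.}
#'     \item{input_dir}{Directory with a written cohort to load instead of
#'       simulating (see [write_cohort()]).}
#'     \item{clusters}{Optional path of a `barcode`/`cluster` TSV; for
#'       synthetic cohorts the ground-truth clusters are used when absent
#'       (clustering itself is an input to this pipeline, not a stage).}
#'     \item{qc}{List with `min_umi`, `max_mito`.}
#'     \item{demux}{List of [demux_rules()] arguments, plus optional
#'       `drop_clusters` (cluster ids excluded after demultiplexing).}
#'     \item{repertoire}{List with `repeat_gt` (default 3).}
#'     \item{signatures}{Named list of gene vectors to score; for synthetic
#'       cohorts defaults to the designed cluster marker sets.}
#'     \item{overlap}{Optional list with `deg_a`, `deg_b` (TSV paths:
#'       gene, log2fc, padj), `padj_max`, `reps`, `seed`.}
#'     \item{stages}{Named logical list to disable stages, e.g.
#'       `list(score = FALSE)`.}
#'   }
#' @return The run summary (a list), invisibly written as
#'   `run_summary.json` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- utils::modifyList(
    list(qc = TRUE, demux = TRUE, repertoire = TRUE, score = TRUE,
         overlap = !is.null(config$overlap)),
    config$stages %||% list())
  seed <- config$seed %||% 1L

  summary <- list(
    pipeline_version = as.character(utils::packageVersion("trexr")),
    seed = seed,
    stages_enabled = stages
  )
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, " failed: ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- input ------------------------------------------------------------
  cohort <- run_stage("input", {
    if (!is.null(config$input_dir)) {
      read_cohort(config$input_dir)
    } else {
      cfg <- do.call(synth_config,
                     utils::modifyList(config$synth %||% list(),
                                       list(seed = seed)))
      co <- generate_cohort(cfg)
      write_cohort(co, file.path(out_dir, "cohort"))
      co
    }
  })
  if (!is.null(config$clusters)) {
    clusters <- readr::read_tsv(config$clusters, progress = FALSE,
                                col_types = readr::cols(.default = "c"))
    names(clusters)[1:2] <- c("barcode", "cluster")
  } else if (!is.null(cohort$truth)) {
    clusters <- tibble::tibble(barcode = cohort$truth$barcode,
                               cluster = cohort$truth$true_cluster)
  } else {
    stop("no cluster labels: supply config$clusters")
  }
  summary$input <- list(n_barcodes = ncol(cohort$matrix$counts),
                        n_genes = nrow(cohort$matrix$counts),
                        n_contigs = nrow(cohort$contigs))

  # --- qc ---------------------------------------------------------------
  if (stages$qc) {
    qc <- run_stage("qc", {
      qc_filter(cohort$matrix,
                min_umi = config$qc$min_umi %||% 1000,
                max_mito = config$qc$max_mito %||% 0.10)
    })
    readr::write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"),
                     progress = FALSE)
    kept <- qc$matrix
    summary$qc <- list(min_umi = config$qc$min_umi %||% 1000,
                       max_mito = config$qc$max_mito %||% 0.10,
                       n_in = nrow(qc$report),
                       n_kept = sum(qc$report$kept),
                       n_removed = sum(!qc$report$kept))
  } else {
    kept <- cohort$matrix
  }
  lognorm <- run_stage("normalize", lognormalize(kept))

  # --- demux ------------------------------------------------------------
  chains <- cell_chains(usable_contigs(cohort$contigs)) |>
    dplyr::filter(.data$barcode %in% colnames(kept$counts))
  assignments <- NULL
  if (stages$demux) {
    demux_cfg <- config$demux %||% list()
    drop_clusters <- demux_cfg$drop_clusters
    demux_cfg$drop_clusters <- NULL
    rules <- do.call(demux_rules, demux_cfg)
    assignments <- run_stage("demux", {
      demultiplex(chains, y_counts(kept), clusters, rules)
    })
    if (!is.null(drop_clusters)) {
      lab <- stats::setNames(clusters$cluster, clusters$barcode)
      keep_bc <- !(unname(lab[assignments$barcode]) %in% drop_clusters)
      assignments <- assignments[keep_bc, ]
    }
    readr::write_tsv(assignments, file.path(out_dir, "assignments.tsv"),
                     progress = FALSE)
    counts <- table(assignments$assigned_type)
    summary$demux <- c(as.list(counts),
                       list(n_cells = nrow(assignments)))
  }

  # --- repertoire -------------------------------------------------------
  if (stages$repertoire && !is.null(assignments)) {
    summary$repertoire <- run_stage("repertoire", {
      repeat_gt <- config$repertoire$repeat_gt %||% 3
      out <- list()
      for (ty in c("iNKT", "MAIT", "gdT")) {
        if (!any(assignments$assigned_type == ty)) next
        tab <- build_clonotype_table(chains, assignments, clusters, ty)
        spec <- repeat_spectrum(tab)
        readr::write_tsv(tab, file.path(out_dir, paste0("clonotypes_", ty, ".tsv")),
                         progress = FALSE)
        readr::write_tsv(spec, file.path(out_dir, paste0("spectrum_", ty, ".tsv")),
                         progress = FALSE)
        readr::write_tsv(cluster_equitability(tab),
                         file.path(out_dir, paste0("equitability_", ty, ".tsv")),
                         progress = FALSE)
        s <- spectrum_summary(spec, repeat_gt = repeat_gt)
        out[[ty]] <- list(n_clonotypes = s$total_clonotypes,
                          n_cells = s$total_cells,
                          pct_singleton_clonotypes = s$pct_singleton_clonotypes,
                          pct_repeat_gt = s$pct_repeat_gt)
      }
      out
    })
  }

  # --- signature scoring ------------------------------------------------
  if (stages$score) {
    sigs <- config$signatures %||% cohort$markers
    if (!is.null(sigs) && length(sigs) > 0) {
      scores <- run_stage("score", {
        purrr::imap_dfr(sigs, function(g, nm) {
          suppressMessages(signature_score(lognorm, g, name = nm))
        })
      })
      readr::write_tsv(scores, file.path(out_dir, "signature_scores.tsv"),
                       progress = FALSE)
      summary$score <- list(n_signatures = length(sigs),
                            n_cells = ncol(lognorm$counts))
    }
  }

  # --- DEG overlap ------------------------------------------------------
  if (stages$overlap && !is.null(config$overlap)) {
    summary$overlap <- run_stage("overlap", {
      oc <- config$overlap
      ta <- readr::read_tsv(oc$deg_a, progress = FALSE,
                            col_types = readr::cols(gene = "c",
                                                    .default = "d"))
      tb <- readr::read_tsv(oc$deg_b, progress = FALSE,
                            col_types = readr::cols(gene = "c",
                                                    .default = "d"))
      universe <- intersect(ta$gene, tb$gene)
      da <- extract_degs(ta[ta$gene %in% universe, ],
                         padj_max = oc$padj_max %||% 0.05)
      db <- extract_degs(tb[tb$gene %in% universe, ],
                         padj_max = oc$padj_max %||% 0.05)
      res <- direction_consistent_overlap(da$up, da$down, db$up, db$down,
                                          universe,
                                          R = oc$reps %||% 10000,
                                          seed = oc$seed %||% seed)
      jsonlite::write_json(tidy(res), file.path(out_dir, "overlap.json"),
                           auto_unbox = TRUE, digits = NA)
      as.list(tidy(res))
    })
  }

  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
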