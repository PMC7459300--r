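# Standard genetic code, amino acid -> synonymous codons. Clone CDR3
# nucleotide sequences are drawn per clone from synonymous codons so that
# clones sharing an invariant amino-acid CDR3 still carry distinct
# nucleotide rearrangements (as real V(D)J junctions do).
CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  K = c("AAA", "AAG"), M = "ATG", F = c("TTT", "TTC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG", Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG")
)

reverse_translate <- function(aa) {
  paste(vapply(strsplit(aa, "")[[1]],
               function(r) sample(CODONS[[r]], 1), character(1)),
        collapse = "")
}

random_cdr3 <- function(len) {
  stopifnot(len >= 3)
  mid <- sample(names(CODONS), len - 2, replace = TRUE)
  paste0("C", paste(mid, collapse = ""), sample(c("F", "W"), 1))
}

MITO_GENE_NAMES <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8",
                     "mt-Atp6", "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4",
                     "mt-Nd5", "mt-Nd6", "mt-Cytb")
Y_GENE_NAMES <- c("Ddx3y", "Eif2s3y", "Uty", "Kdm5d")

#' Default cluster layout of a pooled innate T-cell cohort
#'
#' Clusters per cell type mirroring the progenitor/effector structure of
#' thymic innate T cells (iNKT: NKTp-like N1 and effector N4/N7; MAIT:
#' M1/M2/M5/M8; gamma-delta: progenitor G1 and immature type-1/type-17
#' regions G4/G6). Each cluster gets a block of marker genes whose mean is
#' shifted up two-fold-per-unit `shift` in member cells.
#'
#' @return Tibble `cluster`, `cell_type`, `prob`, `n_markers`, `shift`.
#' @export
default_cluster_spec <- function() {
  tibble::tibble(
    cluster = c("N1", "N4", "N7", "M1", "M2", "M5", "M8", "G1", "G4", "G6"),
    cell_type = c(rep("iNKT", 3), rep("MAIT", 4), rep("gdT", 3)),
    prob = c(0.2, 0.4, 0.4, 0.25, 0.25, 0.25, 0.25, 0.3, 0.35, 0.35),
    n_markers = 5L,
    shift = 2
  )
}

#' Configuration for the synthetic pooled-cohort generator
#'
#' Defines the study conditions the generator emulates: equal numbers of
#' male iNKT, female MAIT and gamma-delta T cells pooled into one droplet
#' run, with canonical and non-canonical TCR rearrangements, designed
#' cross-type doublets, Y-chromosome and mitochondrial marker genes,
#' cluster structure, and heavy-tailed clone sizes.
#'
#' @param n_cells_per_type Named integer vector, cells per `iNKT`, `MAIT`,
#'   `gdT`.
#' @param doublet_fraction Proportion of droplets that are designed
#'   cross-type doublets, in [0, 1).
#' @param noncanonical_alpha_rate Per-clone probability (iNKT/MAIT) of a
#'   non-canonical alpha rearrangement drawn from a decoy V/J pool
#'   (including the Valpha10/Jalpha50 pair), in [0, 1).
#' @param nonoligoclonal_beta_rate Per-clone probability of a beta chain
#'   outside the oligoclonal V-beta set, in [0, 1).
#' @param clonal_shape Power-law exponent of the clone-size distribution
#'   (P(s) proportional to s^-shape, truncated); larger values give more
#'   singletons. Scalar, or named per type.
#' @param n_genes Number of regular (non-mito, non-Y) genes.
#' @param n_mito_genes,n_ygenes Numbers of mitochondrial and Y-chromosome
#'   genes.
#' @param cluster_spec Cluster layout tibble, see [default_cluster_spec()].
#' @param umi_depth_mean Mean per-cell UMI depth.
#' @param qc_fail_fraction Share of singlet cells planted as QC violators
#'   (half low-UMI, half high-mito), in [0, 1).
#' @param beta_rate Per-clone probability that an alpha-beta clone carries
#'   a TRB chain.
#' @param chain_dropout_rate Per-cell probability that the type-identifying
#'   chain (TRA for iNKT/MAIT, TRG for gdT) escapes contig assembly,
#'   leaving the cell for cluster rescue.
#' @param junk_contig_rate Per-cell probability of one additional
#'   non-usable contig (non-productive or low-confidence).
#' @param nb_dispersion Negative-binomial dispersion of gene counts.
#' @param seed Integer seed; a fixed seed makes outputs byte-identical.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_cells_per_type = c(iNKT = 500, MAIT = 500, gdT = 500),
                         doublet_fraction = 0.05,
                         noncanonical_alpha_rate = 0.09,
                         nonoligoclonal_beta_rate = 0.08,
                         clonal_shape = 3.0,
                         n_genes = 200,
                         n_mito_genes = 10,
                         n_ygenes = 4,
                         cluster_spec = default_cluster_spec(),
                         umi_depth_mean = 5000,
                         qc_fail_fraction = 0.04,
                         beta_rate = 0.95,
                         chain_dropout_rate = 0.05,
                         junk_contig_rate = 0.05,
                         nb_dispersion = 0.3,
                         seed = 1L) {
  cfg <- list(n_cells_per_type = n_cells_per_type,
              doublet_fraction = doublet_fraction,
              noncanonical_alpha_rate = noncanonical_alpha_rate,
              nonoligoclonal_beta_rate = nonoligoclonal_beta_rate,
              clonal_shape = clonal_shape, n_genes = n_genes,
              n_mito_genes = n_mito_genes, n_ygenes = n_ygenes,
              cluster_spec = tibble::as_tibble(cluster_spec),
              umi_depth_mean = umi_depth_mean,
              qc_fail_fraction = qc_fail_fraction,
              beta_rate = beta_rate,
              chain_dropout_rate = chain_dropout_rate,
              junk_contig_rate = junk_contig_rate,
              nb_dispersion = nb_dispersion, seed = as.integer(seed))
  types <- c("iNKT", "MAIT", "gdT")
  if (!all(types %in% names(cfg$n_cells_per_type))) {
    stop("n_cells_per_type must name iNKT, MAIT and gdT")
  }
  for (f in c("n_cells_per_type", "n_genes", "n_mito_genes", "n_ygenes",
              "umi_depth_mean", "clonal_shape", "nb_dispersion")) {
    if (any(cfg[[f]] <= 0)) stop("config field `", f, "` must be positive")
  }
  for (f in c("doublet_fraction", "noncanonical_alpha_rate",
              "nonoligoclonal_beta_rate", "qc_fail_fraction",
              "chain_dropout_rate", "junk_contig_rate")) {
    if (any(cfg[[f]] < 0 | cfg[[f]] >= 1)) {
      stop("config field `", f, "` must lie in [0, 1)")
    }
  }
  if (!all(types %in% cfg$cluster_spec$cell_type)) {
    stop("config field `cluster_spec` must cover all three cell types")
  }
  structure(cfg, class = "synth_config")
}

shape_for <- function(cfg, type) {
  s <- cfg$clonal_shape
  if (length(s) > 1) s[[type]] else s
}

#' Sample clone sizes from a truncated discrete power law
#'
#' Draws clone sizes with P(s) proportional to s^-shape on 1..min(n, 1000)
#' until they cover `n_cells` cells; the last clone is trimmed to fit
#' exactly.
#'
#' @param n_cells Number of cells to cover.
#' @param shape Positive power-law exponent.
#' @return Integer vector of clone sizes summing to `n_cells`.
#' @export
sample_clone_sizes <- function(n_cells, shape) {
  smax <- min(n_cells, 1000L)
  p <- (seq_len(smax))^(-shape)
  sizes <- sample.int(smax, n_cells, replace = TRUE, prob = p)
  cum <- cumsum(sizes)
  cut <- which(cum >= n_cells)[1]
  sizes <- sizes[seq_len(cut)]
  sizes[cut] <- sizes[cut] - (cum[cut] - n_cells)
  sizes[sizes > 0]
}

#' Power-law exponent targeting a singleton-cell fraction
#'
#' Under the truncated power law, the expected fraction of cells sitting in
#' singleton clones is `1 / sum(s^(1-shape))`; this inverts that relation
#' numerically.
#'
#' @param target Desired singleton-cell fraction in (0, 1).
#' @param max_size Truncation point of the size distribution.
#' @return The exponent achieving the target in expectation.
#' @export
calibrate_clonal_shape <- function(target, max_size = 1000) {
  stopifnot(target > 0, target < 1)
  f <- function(a) 1 / sum(seq_len(max_size)^(1 - a)) - target
  stats::uniroot(f, c(1.05, 12), tol = 1e-8)$root
}

# Decoy (non-canonical) alpha V/J pools, including the Valpha10/Jalpha50
# pair reported as the most frequent non-canonical iNKT TCR.
DECOY_ALPHA <- list(
  iNKT = list(c("TRAV10", "TRAJ50"), c("TRAV13-1", "TRAJ25"),
              c("TRAV6-7", "TRAJ12"), c("TRAV9-4", "TRAJ31")),
  MAIT = list(c("TRAV10", "TRAJ50"), c("TRAV12-1", "TRAJ22"),
              c("TRAV7-2", "TRAJ40"), c("TRAV16", "TRAJ26"))
)
DECOY_BETA_V <- c("TRBV3", "TRBV5", "TRBV12-1", "TRBV31")
CANONICAL_CDR3A <- c(iNKT = "CVVGDRGSALGRLHF", MAIT = "CAVRDSNYQLIW")
TRG_V <- c("TRGV1", "TRGV4", "TRGV5", "TRGV6", "TRGV7")
TRG_BASE_LEN <- c(TRGV1 = 14L, TRGV4 = 13L, TRGV5 = 12L, TRGV6 = 15L,
                  TRGV7 = 12L)
TRD_V <- c("TRDV2-2", "TRDV4", "TRDV5")

chain_row <- function(chain, v, j, cdr3_aa, d = NA_character_,
                      c_gene = NA_character_) {
  tibble::tibble(chain = chain, v_gene = v, d_gene = d, j_gene = j,
                 c_gene = c_gene, cdr3 = cdr3_aa,
                 cdr3_nt = reverse_translate(cdr3_aa))
}

# Chains of one clone; returns list(chains = tibble, canonical_alpha,
# oligoclonal_beta) with NA flags where undefined (gdT; no beta).
gen_clone_chains <- function(type, cfg) {
  if (type == "gdT") {
    vg <- sample(TRG_V, 1)
    glen <- TRG_BASE_LEN[[vg]] + sample(-1:1, 1)
    dlen <- sample(10:20, 1)
    chains <- dplyr::bind_rows(
      chain_row("TRG", vg, "TRGJ1", random_cdr3(glen), c_gene = "TRGC1"),
      chain_row("TRD", sample(TRD_V, 1), sample(c("TRDJ1", "TRDJ2"), 1),
                random_cdr3(dlen), d = "TRDD2", c_gene = "TRDC")
    )
    return(list(chains = chains, canonical_alpha = NA,
                oligoclonal_beta = NA))
  }
  canonical <- stats::runif(1) >= cfg$noncanonical_alpha_rate
  if (canonical) {
    v <- if (type == "iNKT") sample(c("TRAV11", "TRAV11D"), 1) else "TRAV1"
    j <- if (type == "iNKT") "TRAJ18" else "TRAJ33"
    # occasional allele suffix exercises gene-name normalization
    if (stats::runif(1) < 0.2) v <- paste0(v, "*01")
    alpha <- chain_row("TRA", v, j, CANONICAL_CDR3A[[type]], c_gene = "TRAC")
  } else {
    vj <- DECOY_ALPHA[[type]][[sample(length(DECOY_ALPHA[[type]]), 1)]]
    alpha <- chain_row("TRA", vj[1], vj[2], random_cdr3(sample(10:14, 1)),
                       c_gene = "TRAC")
  }
  has_beta <- stats::runif(1) < cfg$beta_rate
  if (has_beta) {
    oligo <- stats::runif(1) >= cfg$nonoligoclonal_beta_rate
    vb <- if (oligo) sample(oligoclonal_vb(type), 1) else
      sample(DECOY_BETA_V, 1)
    beta <- chain_row("TRB", vb,
                      sample(c("TRBJ1-1", "TRBJ2-1", "TRBJ2-5", "TRBJ2-7"), 1),
                      random_cdr3(sample(12:16, 1)), d = "TRBD1",
                      c_gene = "TRBC1")
    chains <- dplyr::bind_rows(alpha, beta)
    oligo_flag <- oligo
  } else {
    chains <- alpha
    oligo_flag <- NA
  }
  list(chains = chains, canonical_alpha = canonical,
       oligoclonal_beta = oligo_flag)
}

random_barcodes <- function(n) {
  repeat {
    bc <- vapply(seq_len(n), function(i) {
      paste0(paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE),
                   collapse = ""), "-1")
    }, character(1))
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Generate a synthetic pooled innate T-cell cohort
#'
#' Produces a raw gene-by-cell UMI matrix, a 10x-style contig table and a
#' ground-truth table for a pooled cohort of male iNKT, female MAIT and
#' gamma-delta T cells, with designed cross-type doublets, planted QC
#' violators, cluster marker structure and power-law clone sizes. All
#' randomness is governed by `config$seed`: the same config yields
#' byte-identical outputs.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_cohort` with `matrix` (raw
#'   [gene_matrix()]), `contigs` (tibble in the [read_contigs()] layout)
#'   and `truth` (tibble: `barcode`, `true_type`, `sex`, `is_doublet`,
#'   `true_cluster`, `canonical_alpha`, `oligoclonal_beta`, `clone_id`,
#'   `qc_violation`).
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  types <- c("iNKT", "MAIT", "gdT")

  # --- clones and cells per type ---------------------------------------
  cells <- list()
  clones <- list()
  for (ty in types) {
    n <- cfg$n_cells_per_type[[ty]]
    sizes <- sample_clone_sizes(n, shape_for(cfg, ty))
    ids <- sprintf("%s_clone%04d", ty, seq_along(sizes))
    for (i in seq_along(ids)) {
      clones[[ids[i]]] <- gen_clone_chains(ty, cfg)
    }
    spec <- cfg$cluster_spec[cfg$cluster_spec$cell_type == ty, ]
    cells[[ty]] <- tibble::tibble(
      true_type = ty,
      sex = switch(ty, iNKT = "male", MAIT = "female",
                   gdT = sample(c("male", "female"), n, replace = TRUE)),
      true_cluster = sample(spec$cluster, n, replace = TRUE,
                            prob = spec$prob),
      clone_id = rep(ids, times = sizes)[sample.int(n)]
    )
  }
  cells <- dplyr::bind_rows(cells)
  n_total <- nrow(cells)

  # --- designed doublets: pair a host cell with an extra cell of a
  # different type; the droplet carries the union of contigs and the sum
  # of counts ----------------------------------------------------------
  n_doub <- round(cfg$doublet_fraction * n_total)
  cells$droplet <- seq_len(n_total)
  cells$is_host <- TRUE
  if (n_doub > 0) {
    hosts <- sample.int(n_total, n_doub)
    extra <- purrr::map_dfr(hosts, function(h) {
      ty <- sample(setdiff(types, cells$true_type[h]), 1)
      sizes_id <- sprintf("%s_extra%04d", ty, h)
      clones[[sizes_id]] <<- gen_clone_chains(ty, cfg)
      spec <- cfg$cluster_spec[cfg$cluster_spec$cell_type == ty, ]
      tibble::tibble(
        true_type = ty,
        sex = switch(ty, iNKT = "male", MAIT = "female",
                     gdT = sample(c("male", "female"), 1)),
        true_cluster = sample(spec$cluster, 1, prob = spec$prob),
        clone_id = sizes_id, droplet = cells$droplet[h], is_host = FALSE
      )
    })
    cells <- dplyr::bind_rows(cells, extra)
  }
  droplets <- sort(unique(cells$droplet))
  bc <- random_barcodes(length(droplets))
  names(bc) <- as.character(droplets)
  cells$barcode <- unname(bc[as.character(cells$droplet)])

  # --- gene universe ----------------------------------------------------
  reg_genes <- sprintf("Gene%04d", seq_len(cfg$n_genes))
  mito_genes <- c(MITO_GENE_NAMES,
                  sprintf("mt-Gene%02d", seq_len(max(0, cfg$n_mito_genes -
                                                       length(MITO_GENE_NAMES)))))
  mito_genes <- mito_genes[seq_len(cfg$n_mito_genes)]
  y_genes <- c(Y_GENE_NAMES,
               sprintf("Ygene%02d", seq_len(max(0, cfg$n_ygenes -
                                                  length(Y_GENE_NAMES)))))
  y_genes <- y_genes[seq_len(cfg$n_ygenes)]
  all_genes <- c(reg_genes, mito_genes, y_genes)

  # cluster marker blocks: disjoint slices of the regular genes
  spec <- cfg$cluster_spec
  marker_idx <- list()
  nxt <- 1L
  for (i in seq_len(nrow(spec))) {
    take <- min(spec$n_markers[i], cfg$n_genes - nxt + 1L)
    marker_idx[[spec$cluster[i]]] <- seq.int(nxt, length.out = max(take, 0))
    nxt <- nxt + take
  }

  # --- per source-cell expected depth and QC violations ----------------
  n_src <- nrow(cells)
  depth <- stats::rlnorm(n_src, log(cfg$umi_depth_mean) - 0.5 * 0.3^2, 0.3)
  mito_frac <- stats::runif(n_src, 0.005, 0.08)
  viol <- rep("none", n_src)
  doublet_droplets <- cells$droplet[!cells$is_host]
  host_idx <- which(cells$is_host & !(cells$droplet %in% doublet_droplets))
  n_viol <- round(cfg$qc_fail_fraction * length(host_idx))
  if (n_viol > 0) {
    chosen <- sample(host_idx, n_viol)
    half <- seq_len(ceiling(n_viol / 2))
    low <- chosen[half]
    high <- setdiff(chosen, low)
    depth[low] <- stats::runif(length(low), 300, 900)
    mito_frac[high] <- stats::runif(length(high), 0.12, 0.30)
    viol[low] <- "low_umi"
    viol[high] <- "high_mito"
  }

  # --- counts per source cell, then summed per droplet ------------------
  w <- stats::rgamma(cfg$n_genes, 2, 2) + 0.05
  w_mito <- stats::rgamma(cfg$n_mito_genes, 2, 2) + 0.05
  size_nb <- 1 / cfg$nb_dispersion
  y_share <- 12 / cfg$umi_depth_mean  # expected male Y total at mean depth

  counts <- matrix(0L, nrow = length(all_genes), ncol = n_src,
                   dimnames = list(all_genes, NULL))
  for (i in seq_len(n_src)) {
    wi <- w
    mk <- marker_idx[[cells$true_cluster[i]]]
    shift <- spec$shift[spec$cluster == cells$true_cluster[i]][1]
    if (length(mk) > 0) wi[mk] <- wi[mk] * 2^shift
    male <- cells$sex[i] == "male"
    y_mu <- if (male) depth[i] * y_share else 0
    reg_mu <- depth[i] * (1 - mito_frac[i]) - y_mu
    mu <- c(reg_mu * wi / sum(wi),
            depth[i] * mito_frac[i] * w_mito / sum(w_mito),
            rep(y_mu / cfg$n_ygenes, cfg$n_ygenes))
    counts[, i] <- stats::rnbinom(length(mu), mu = pmax(mu, 0),
                                  size = size_nb)
  }
  # aggregate to droplets (doublets sum their two cells)
  drop_of <- match(cells$droplet, droplets)
  agg <- matrix(0L, nrow = length(all_genes), ncol = length(droplets),
                dimnames = list(all_genes, unname(bc)))
  for (i in seq_len(n_src)) {
    agg[, drop_of[i]] <- agg[, drop_of[i]] + counts[, i]
  }
  gm <- gene_matrix(agg, layer = "raw")

  # --- contigs ----------------------------------------------------------
  dropout <- cells$is_host &
    stats::runif(n_src) < cfg$chain_dropout_rate &
    !(cells$droplet %in% cells$droplet[!cells$is_host])
  contigs <- purrr::map_dfr(seq_len(n_src), function(i) {
    ch <- clones[[cells$clone_id[i]]]$chains
    if (dropout[i]) {
      drop_chain <- if (cells$true_type[i] == "gdT") "TRG" else "TRA"
      ch <- ch[ch$chain != drop_chain, , drop = FALSE]
    }
    if (nrow(ch) == 0) return(NULL)
    umis <- stats::rpois(nrow(ch), 2) + 1L
    tibble::tibble(
      barcode = cells$barcode[i], chain = ch$chain, v_gene = ch$v_gene,
      d_gene = ch$d_gene, j_gene = ch$j_gene, c_gene = ch$c_gene,
      cdr3 = ch$cdr3, cdr3_nt = ch$cdr3_nt,
      productive = TRUE, high_confidence = TRUE,
      umis = umis, reads = umis * 10L,
      raw_clonotype_id = cells$clone_id[i]
    )
  })
  # sprinkle non-usable background contigs to exercise the usable filter
  junk_cells <- which(stats::runif(n_src) < cfg$junk_contig_rate)
  if (length(junk_cells) > 0) {
    junk <- tibble::tibble(
      barcode = cells$barcode[junk_cells],
      chain = sample(c("TRA", "TRB"), length(junk_cells), replace = TRUE),
      v_gene = "TRAV21", d_gene = NA_character_, j_gene = "TRAJ2",
      c_gene = NA_character_,
      cdr3 = "CAVF", cdr3_nt = vapply(seq_along(junk_cells),
                                      function(i) reverse_translate("CAVF"),
                                      character(1)),
      productive = FALSE,
      high_confidence = stats::runif(length(junk_cells)) < 0.5,
      umis = 1L, reads = 10L, raw_clonotype_id = NA_character_
    )
    contigs <- dplyr::bind_rows(contigs, junk)
  }
  contigs <- dplyr::arrange(contigs, .data$barcode, .data$chain,
                            .data$v_gene, .data$cdr3_nt)

  # --- truth (one row per droplet, host cell attributes) ----------------
  host <- cells[cells$is_host, ]
  is_doub <- host$droplet %in% cells$droplet[!cells$is_host]
  truth <- tibble::tibble(
    barcode = host$barcode,
    true_type = host$true_type,
    sex = host$sex,
    is_doublet = is_doub,
    true_cluster = host$true_cluster,
    canonical_alpha = vapply(host$clone_id,
                             function(id) clones[[id]]$canonical_alpha,
                             logical(1)),
    oligoclonal_beta = vapply(host$clone_id,
                              function(id) clones[[id]]$oligoclonal_beta,
                              logical(1)),
    clone_id = host$clone_id,
    qc_violation = viol[cells$is_host]
  )
  markers <- purrr::map(marker_idx, function(ix) reg_genes[ix])
  structure(list(matrix = gm, contigs = contigs, truth = truth,
                 markers = markers, config = cfg),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d droplets (%d doublets), %d genes, %d contigs\n",
              nrow(x$truth), sum(x$truth$is_doublet), nrow(x$matrix$counts),
              nrow(x$contigs)))
  invisible(x)
}

#' Write a cohort as a 10x-style directory
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv`,
#' `filtered_contig_annotations.csv` and `truth.tsv` under `out_dir`; the
#' files round-trip losslessly through [read_cohort()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(
    matrix = file.path(out_dir, "matrix.mtx"),
    features = file.path(out_dir, "features.tsv"),
    barcodes = file.path(out_dir, "barcodes.tsv"),
    contigs = file.path(out_dir, "filtered_contig_annotations.csv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  Matrix::writeMM(cohort$matrix$counts, paths[["matrix"]])
  readr::write_tsv(tibble::tibble(id = rownames(cohort$matrix$counts),
                                  name = rownames(cohort$matrix$counts),
                                  type = "Gene Expression"),
                   paths[["features"]], col_names = FALSE, progress = FALSE)
  readr::write_tsv(tibble::tibble(barcode = colnames(cohort$matrix$counts)),
                   paths[["barcodes"]], col_names = FALSE, progress = FALSE)
  write_contigs(cohort$contigs, paths[["contigs"]])
  readr::write_tsv(cohort$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}

#' Read a 10x-style matrix directory
#'
#' Reads the MTX trio (`matrix.mtx`, `features.tsv` or `genes.tsv`,
#' `barcodes.tsv`) into a raw [gene_matrix()].
#'
#' @param dir Directory containing the trio.
#' @inheritParams gene_matrix
#' @return A raw-layer `gene_matrix`.
#' @export
read_10x <- function(dir, mito_prefix = "mt-",
                     y_genes = c("Ddx3y", "Eif2s3y", "Uty", "Kdm5d")) {
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  if (!file.exists(feat)) feat <- file.path(dir, "genes.tsv")
  bcs <- file.path(dir, "barcodes.tsv")
  for (p in c(mtx, feat, bcs)) {
    if (!file.exists(p)) stop("missing 10x file: ", p)
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- readr::read_tsv(feat, col_names = FALSE, progress = FALSE,
                              col_types = readr::cols(.default = "c"))
  barcodes <- readr::read_tsv(bcs, col_names = FALSE, progress = FALSE,
                              col_types = readr::cols(.default = "c"))
  dimnames(m) <- list(features[[1]], barcodes[[1]])
  gene_matrix(m, layer = "raw", mito_prefix = mito_prefix, y_genes = y_genes)
}

#' Read back a cohort written by [write_cohort()]
#'
#' @param dir Directory written by [write_cohort()].
#' @return List with `matrix`, `contigs` and (when `truth.tsv` is present)
#'   `truth`.
#' @export
read_cohort <- function(dir) {
  out <- list(
    matrix = read_10x(dir),
    contigs = read_contigs(file.path(dir, "filtered_contig_annotations.csv"))
  )
  tp <- file.path(dir, "truth.tsv")
  if (file.exists(tp)) {
    out$truth <- readr::read_tsv(
      tp, progress = FALSE,
      col_types = readr::cols(
        barcode = "c", true_type = "c", sex = "c", is_doublet = "l",
        true_cluster = "c", canonical_alpha = "l", oligoclonal_beta = "l",
        clone_id = "c", qc_violation = "c"
      ))
  }
  out
}
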