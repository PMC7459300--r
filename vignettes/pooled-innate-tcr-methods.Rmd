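---
title: "Methods: demultiplexing and repertoire analysis of pooled innate T cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demultiplexing and repertoire analysis of pooled innate T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trexr)
```

## The analysis problem

Thymic innate T cells — iNKT, MAIT and γδ T cells — are rare, so a
practical droplet experiment pools all three into one run, sorting iNKT
cells from male mice and MAIT cells from female mice. Each droplet barcode
must then be assigned back to its population before any per-type analysis.
Two signals make this possible without exogenous hashing: the
semi-invariant TCRα rearrangements that define the two αβ lineages
(Vα14-Jα18 for iNKT, Vα19-Jα33 for MAIT) and the binary presence of
Y-chromosome transcripts that encodes donor sex. This vignette documents
the package's model of that procedure, its tunable parameters, the
synthetic-data generator that stands in for real cohorts in the test
suite, and the numerical conventions used throughout.

## Cell QC and normalization

`qc_filter()` removes cells with fewer than `min_umi` (default 1000) total
UMIs or more than `max_mito` (default 0.10) mitochondrial UMI fraction.
Both thresholds are the standard droplet QC conventions for mouse thymocyte
data and are exposed as arguments, since in practice they are chosen by
inspecting QC-metric outliers for the dataset at hand. A cell failing both
rules is reported once, under `low_umi`. Mitochondrial genes are flagged by
the `mt-` name prefix, Y genes by an explicit list (Ddx3y, Eif2s3y, Uty,
Kdm5d); both are configurable in `annotate_genes()`.

`size_factors()` returns per-cell library-size factors scaled to mean 1.
Pooled-deconvolution factors (scran-style) are deliberately not
re-implemented here; because `lognormalize()` accepts any positive factor
vector, externally computed factors can be injected without touching the
rest of the pipeline. The normalized value is `log2(raw/factor + 1)`, so
zeros stay zero and the sparse pattern is preserved.

## Demultiplexing model

`demultiplex()` applies three passes, each with full rule provenance in the
output (`pass_id`, `rule_trace`):

1. **TCR/sex rules** (`assign_by_tcr()`). "Not expressing Y-chromosomal
   genes" is operationalized as a raw Y-UMI total of at most `y_tolerance`
   (default 0): Y transcripts are near-binary between sexes in droplet
   data, so a zero cut loses almost nothing while a small tolerance is
   available for noisier chemistries. An optional `male_only_inkt` flag
   additionally requires Y expression for an iNKT call; it is off by
   default because the canonical α rearrangement alone is already
   essentially specific and the pooling scheme only guarantees, not
   requires, male iNKT donors.
2. **Doublet removal** (`flag_doublets()`). TRA+TRD co-occurrence and
   dual-canonical-α co-occurrence are biologically impossible in one cell
   and mark a doublet regardless of any earlier label.
3. **Cluster rescue and fallback** (`cluster_rescue()`,
   `tcr_fallback()`). The majority fraction is computed **among assigned
   cells only**: unassigned cells are the quantity being estimated, so
   including them in the denominator would make the threshold depend on
   TCR capture efficiency rather than on cluster purity. The comparison is
   strict (`> 0.80`), so a cluster at exactly the threshold is treated as
   mixed. Both choices are recorded in the assignment trace for audit.
   Clusters failing the majority rule feed the fallback pass, where TRAV1
   expression suffices for MAIT and TRG-plus-TRD V segments for γδ T —
   deliberately weaker rules, applied only where cluster identity cannot
   arbitrate. The removal of specific contaminating clusters (e.g.
   double-positive thymocytes) is generalized as the `drop_clusters`
   pipeline option rather than hard-coded.

Cluster labels are an *input*: graph clustering, HVG selection and
dimensionality reduction are established upstream steps, not part of this
package.

## Clonotypes and repertoire statistics

A clonotype is the set of a cell's productive, high-confidence chains keyed
by (chain, V, J, CDR3). Identity is at the CDR3 **nucleotide** level by
default — the 10x clonotype convention, and the stricter reading of "same
rearranged CDR3 sequences" — with an amino-acid mode as a switch
(`level = "aa"`). TRAV11D is merged into TRAV11 (a duplicated, functionally
equivalent V segment) and allele suffixes are stripped before comparison.
Cells carrying several productive chains of one locus keep all of them in
the key.

Percentages in repertoire summaries are **truncated** (floored) at the
reported precision by `percent_floor()`; this is how such summaries are
conventionally printed (17/1760 → 0.96 at two decimals, 359/1665 → 21 at
zero), and full-precision fractions are always stored alongside. "Repeated
more than three times" means clone size strictly greater than 3; bar-plot
displays that start at "3 or more" are a separate display parameter.

Shannon equitability uses natural logarithms normalized by ln S, so values
lie in [0, 1]; a single-clonotype repertoire is defined as 0. The
oligoclonal Vβ sets used by `classify_canonical()` default to the
Vβ8.1/8.2/8.3 (TRBV13-1/2/3), Vβ7 (TRBV29) and Vβ2 (TRBV1) segments for
iNKT and Vβ6 (TRBV19) plus the Vβ8 family for MAIT — the restricted Vβ
usage characteristic of these lineages — and must be overridden when a
study defines its own sets. Cells without a TRB have an undefined β flag
and are excluded from β denominators. The classification supports the
exclusion re-analysis pattern (drop cells non-canonical on both chains,
recompute) via `exclude_both = TRUE`.

`composition_logo()` restricts to the modal CDR3 length; ties are broken
toward the shorter length (a deterministic choice, logged via a message)
since shorter junctions carry fewer inserted residues. Hydropathy classes
follow the WebLogo scheme: RKDENQ hydrophilic, SGHTAP neutral, CVLIMFWY
hydrophobic.

## Signature scores

`signature_score()` standardizes each signature gene across cells using the
**population** standard deviation (divide by n, not n−1); the difference is
immaterial at hundreds of cells but must be fixed for bit-reproducibility.
Zero-variance genes carry no information and contribute 0 (logged). The
standardization population is whatever matrix is passed in — per-type
matrices in per-type analyses — since the reference population is an
analysis choice, not a property of the score. Start-cell selection takes
the within-cluster argmax with lexicographic tie-breaking, so a rerun on
permuted input returns the same barcode.

## The DEG-overlap resampling test

The null model draws R independent pairs of uniform without-replacement
gene sets of the observed sizes from the testable universe. The universe is
the **intersection** of genes tested in both differential-expression
analyses: overlap probability must condition on a gene being observable in
both comparisons, not on the genome. The empirical p-value uses a
pseudo-count, `(1 + #{null ≥ k})/(R + 1)`, so it can never be zero, and the
alternative is one-sided ("greater") throughout, matching the question of
whether analogous subsets share more DEGs than chance. The exact
hypergeometric tail is reported next to the empirical p as a built-in
cross-check; for the direction-consistent statistic (|up∩up| + |down∩down|)
the analytic reference is the convolution of the two independent
hypergeometric overlap distributions, which is exactly the simulated null's
distribution. Both the direction-blind and direction-aware variants are
implemented and reported, since either null construction is defensible.
`category_correlation()` uses Spearman rank correlation by default
(fold-change distributions are heavy-tailed; Pearson is available by flag)
and permutes category labels to test whether in-category correlation
exceeds out-of-category correlation.

## The synthetic-data generator

`generate_cohort()` emulates the pooled design so that every downstream
stage can be tested against known truth:

- **Counts**: negative-binomial per gene with dispersion 0.3 — the
  standard droplet overdispersion model — with per-cell depths log-normal
  around `umi_depth_mean` (default 5000) and cluster-specific marker-gene
  mean shifts. Y genes are structurally zero in female cells and average
  ~12 UMIs in male cells at mean depth, mirroring their near-binary
  behaviour.
- **QC violators**: a configurable share of singlet cells
  (`qc_fail_fraction`, default 4%) is planted as violations, half low-UMI
  and half high-mito, so the QC stage has true positives to find.
- **Clones**: sizes follow a discrete power law P(s) ∝ s^−shape truncated
  at 1000, because observed repeat spectra are heavy-tailed. The default
  exponent 3.0 puts roughly 60% of cells in singleton clones, the regime
  the iNKT/γδ narratives describe (59%/63% singleton cells); per-type
  exponents are not published, so one shared default is used and
  `calibrate_clonal_shape()` inverts the singleton-fraction relation for
  scenario design. Clone CDR3s are generated as amino-acid strings and
  reverse-translated with random synonymous codons, so clones sharing the
  invariant CDR3α still carry distinct nucleotide junctions — exactly the
  property that makes nucleotide-level clonotyping informative.
- **TCRs**: canonical α rearrangements (with occasional TRAV11D and
  `*01` allele spellings to exercise normalization), non-canonical α
  chains from a decoy pool that includes Vα10/Jα50 (the most frequent
  non-canonical iNKT receptor), oligoclonal and non-oligoclonal β chains,
  and γ chains with narrow V-specific CDR3γ length ranges against broad
  CDR3δ lengths. Default non-canonical rates (9% α, 8% β) sit at the
  reported ~9% non-canonical cell share.
- **Doublets**: `doublet_fraction` (default 5%) of droplets receive a
  second cell of a different type; the droplet carries the union of the
  contigs and the sum of the counts. A small `chain_dropout_rate` (5%)
  removes the identifying chain from some singlets so the cluster-rescue
  pass has genuine work to do, and `junk_contig_rate` adds non-productive
  or low-confidence contigs to exercise the usable-contig filter.

What the generator does **not** emulate: ambient RNA and empty droplets
(no emptyDrops stage is needed or included), batch effects, UMI collision,
transcriptional doublet nonadditivity, or germline-encoded V(D)J junction
biology beyond codon-level consistency. Passing tests therefore demonstrate
the correctness of the rules and statistics, not robustness to every
real-data artifact; on real cohorts the QC thresholds and oligoclonal Vβ
sets in particular should be revisited.

## Problem sizes and determinism

The test suite runs cohorts of 30–150 cells per type for unit checks and a
3×500-cell cohort with 5% doublets for the end-to-end demultiplexing check;
overlap-test calibration uses R = 10000 replicates on a grid of universe
sizes and a 1000-dataset null simulation at R = 500 (p-value resolution
0.002, ample at α = 0.05). These sizes were chosen as the smallest at which
the statistics stabilize. All generator and test randomness flows through
explicit seeds; `generate_cohort()` is byte-identical under a fixed seed,
and `run_pipeline()` reruns are byte-identical including the JSON summary.

## Known limitations

- Library-size factors ignore composition effects that pooled
  deconvolution corrects; for strongly heterogeneous real data, inject
  external factors into `lognormalize()`.
- The 80% majority rule's denominator (assigned cells) is a documented
  choice; with very low TCR capture the rescue pass becomes aggressive,
  and the threshold should be raised.
- Clonotype sharing percentages count shared-clonotype cells within the
  two compared regions but normalize against all cells in the table;
  alternative normalizations are easy to derive from the returned tibbles.
- The iterative re-clustering rounds of a full real-data workflow are
  represented by accepting updated cluster-label inputs, not by
  re-clustering internally.
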