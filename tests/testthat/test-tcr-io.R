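contig_csv <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  header <- paste(c("barcode", "is_cell", "high_confidence", "chain",
                    "v_gene", "d_gene", "j_gene", "c_gene", "full_length",
                    "productive", "cdr3", "cdr3_nt", "reads", "umis",
                    "raw_clonotype_id"), collapse = ",")
  path <- file.path(dir, "contigs.csv")
  writeLines(c(header, rows), path)
  path
}

test_that("read_contigs parses the 10x boolean dialect", {
  path <- contig_csv(c(
    'AAAC-1,True,True,TRA,TRAV11,None,TRAJ18,TRAC,True,True,CAF,TGTGCTTTT,50,5,clonotype1',
    'AAAC-1,True,true,TRB,TRBV29,TRBD1,TRBJ2-1,TRBC1,True,None,CASF,TGTGCTAGTTTT,30,3,clonotype1',
    'AAAG-1,True,False,TRA,TRAV1,None,TRAJ33,TRAC,True,false,CAF,TGTGCTTTT,10,1,None'
  ))
  x <- read_contigs(path)
  expect_equal(nrow(x), 3)
  expect_equal(x$productive, c(TRUE, FALSE, FALSE))
  expect_equal(x$high_confidence, c(TRUE, TRUE, FALSE))
  expect_equal(x$umis, c(5L, 3L, 1L))
})

test_that("read_contigs rejects malformed input", {
  path <- contig_csv('AAAC-1,True,True,IGH,IGHV1,None,IGHJ1,IGHM,True,True,CAF,TGTGCTTTT,5,1,None')
  expect_error(read_contigs(path), "row")
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines("barcode,chain,v_gene", bad)
  expect_error(read_contigs(bad), "cdr3")
})

test_that("an empty table with a header reads as zero contigs", {
  path <- contig_csv(character(0))
  expect_equal(nrow(read_contigs(path)), 0)
})

test_that("usable_contigs keeps exactly productive high-confidence rows", {
  set.seed(1)
  x <- tibble::tibble(
    barcode = sprintf("bc%02d-1", 1:10), chain = "TRA",
    v_gene = "TRAV11", d_gene = NA, j_gene = "TRAJ18", c_gene = NA,
    cdr3 = "CAF", cdr3_nt = "TGTGCTTTT",
    productive = sample(c(TRUE, FALSE), 10, replace = TRUE),
    high_confidence = sample(c(TRUE, FALSE), 10, replace = TRUE),
    umis = 1L, reads = 10L, raw_clonotype_id = NA
  )
  kept <- usable_contigs(x)
  # row-by-row oracle
  oracle <- x[vapply(seq_len(10), function(i) {
    x$productive[i] && x$high_confidence[i]
  }, logical(1)), ]
  expect_identical(kept, oracle)
})

test_that("cell_chains groups, deduplicates and keeps multi-chain loci", {
  ch <- cell_chains(tibble::tibble(
    barcode = c("b1", "b1", "b1", "b2", "b2"),
    chain = c("TRA", "TRB", "TRA", "TRA", "TRA"),
    v_gene = c("TRAV11", "TRBV29", "TRAV11", "TRAV1", "TRAV10"),
    j_gene = c("TRAJ18", "TRBJ2-1", "TRAJ18", "TRAJ33", "TRAJ50"),
    cdr3_nt = c("TGTGCTTTT", "TGTTCTTTT", "TGTGCTTTT", "TGTAAATTT",
                "TGTCCCTTT"),
    cdr3 = c("CAF", "CSF", "CAF", "CKF", "CPF")
  ))
  expect_equal(nrow(ch[ch$barcode == "b1", ]), 2)  # duplicate TRA collapsed
  expect_equal(nrow(ch[ch$barcode == "b2", ]), 2)  # two distinct TRA kept
})

test_that("clonotype keys merge TRAV11D, strip alleles and ignore order", {
  a <- chain_tbl(list("c", "TRA", "TRAV11D", "TRAJ18", "TGTGCTTTT"))
  b <- chain_tbl(list("c", "TRA", "TRAV11", "TRAJ18", "TGTGCTTTT"))
  expect_identical(clonotype_key(a), clonotype_key(b))

  allele <- chain_tbl(list("c", "TRA", "TRAV11*01", "TRAJ18", "TGTGCTTTT"))
  expect_identical(clonotype_key(allele), clonotype_key(b))

  two <- chain_tbl(list("c", "TRA", "TRAV11", "TRAJ18", "TGTGCTTTT"),
                   list("c", "TRB", "TRBV29", "TRBJ2-1", "TGTTCTTTT"))
  expect_identical(clonotype_key(two), clonotype_key(two[2:1, ]))

  other_nt <- chain_tbl(list("c", "TRA", "TRAV11", "TRAJ18", "TGCGCTTTT"))
  expect_false(clonotype_key(other_nt) == clonotype_key(b))
  # amino-acid mode collapses synonymous nucleotide variants
  expect_identical(clonotype_key(other_nt, level = "aa"),
                   clonotype_key(b, level = "aa"))
  expect_error(clonotype_key(b[0, ]), "empty")
})

test_that("keyed cells never exceed barcodes and keys are content-pure", {
  co <- small_cohort(seed = 17, n = 60)
  chains <- cell_chains(usable_contigs(co$contigs))
  keys <- clonotype_keys(chains)
  expect_lte(nrow(keys), length(unique(co$contigs$barcode)))
  # same content, different row order => same keys
  shuffled <- chains[sample(nrow(chains)), ]
  keys2 <- clonotype_keys(shuffled)
  expect_identical(dplyr::arrange(keys, barcode),
                   dplyr::arrange(keys2, barcode))
})
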