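# Contig operon scan: locus finding, windows, ORF extraction, annotation.

test_that("window extraction clamps at contig ends and round-trips coordinates", {
  contig <- strrep("ACGT", 12500) # 50 kb
  locus <- data.frame(start = 200L, end = 500L)
  win <- extract_window(contig, locus, flank = 10000L)
  expect_equal(win$window, c(0L, 10500L)) # truncated upstream
  expect_equal(win$offset, 0L)
  mid <- data.frame(start = 12000L, end = 12300L)
  win2 <- extract_window(substr(contig, 1, 30000), mid, flank = 10000L)
  expect_equal(diff(win2$window), 300L + 20000L)
  # round trip: window coordinate w -> contig -> back
  w <- 1234L
  contig_coord <- win2$offset + w
  expect_equal(contig_coord - win2$offset, w)
  expect_identical(substr(win2$sequence, w + 1, w + 10),
                   substr(substr(contig, 1, 30000), contig_coord + 1,
                          contig_coord + 10))
})

test_that("ORF extraction finds planted genes on both strands", {
  set.seed(71)
  pep <- paste0(c("M", sample(strsplit("ACDEFGHIKNQRSTWY", "")[[1]],
                              89, replace = TRUE)), collapse = "")
  gene <- paste0(reverse_translate(pep), "TAA")
  # a TAA-rich background prevents long spurious ORFs
  bg <- function(n) paste0(rep("TTAA", n / 4), collapse = "")
  fwd <- paste0(bg(600), gene, bg(600))
  orfs <- extract_orfs(fwd, min_length_aa = 30L)
  hit <- orfs[orfs$peptide == pep, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$length_aa, 90L)
  expect_equal(hit$start, 600L)
  expect_equal(hit$end, 600L + nchar(gene))
  # same gene on the reverse strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  orfs_rc <- extract_orfs(rc, min_length_aa = 30L)
  hit_rc <- orfs_rc[orfs_rc$peptide == pep, ]
  expect_equal(hit_rc$strand, "-")
  expect_identical(hit_rc$peptide, pep)
  # window with no ATG
  expect_equal(nrow(extract_orfs(paste0(rep("TTAA", 300), collapse = ""))), 0L)
})

test_that("reported ORF peptides equal the translation at their coordinates", {
  op <- make_synthetic_operon(seed = 8L)
  contig <- op$contig[[1]]
  orfs <- extract_orfs(list(sequence = contig, offset = 0L), min_length_aa = 30L)
  expect_gt(nrow(orfs), 0)
  for (i in seq_len(nrow(orfs))) {
    sub <- substr(contig, orfs$start[i] + 1, orfs$end[i])
    if (orfs$strand[i] == "-")
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    expect_identical(translate_six_frames(sub)[["+1"]],
                     paste0(orfs$peptide[i], "*"))
  }
})

test_that("loci are found at planted positions and co-member hits merge", {
  op <- make_synthetic_operon(seed = 9L)
  loci <- find_loci(op$contig, op$clusters, op$db)
  expect_equal(nrow(loci), 1L)
  tr <- op$truth$bacteriocin
  expect_lt(loci$start, tr["end"])
  expect_gt(loci$end, tr["start"])
  expect_true(all(loci$evalue < 1e-5))
  # two identical cluster variants hitting the same spot merge to one locus
  db2 <- stats::setNames(rep(op$db, 2), c(names(op$db), "bac001_v2 cluster=bac001"))
  cl2 <- data.frame(id = c("bac001_v1", "bac001_v2"), cluster = "bac001")
  loci2 <- find_loci(op$contig, cl2, db2)
  expect_equal(nrow(loci2), 1L)
})

test_that("annotation flags categories and distinguishes NA from minus", {
  op <- make_synthetic_operon(seed = 10L)
  loci <- find_loci(op$contig, op$clusters, op$db)
  win <- extract_window(op$contig[[1]], loci[1, ], flank = 10000L)
  orfs <- extract_orfs(win)
  ann <- annotate_orfs(orfs, op$reference_proteins)
  expect_equal(unname(ann$flags), c("+", "+", "+"))
  expect_true(all(ann$hits$evalue < 1e-5))
  # bacteriocin-only construction (no known immunity/secretion genes planted)
  solo <- make_synthetic_operon(seed = 11L, include = "bacteriocin")
  loci_s <- find_loci(solo$contig, solo$clusters, solo$db)
  win_s <- extract_window(solo$contig[[1]], loci_s[1, ], flank = 10000L)
  ann_s <- annotate_orfs(extract_orfs(win_s), solo$reference_proteins)
  expect_equal(unname(ann_s$flags["bacteriocin"]), "+")
  expect_equal(unname(ann_s$flags["immunity"]), "-")
  expect_equal(unname(ann_s$flags["secretion"]), "-")
  # categories without reference proteins are not evaluable (NA), not "-"
  refs_bac_only <- solo$reference_proteins[grepl("category=bacteriocin",
                                                 names(solo$reference_proteins))]
  ann_na <- annotate_orfs(extract_orfs(win_s), refs_bac_only)
  expect_true(is.na(ann_na$flags[["immunity"]]))
  expect_equal(unname(ann_na$flags[["bacteriocin"]]), "+")
  # untagged reference sets are a validation error
  bad <- stats::setNames("MKVLA", "ref_x")
  expect_error(annotate_orfs(extract_orfs(win_s), bad), "category")
})

test_that("the full scan reports one Table-style row per locus", {
  op <- make_synthetic_operon(seed = 12L)
  tab <- operon_scan(op$contig, op$clusters, op$db, op$reference_proteins)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$bacteriocin, "+")
  expect_equal(tab$immunity, "+")
  expect_equal(tab$secretion, "+")
  # a contig without any planted gene yields no rows
  set.seed(73)
  empty <- stats::setNames(random_dna_str(20000), "bare")
  expect_equal(nrow(operon_scan(empty, op$clusters, op$db,
                                op$reference_proteins)), 0L)
})
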