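# K-mer index, read classification and community profiles.

test_that("index ownership follows the sharing rule", {
  set.seed(51)
  g1 <- random_dna_str(2000)
  tax1 <- data.frame(genome_id = "gA", species = "sp1")
  idx1 <- build_index(stats::setNames(g1, "gA"), tax1, k = 21L)
  st <- bacmine:::.kmer_index_stats_cpp(idx1$ptr)
  expect_equal(st$n_genome_owned, st$n_kmers) # single genome owns everything

  # identical genomes in different species: every k-mer ambiguous
  tax2 <- data.frame(genome_id = c("gA", "gB"), species = c("sp1", "sp2"))
  idx2 <- build_index(stats::setNames(c(g1, g1), c("gA", "gB")), tax2, k = 21L)
  st2 <- bacmine:::.kmer_index_stats_cpp(idx2$ptr)
  expect_equal(st2$n_ambiguous, st2$n_kmers)

  # identical genomes in one species: species-owned
  tax3 <- data.frame(genome_id = c("gA", "gB"), species = c("sp1", "sp1"))
  idx3 <- build_index(stats::setNames(c(g1, g1), c("gA", "gB")), tax3, k = 21L)
  st3 <- bacmine:::.kmer_index_stats_cpp(idx3$ptr)
  expect_equal(st3$n_species_owned, st3$n_kmers)

  expect_error(build_index(stats::setNames(c(g1, g1), c("gA", "gA")), tax3),
               "duplicate")
  expect_error(build_index(stats::setNames(g1, "gA"), tax1, k = 20L), "odd")
})

test_that("strains keep unique k-mers in their marker regions", {
  cfg <- tiny_config()
  db <- make_bacteriocin_db(cfg)
  coll <- make_genome_collection(cfg, db)
  idx <- build_index(coll$genomes, coll$taxonomy)
  st <- bacmine:::.kmer_index_stats_cpp(idx$ptr)
  expect_gt(st$n_genome_owned, 0)
  # error-free reads from each genome's marker region classify to that genome
  mk <- coll$truth$markers
  for (r in seq_len(nrow(mk))) {
    g <- coll$genomes[[mk$genome_id[r]]]
    reads <- stats::setNames(
      vapply(seq(mk$start[r], mk$end[r] - 120, by = 60), function(p)
        substr(g, p + 1, p + 120), ""),
      paste0("m", seq_len(7)))
    cl <- classify_reads(reads, idx)
    expect_true(all(cl$genome == mk$genome_id[r]),
                label = paste("marker reads of", mk$genome_id[r]))
  }
})

test_that("classification handles unknown reads, short reads and ties", {
  set.seed(52)
  segA <- random_dna_str(400); segB <- random_dna_str(400)
  gA <- paste0(random_dna_str(500), segA, random_dna_str(500))
  gB <- paste0(random_dna_str(500), segB, random_dna_str(500))
  tax <- data.frame(genome_id = c("gA", "gB"), species = c("sp1", "sp2"))
  idx <- build_index(stats::setNames(c(gA, gB), c("gA", "gB")), tax, k = 21L)
  # read with no indexed k-mers
  cl <- classify_reads(stats::setNames(random_dna_str(100), "novel"), idx)
  expect_true(is.na(cl$genome))
  # read shorter than k
  cl <- classify_reads(stats::setNames("ACGTACGTAC", "short"), idx)
  expect_true(is.na(cl$genome))
  # balanced chimeric read: equal unique votes for two genomes -> unassigned
  half <- 100L
  chimera <- paste0(substr(segA, 1, half), substr(segB, 1, half))
  cl <- classify_reads(stats::setNames(chimera, "tie"), idx)
  expect_true(is.na(cl$genome))
})

test_that("assigned plus unassigned reads equals the total", {
  cfg <- tiny_config(error_rate = 0.01)
  db <- make_bacteriocin_db(cfg)
  coll <- make_genome_collection(cfg, db)
  sim <- simulate_metagenomes(cfg, coll)
  idx <- build_index(coll$genomes, coll$taxonomy)
  cl <- classify_reads(sim$samples[[1]], idx)
  expect_equal(nrow(cl), cfg$reads_per_sample)
  expect_equal(sum(!is.na(cl$genome)) + sum(is.na(cl$genome)),
               cfg$reads_per_sample)
})

test_that("index save/load round-trips classifications", {
  cfg <- tiny_config()
  db <- make_bacteriocin_db(cfg)
  coll <- make_genome_collection(cfg, db)
  idx <- build_index(coll$genomes, coll$taxonomy, k = 21L)
  path <- tempfile(fileext = ".idx")
  save_index(idx, path)
  idx2 <- load_index(path)
  g <- coll$genomes[[1]]
  reads <- stats::setNames(substring(g, seq(1, 3000, by = 300),
                                     seq(1, 3000, by = 300) + 119),
                           paste0("r", 1:10))
  expect_identical(classify_reads(reads, idx), classify_reads(reads, idx2))
  unlink(path)
})

test_that("CLR transform and Shannon follow their closed forms", {
  counts <- matrix(c(10, 10, 10, 10,
                     40, 30, 20, 10), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), paste0("sp", 1:4)))
  clr <- clr_transform(counts)
  expect_equal(unname(clr["s1", ]), rep(0, 4))
  expect_true(all(abs(rowSums(clr)) < 1e-10))
  cls <- list(
    s1 = data.frame(read_id = paste0("r", 1:4), genome = "g",
                    species = paste0("sp", 1:4)),
    s2 = data.frame(read_id = paste0("r", 1:4), genome = "g",
                    species = c("sp1", "sp1", "sp1", "sp2")))
  tax <- data.frame(genome_id = "g", species = paste0("sp", 1:4),
                    family = "famX")
  prof <- community_profile(cls, tax)
  expect_equal(unname(prof$shannon["s1"]), log(4))
  expect_equal(unname(prof$shannon["s2"]),
               -sum(c(0.75, 0.25) * log(c(0.75, 0.25))))
  expect_equal(unname(rowSums(prof$relative)), c(1, 1))
})

test_that("infant samples show lower Shannon diversity than adult-like", {
  cfg <- tiny_config(n_species = 8L, infant_alpha_diversity = 2,
                     n_samples_per_group = c(infant = 6L, child = 0L,
                                             adolescent = 0L, adult = 6L,
                                             elderly = 0L))
  db <- make_bacteriocin_db(cfg)
  coll <- make_genome_collection(cfg, db)
  sim <- simulate_metagenomes(cfg, coll)
  idx <- build_index(coll$genomes, coll$taxonomy)
  cls <- lapply(sim$samples, classify_reads, index = idx)
  prof <- community_profile(cls, coll$taxonomy)
  grp <- sim$metadata$group[match(names(prof$shannon), sim$metadata$sample_id)]
  expect_lt(mean(prof$shannon[grp == "infant"]),
            mean(prof$shannon[grp != "infant"]))
  # PCA coordinates exist for both components and all samples
  expect_equal(dim(prof$pca), c(12L, 2L))
})
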