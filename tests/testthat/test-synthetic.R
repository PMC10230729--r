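# Synthetic-data generator contracts: validation, determinism, conservation,
# traceability, and planted-effect realizability.

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(synthetic_config(variant_identity = 1.2), "probabilities")
  expect_error(synthetic_config(carriage_prob = -0.1), "probabilities")
  expect_error(synthetic_config(n_bacteriocins = 0), "counts")
  expect_error(synthetic_config(genome_length = 500, read_length = 150),
               "10 \\* read_length")
  expect_error(synthetic_config(protein_length = c(10, 50)), "30")
  expect_s3_class(synthetic_config(), "synthetic_config")
})

test_that("database generator produces labelled variant clusters", {
  cfg <- synthetic_config(seed = 2L, n_bacteriocins = 8L,
                          variants_per_bacteriocin = 3L, variant_identity = 0.97)
  db <- make_bacteriocin_db(cfg)
  expect_length(db$proteins, 24L)
  lens <- nchar(db$proteins)
  expect_true(all(lens >= 30 & lens <= 120))
  expect_true(all(db$truth$class %in% c("I", "II", "III")))
  expect_true(all(grepl("class=(I{1,3}) cluster=bac\\d+", names(db$proteins))))
  # variants differ from the base at the configured identity
  for (cl in unique(db$truth$cluster_id)) {
    seqs <- db$proteins[db$truth$cluster_id == cl]
    base <- strsplit(seqs[[1]], "")[[1]]
    for (v in seqs[-1]) {
      ident <- mean(strsplit(v, "")[[1]] == base)
      expect_equal(ident, 0.97, tolerance = 0.02)
    }
  }
})

test_that("degenerate variant settings behave as stated", {
  one <- make_bacteriocin_db(synthetic_config(variants_per_bacteriocin = 1L))
  expect_false(anyDuplicated(one$truth$cluster_id) > 0) # every record its own cluster
  same <- make_bacteriocin_db(synthetic_config(variants_per_bacteriocin = 3L,
                                               variant_identity = 1.0))
  for (cl in unique(same$truth$cluster_id)) {
    seqs <- unname(same$proteins[same$truth$cluster_id == cl])
    expect_equal(length(unique(seqs)), 1L)
  }
})

test_that("genome collection plants carriage at the configured rate", {
  cfg <- synthetic_config(seed = 3L, n_bacteriocins = 2L,
                          variants_per_bacteriocin = 1L,
                          n_species = 20L, strains_per_species = c(4L, 4L),
                          carriage_prob = 0.5, genome_length = 6000L)
  db <- make_bacteriocin_db(cfg)
  coll <- make_genome_collection(cfg, db)
  expect_equal(length(coll$genomes), 80L)
  carr <- coll$truth$carriage
  frac <- mean(names(coll$genomes) %in% carr$genome_id[carr$cluster_id == "bac001"])
  se <- sqrt(0.25 / 80)
  expect_lt(abs(frac - 0.5), 3 * se)
  # planted genes decode back to their source proteins
  for (r in sample(nrow(carr), 5)) {
    g <- coll$genomes[[carr$genome_id[r]]]
    gene <- substr(g, carr$start[r] + 1, carr$end[r])
    pep <- translate_six_frames(gene)[["+1"]]
    expect_identical(pep, paste0(db$proteins[[which(db$truth$protein_id ==
                                                      carr$protein_id[r])]], "*"))
  }
})

test_that("carriage zero and single strains behave as stated", {
  cfg0 <- synthetic_config(carriage_prob = 0)
  coll0 <- make_genome_collection(cfg0, NULL)
  expect_equal(nrow(coll0$truth$carriage), 0L)
  expect_error(make_genome_collection(synthetic_config(carriage_prob = 0.5), NULL),
               "non-empty")
  cfg1 <- synthetic_config(strains_per_species = c(1L, 1L), carriage_prob = 0)
  coll1 <- make_genome_collection(cfg1, NULL)
  expect_equal(nrow(coll1$taxonomy), cfg1$n_species)
  expect_equal(anyDuplicated(coll1$taxonomy$species), 0L)
})

test_that("strain genomes stay near-identical with unique marker regions", {
  cfg <- tiny_config()
  db <- make_bacteriocin_db(cfg)
  coll <- make_genome_collection(cfg, db)
  tax <- coll$taxonomy
  sp1 <- tax$genome_id[tax$species == "sp01"]
  a <- strsplit(coll$genomes[[sp1[1]]], "")[[1]]
  b <- strsplit(coll$genomes[[sp1[2]]], "")[[1]]
  mk <- coll$truth$markers
  # backbone identity >= 97.5%, measured outside marker regions and outside
  # the gene-insert half of the genome
  marked <- unlist(lapply(sp1, function(g) {
    m <- mk[mk$genome_id == g, ]
    seq(m$start + 1L, m$end)
  }))
  backbone <- setdiff(seq_len(length(a) %/% 2L), marked)
  expect_gte(mean(a[backbone] == b[backbone]), 0.975)
  expect_true(all(mk$end - mk$start == 500L))
  # markers are genome-unique
  m1 <- substr(coll$genomes[[sp1[1]]], mk$start[mk$genome_id == sp1[1]] + 1,
               mk$end[mk$genome_id == sp1[1]])
  expect_false(grepl(m1, coll$genomes[[sp1[2]]], fixed = TRUE))
})

test_that("simulation conserves read counts and is traceable", {
  cfg <- tiny_config()
  db <- make_bacteriocin_db(cfg)
  coll <- make_genome_collection(cfg, db)
  sim <- simulate_metagenomes(cfg, coll)
  expect_equal(unname(vapply(sim$samples, length, 0L)),
               rep(cfg$reads_per_sample, nrow(sim$metadata)))
  for (tr in sim$truth) expect_equal(sum(tr$species_weights), 1)
  # with error_rate = 0 every read equals the encoded genome substring
  reads <- sim$samples[[1]]
  info <- regmatches(names(reads),
                     regexec("g=(g\\d+)\\|pos=(\\d+)\\|strand=([+-])", names(reads)))
  for (i in sample(length(reads), 25)) {
    gid <- info[[i]][2]; pos <- as.integer(info[[i]][3]); strand <- info[[i]][4]
    sub <- substr(coll$genomes[[gid]], pos + 1, pos + cfg$read_length)
    if (strand == "-")
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    expect_identical(unname(reads[i]), sub)
  }
})

test_that("identical configurations give byte-identical outputs", {
  cfg <- tiny_config()
  db1 <- make_bacteriocin_db(cfg); db2 <- make_bacteriocin_db(cfg)
  expect_identical(db1, db2)
  coll <- make_genome_collection(cfg, db1)
  expect_identical(coll, make_genome_collection(cfg, db2))
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_metagenomes(cfg, coll, outdir = d1)
  simulate_metagenomes(cfg, coll, outdir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("infant carrier up-weighting realizes the planted enrichment factor", {
  # equal Dirichlet concentrations and small carriage isolate the multiplier;
  # the bacteriocin-read fraction is measured from ground truth intervals
  cfg <- synthetic_config(
    seed = 19L, n_bacteriocins = 3L, variants_per_bacteriocin = 1L,
    n_species = 20L, strains_per_species = c(2L, 2L), genome_length = 8000L,
    carriage_prob = 0.02, infant_enrichment_factor = 3,
    infant_alpha_diversity = 20, adult_alpha_diversity = 20,
    carrier_sample_prob = 1, error_rate = 0,
    n_samples_per_group = c(infant = 40L, child = 40L, adolescent = 0L,
                            adult = 0L, elderly = 0L),
    reads_per_sample = 2000L, read_length = 100L)
  db <- make_bacteriocin_db(cfg)
  coll <- make_genome_collection(cfg, db)
  carr <- coll$truth$carriage
  frac <- numeric(0); grp <- character(0)
  sim <- simulate_metagenomes(cfg, coll, callback = function(sid, reads, meta) {
    info <- regmatches(names(reads),
                       regexec("g=(g\\d+)\\|pos=(\\d+)", names(reads)))
    gid <- vapply(info, `[`, "", 2)
    pos <- as.integer(vapply(info, `[`, "", 3))
    hit <- rep(FALSE, length(reads))
    for (r in seq_len(nrow(carr))) {
      on_g <- gid == carr$genome_id[r]
      hit <- hit | (on_g & pos < carr$end[r] & (pos + cfg$read_length) > carr$start[r])
    }
    frac <<- c(frac, mean(hit)); grp <<- c(grp, meta$group)
  })
  fi <- frac[grp == "infant"]; fa <- frac[grp != "infant"]
  F <- cfg$infant_enrichment_factor
  se <- sqrt(stats::var(fi) / length(fi) + F^2 * stats::var(fa) / length(fa))
  expect_lt(abs(mean(fi) - F * mean(fa)), 3 * se)
  expect_gt(mean(fi), mean(fa)) # direction of the planted effect
})

test_that("operon fixture plants decodable three-gene neighborhoods", {
  op <- make_synthetic_operon(seed = 5L)
  expect_named(op$truth, c("bacteriocin", "immunity", "secretion"))
  for (cat in names(op$truth)) {
    gene <- substr(op$contig[[1]], op$truth[[cat]]["start"] + 1,
                   op$truth[[cat]]["end"])
    pep <- translate_six_frames(gene)[["+1"]]
    ref <- op$reference_proteins[grepl(paste0("category=", cat),
                                       names(op$reference_proteins))]
    expect_identical(pep, paste0(ref[[1]], "*"))
  }
})
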