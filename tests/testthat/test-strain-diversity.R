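# Rarefaction, diversity records and the analysis of covariance fit.

fake_classification <- function(n, species_counts, prefix = "r") {
  # species_counts: named vector species -> reads; remainder unassigned
  sp <- rep(NA_character_, n)
  gen <- rep(NA_character_, n)
  i <- 1L
  for (s in names(species_counts)) {
    k <- species_counts[[s]]
    sp[i:(i + k - 1L)] <- s
    gen[i:(i + k - 1L)] <- paste0(s, "_g", rep_len(1:3, k))
    i <- i + k
  }
  data.frame(read_id = paste0(prefix, seq_len(n)), genome = gen, species = sp,
             stringsAsFactors = FALSE)
}

test_that("rarefaction returns exactly the requested depth, deterministically", {
  cl <- fake_classification(500, c(spA = 100, spB = 50))
  r1 <- rarefy(cl, depth = 200, seed = 9L)
  r2 <- rarefy(cl, depth = 200, seed = 9L)
  expect_equal(nrow(r1), 200L)
  expect_identical(r1, r2)
  expect_false(identical(r1, rarefy(cl, depth = 200, seed = 10L)))
  # exactly at depth: unchanged multiset
  expect_setequal(rarefy(cl, depth = 500, seed = 1L)$read_id, cl$read_id)
  expect_warning(out <- rarefy(cl, depth = 501, seed = 1L), "below")
  expect_null(out)
})

test_that("rarefied species counts match the hypergeometric oracle", {
  N <- 2000L; c_sp <- 400L; d <- 1000L
  cl <- fake_classification(N, c(spA = c_sp))
  counts <- vapply(1:100, function(s)
    sum(rarefy(cl, depth = d, seed = s)$species == "spA", na.rm = TRUE), 0L)
  mu <- c_sp * d / N
  v <- d * (c_sp / N) * (1 - c_sp / N) * (N - d) / (N - 1) # hypergeometric
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(v / 100))
})

test_that("diversity records count genomes and scale abundance per million", {
  cls <- list(
    s1 = fake_classification(1000, c(spA = 30)),   # 3 genomes hit
    s2 = fake_classification(1000, c(spA = 2)),    # 2 genomes hit
    s3 = fake_classification(1000, c(spB = 10)))   # spA absent
  tax <- data.frame(genome_id = c(paste0("spA_g", 1:3), paste0("spB_g", 1:3)),
                    species = rep(c("spA", "spB"), each = 3))
  pres <- c(s1 = TRUE, s2 = FALSE, s3 = FALSE)
  rec <- diversity_records(cls, "spA", tax, pres)
  expect_equal(rec$y, c(3L, 2L, 0L))
  expect_equal(rec$x, c(30, 2, 0) / 1000 * 1e6)
  expect_equal(rec$I, c(1L, 0L, 0L))
  expect_true(all((rec$y == 0) == (rec$x == 0)))
  expect_error(diversity_records(cls, "spZ", tax, pres), "absent")
  expect_error(diversity_records(cls, "spA", tax, pres[1:2]), "missing")
})

test_that("noise-free records are interpolated exactly", {
  rec <- data.frame(y = NA, x = c(0, 100, 200, 300, 150, 250),
                    I = c(0, 0, 0, 1, 1, 1))
  rec$y <- 1 + 2 * rec$I + 0.01 * rec$x
  fit <- fit_covariance_model(rec)
  expect_equal(fit$b0, 1)
  expect_equal(fit$a0, 2)
  expect_equal(fit$b1, 0.01)
  expect_equal(fit$lines$positive[["intercept"]] -
                 fit$lines$negative[["intercept"]], fit$a0)
})

test_that("degenerate designs raise explicit errors", {
  rec <- simulate_diversity_records(20, seed = 2L)
  expect_error(fit_covariance_model(rec[1:2, ]), "at least 3")
  rec0 <- rec; rec0$I <- 0
  expect_error(fit_covariance_model(rec0), "indicator")
  recx <- rec; recx$x <- 5
  expect_error(fit_covariance_model(recx), "constant")
  recc <- rec[1:6, ]; recc$I <- c(0, 0, 0, 1, 1, 1); recc$x <- recc$I * 3
  expect_error(fit_covariance_model(recc), "collinear|constant|rank")
})

test_that("coefficients match the closed-form normal equations", {
  set.seed(61)
  for (i in 1:10) {
    rec <- simulate_diversity_records(50, b0 = 2, a0 = 1.5, b1 = 0.002,
                                      sigma = 0.8, seed = 100 + i)
    fit <- fit_covariance_model(rec)
    X <- cbind(1, rec$I, rec$x)
    beta <- solve(t(X) %*% X, t(X) %*% rec$y)
    expect_equal(c(fit$b0, fit$a0, fit$b1), as.numeric(beta), tolerance = 1e-8)
    # residual orthogonality
    e <- rec$y - X %*% beta
    expect_lt(max(abs(c(sum(e), sum(e * rec$x), sum(e * rec$I)))), 1e-8)
  }
})

test_that("a0 recovery is unbiased with nominal interval coverage", {
  reps <- 200
  for (a0 in c(0, 1, 2)) {
    for (n in c(30, 100)) {
      est <- numeric(reps); cover <- logical(reps)
      for (r in seq_len(reps)) {
        rec <- simulate_diversity_records(n, b0 = 1, a0 = a0, b1 = 0.001,
                                          sigma = 1, seed = 7000 + r)
        fit <- fit_covariance_model(rec)
        est[r] <- fit$a0
        ci <- fit$a0 + c(-1, 1) * stats::qt(0.975, n - 3) * fit$se[["a0"]]
        cover[r] <- ci[1] <= a0 && a0 <= ci[2]
      }
      expect_lt(abs(mean(est) - a0), 0.2)
      expect_gte(mean(cover), 0.90)
      expect_lte(mean(cover), 0.99)
    }
  }
})

test_that("null worlds give approximately uniform p-values for a0", {
  reps <- 300
  p <- vapply(seq_len(reps), function(r)
    fit_covariance_model(simulate_diversity_records(
      40, a0 = 0, sigma = 1, seed = 9000 + r))$p_a0, 0)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("planted strain-diversity effects are recovered from reads", {
  # generous world: many strains per species (so the planted +2 is not
  # truncated) and sparse carriage (so negative samples can swap carrier
  # strains for non-carriers without shrinking)
  cfg <- synthetic_config(
    seed = 23L, n_bacteriocins = 1L, variants_per_bacteriocin = 1L,
    n_species = 3L, strains_per_species = c(6L, 8L), genome_length = 16000L,
    carriage_prob = 0.15, diversity_effect = 2, strain_presence_prob = 0.5,
    n_samples_per_group = c(infant = 30L, child = 0L, adolescent = 0L,
                            adult = 0L, elderly = 0L),
    reads_per_sample = 8000L, read_length = 150L, error_rate = 0,
    infant_enrichment_factor = 1)
  db <- make_bacteriocin_db(cfg)
  coll <- make_genome_collection(cfg, db)
  sim <- simulate_metagenomes(cfg, coll)
  carr <- coll$truth$carriage
  carrier_sp <- unique(coll$taxonomy$species[
    coll$taxonomy$genome_id %in% carr$genome_id])
  expect_gt(length(carrier_sp), 0)
  idx <- build_index(coll$genomes, coll$taxonomy)
  cls <- lapply(sim$samples, classify_reads, index = idx)
  pres <- vapply(sim$truth, function(t) t$positive, TRUE)
  rec <- diversity_records(cls, carrier_sp[1], coll$taxonomy, pres)
  fit <- fit_covariance_model(rec)
  expect_lt(abs(fit$a0 - cfg$diversity_effect), 3 * fit$se[["a0"]])
  expect_gt(fit$a0, 0) # positive line above negative line
})
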