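# Independent oracles and small fixtures shared across test files.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Independent full-DP Smith-Waterman (Gotoh affine) score oracle, written
# directly from the recurrences; quadratic, score only. A gap of length L
# costs gap_open + L * gap_extend.
sw_oracle <- function(query, subject, mat = blosum62, gap_open = 11,
                      gap_extend = 1) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  q[!q %in% rownames(mat)] <- "X"
  s[!s %in% rownames(mat)] <- "X"
  n <- length(q); m <- length(s)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  stop_pen <- -1e6
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (q[i - 1] == "*" || s[j - 1] == "*") stop_pen else
        mat[q[i - 1], s[j - 1]]
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_peptide <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small synthetic world reused by search / screen / pipeline tests;
# arguments override the fast defaults.
tiny_config <- function(...) {
  args <- list(
    seed = 11L, n_bacteriocins = 4L, variants_per_bacteriocin = 1L,
    n_species = 4L, strains_per_species = c(2L, 2L), genome_length = 4000L,
    carriage_prob = 0.4,
    n_samples_per_group = c(infant = 4L, child = 1L, adolescent = 1L,
                            adult = 3L, elderly = 1L),
    reads_per_sample = 1000L, read_length = 120L, error_rate = 0)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}
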