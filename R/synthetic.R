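# Synthetic-data generator: bacteriocin protein databases, strain-structured
# genome collections with taxonomy, and age-labeled metagenomes with planted
# enrichment and strain-diversity effects, all with full ground truth.

AGE_GROUP_RANGES <- list(
  infant = c(0L, 1L), child = c(2L, 9L), adolescent = c(10L, 19L),
  adult = c(20L, 59L), elderly = c(60L, 107L))

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Most frequent codon per amino acid (fixed E. coli-style usage table);
# deterministic reverse translation guarantees a perfect six-frame hit.
PREFERRED_CODON <- c(
  A = "GCG", R = "CGC", N = "AAC", D = "GAT", C = "TGC", Q = "CAG", E = "GAA",
  G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA", M = "ATG", F = "TTT",
  P = "CCG", S = "AGC", T = "ACC", W = "TGG", Y = "TAT", V = "GTG")

#' Reverse-translate a protein with the fixed preferred-codon table
#'
#' @param protein Amino-acid string (standard 20-letter alphabet).
#' @return Nucleotide coding sequence (no stop codon appended).
#' @export
reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  codons <- PREFERRED_CODON[aa]
  if (anyNA(codons)) stop("protein contains residues outside the standard alphabet")
  paste0(codons, collapse = "")
}

#' Configuration for the synthetic study world
#'
#' The defaults define the study conditions every synthetic run emulates:
#' age-structured samples in the five age groups, infant samples with lower
#' alpha diversity (smaller Dirichlet concentration) and a multiplicative
#' up-weighting of bacteriocin-carrier genomes, strain-structured species
#' (several near-identical genomes per species, each with a genome-unique
#' marker region), bacteriocin genes planted in a subset of genomes, and a
#' planted increase of `diversity_effect` strains in bacteriocin-positive
#' samples.
#'
#' @param seed Integer seed; identical configurations produce byte-identical
#'   outputs.
#' @param n_bacteriocins Number of distinct bacteriocins (clusters).
#' @param variants_per_bacteriocin Database variants per bacteriocin.
#' @param variant_identity Fraction of identical residues between a variant
#'   and its base sequence; values >= 0.95 generate within-cluster variants.
#' @param protein_length Length range (residues) for base proteins, within
#'   30-120.
#' @param n_species Number of species in the genome collection.
#' @param strains_per_species Integer range `c(min, max)` of genomes per
#'   species.
#' @param genome_length Genome length in bases (>= 10 * `read_length`).
#' @param carriage_prob Probability that a genome carries a given bacteriocin
#'   gene.
#' @param n_samples_per_group Named integer vector of sample counts for the
#'   groups infant, child, adolescent, adult, elderly.
#' @param reads_per_sample Reads simulated per sample.
#' @param read_length Read length in bases.
#' @param infant_enrichment_factor Multiplier (>= 1) on bacteriocin-carrier
#'   genome weights in infant samples.
#' @param diversity_effect Expected extra strains present in
#'   bacteriocin-positive samples for carrier species (the planted ANCOVA
#'   level shift).
#' @param infant_alpha_diversity Effective number of species for infant
#'   samples (Dirichlet concentration knob; lower than
#'   `adult_alpha_diversity`).
#' @param adult_alpha_diversity Effective number of species for adult-like
#'   samples; defaults to `n_species`.
#' @param error_rate Per-base substitution probability of simulated reads.
#' @param carrier_sample_prob Probability that a sample harbors the carrier
#'   strains (is bacteriocin-positive).
#' @param strain_presence_prob Baseline probability that a strain of a species
#'   is present in a sample.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_bacteriocins = 12L,
                             variants_per_bacteriocin = 2L,
                             variant_identity = 0.97,
                             protein_length = c(40L, 80L),
                             n_species = 12L,
                             strains_per_species = c(2L, 4L),
                             genome_length = 10000L,
                             carriage_prob = 0.05,
                             n_samples_per_group = c(infant = 10L, child = 3L,
                                                     adolescent = 3L, adult = 10L,
                                                     elderly = 4L),
                             reads_per_sample = 5000L,
                             read_length = 150L,
                             infant_enrichment_factor = 3,
                             diversity_effect = 1,
                             infant_alpha_diversity = 4,
                             adult_alpha_diversity = NULL,
                             error_rate = 0.005,
                             carrier_sample_prob = 0.5,
                             strain_presence_prob = 0.6) {
  if (is.null(adult_alpha_diversity)) adult_alpha_diversity <- n_species
  cfg <- list(seed = as.integer(seed), n_bacteriocins = as.integer(n_bacteriocins),
              variants_per_bacteriocin = as.integer(variants_per_bacteriocin),
              variant_identity = variant_identity,
              protein_length = as.integer(protein_length),
              n_species = as.integer(n_species),
              strains_per_species = as.integer(strains_per_species),
              genome_length = as.integer(genome_length),
              carriage_prob = carriage_prob,
              n_samples_per_group = n_samples_per_group,
              reads_per_sample = as.integer(reads_per_sample),
              read_length = as.integer(read_length),
              infant_enrichment_factor = infant_enrichment_factor,
              diversity_effect = diversity_effect,
              infant_alpha_diversity = infant_alpha_diversity,
              adult_alpha_diversity = adult_alpha_diversity,
              error_rate = error_rate,
              carrier_sample_prob = carrier_sample_prob,
              strain_presence_prob = strain_presence_prob)
  counts <- c(cfg$n_bacteriocins, cfg$variants_per_bacteriocin, cfg$n_species,
              cfg$strains_per_species, cfg$genome_length, cfg$reads_per_sample,
              cfg$read_length)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  probs <- c(cfg$variant_identity, cfg$carriage_prob, cfg$error_rate,
             cfg$carrier_sample_prob, cfg$strain_presence_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$infant_enrichment_factor < 1) stop("infant_enrichment_factor must be >= 1")
  if (cfg$genome_length < 10L * cfg$read_length)
    stop("genome_length must be at least 10 * read_length")
  if (any(cfg$protein_length < 30L) || any(cfg$protein_length > 120L))
    stop("protein_length must lie within [30, 120] residues")
  if (!all(names(AGE_GROUP_RANGES) %in% names(cfg$n_samples_per_group)))
    stop("n_samples_per_group must name all five age groups")
  structure(cfg, class = "synthetic_config")
}

#' @noRd
random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# sample one integer from [lo, hi]; avoids sample()'s scalar expansion
#' @noRd
sample_range <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1L)

# Substitute residues conservatively (non-negative BLOSUM62 pairs, falling
# back to the least destructive alternative). Within-cluster variants must
# stay above the 0.95 normalized bit-score similarity their identity implies,
# which arbitrary substitutions on short peptides would not guarantee.
#' @noRd
mutate_protein <- function(s, positions, conservative) {
  mat <- scoring_params()$substitution_matrix
  ch <- strsplit(s, "")[[1]]
  for (p in positions) {
    alt <- setdiff(AA20, ch[p])
    if (conservative) {
      scores <- mat[ch[p], alt]
      ok <- alt[scores >= 0]
      if (length(ok) == 0L) ok <- alt[scores == max(scores)]
      alt <- ok
    }
    ch[p] <- if (length(alt) == 1L) alt else sample(alt, 1L)
  }
  paste0(ch, collapse = "")
}

#' @noRd
mutate_string <- function(s, positions, alphabet) {
  ch <- strsplit(s, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(alphabet, ch[p]), 1L)
  paste0(ch, collapse = "")
}

#' Generate a synthetic bacteriocin protein database
#'
#' Produces `n_bacteriocins * variants_per_bacteriocin` proteins of 30-120
#' residues. Each record carries a class label in I/II/III and a cluster id in
#' its header (`class=` and `cluster=` tokens). The first variant of each
#' cluster is the base sequence; further variants differ from it by point
#' substitutions at the configured identity.
#'
#' @param config A [synthetic_config()].
#' @return List with `proteins` (named character vector) and `truth`
#'   (data frame: protein_id, cluster_id, class, length).
#' @export
make_bacteriocin_db <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 101L, {
    ids <- sprintf("bac%03d", seq_len(config$n_bacteriocins))
    classes <- sample(c("I", "II", "III"), config$n_bacteriocins, replace = TRUE)
    proteins <- character(0)
    truth <- list()
    for (i in seq_len(config$n_bacteriocins)) {
      len <- sample_range(config$protein_length[1], config$protein_length[2])
      base <- paste0(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = "")
      for (v in seq_len(config$variants_per_bacteriocin)) {
        seqv <- base
        if (v > 1L) {
          n_sub <- round((1 - config$variant_identity) * len)
          if (n_sub > 0L) {
            pos <- sample(2:len, n_sub) # keep the initial M intact
            seqv <- mutate_protein(base, pos,
                                   conservative = config$variant_identity >= 0.95)
          }
        }
        pid <- sprintf("%s_v%d", ids[i], v)
        header <- sprintf("%s class=%s cluster=%s", pid, classes[i], ids[i])
        proteins[header] <- seqv
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = pid, cluster_id = ids[i], class = classes[i],
          length = len, stringsAsFactors = FALSE)
      }
    }
    list(proteins = proteins, truth = do.call(rbind, truth))
  })
}

#' Generate a strain-structured genome collection with taxonomy
#'
#' Each species gets a base genome and 1..k strain genomes derived from it by
#' point mutations (pairwise identity >= 97.5%). Every genome receives a 500 bp
#' genome-unique random marker region so the k-mer classifier has unique
#' anchors. Each genome carries each bacteriocin gene independently with
#' probability `carriage_prob`; carried genes are in-frame reverse-translated
#' copies of the cluster's base protein followed by a stop codon, planted at
#' fixed per-cluster slots in the back half of the genome.
#'
#' @param config A [synthetic_config()].
#' @param db Output of [make_bacteriocin_db()] (or `NULL` when
#'   `carriage_prob = 0`).
#' @return List with `genomes` (named character vector), `taxonomy`
#'   (data frame: genome_id, species, genus, family, class), and `truth`
#'   (list: `carriage` data frame with insert coordinates, `markers` data
#'   frame, `strain_mutation_rate`).
#' @export
make_genome_collection <- function(config, db = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$carriage_prob > 0 && (is.null(db) || length(db$proteins) == 0L))
    stop("carriage_prob > 0 requires a non-empty bacteriocin database")
  L <- config$genome_length
  marker_len <- 500L
  gene_gap <- 30L
  insert_base <- L %/% 2L
  cluster_ids <- if (!is.null(db)) unique(db$truth$cluster_id) else character(0)
  base_protein <- if (!is.null(db))
    stats::setNames(unname(db$proteins[match(paste0(cluster_ids, "_v1"),
                                             db$truth$protein_id)]), cluster_ids)
  withr::with_seed(config$seed + 202L, {
    genomes <- character(0)
    tax <- list(); carr <- list(); marks <- list()
    g_i <- 0L
    for (s in seq_len(config$n_species)) {
      sp <- sprintf("sp%02d", s)
      k <- sample_range(config$strains_per_species[1], config$strains_per_species[2])
      base <- random_dna(L)
      for (j in seq_len(k)) {
        g_i <- g_i + 1L
        gid <- sprintf("g%03d", g_i)
        n_mut <- round(0.005 * L) # pairwise strain identity ~99%, above the 97.5% floor
        gseq <- mutate_string(base, sample.int(L, n_mut), c("A", "C", "G", "T"))
        mstart <- 200L + (j - 1L) * (marker_len + 20L)
        if (mstart + marker_len > insert_base)
          stop("genome_length too small for ", k, " strain marker regions")
        marker <- random_dna(marker_len)
        substr(gseq, mstart + 1L, mstart + marker_len) <- marker
        marks[[length(marks) + 1L]] <- data.frame(
          genome_id = gid, start = mstart, end = mstart + marker_len,
          stringsAsFactors = FALSE)
        if (length(cluster_ids) > 0L) {
          carried <- which(stats::runif(length(cluster_ids)) < config$carriage_prob)
          pos <- insert_base
          for (ci in carried) {
            gene <- paste0(reverse_translate(base_protein[[ci]]), "TAA")
            if (pos + nchar(gene) > L)
              stop("genome_length too small to host ", length(carried),
                   " carried bacteriocin genes")
            substr(gseq, pos + 1L, pos + nchar(gene)) <- gene
            carr[[length(carr) + 1L]] <- data.frame(
              genome_id = gid, cluster_id = cluster_ids[ci],
              protein_id = paste0(cluster_ids[ci], "_v1"),
              start = pos, end = pos + nchar(gene), stringsAsFactors = FALSE)
            pos <- pos + nchar(gene) + gene_gap
          }
        }
        genomes[gid] <- gseq
        tax[[g_i]] <- data.frame(
          genome_id = gid, species = sp,
          genus = sprintf("genus%02d", (s - 1L) %/% 2L + 1L),
          family = sprintf("family%02d", (s - 1L) %/% 4L + 1L),
          class = sprintf("class%02d", (s - 1L) %/% 8L + 1L),
          stringsAsFactors = FALSE)
      }
    }
    empty_carr <- data.frame(genome_id = character(), cluster_id = character(),
                             protein_id = character(), start = integer(),
                             end = integer(), stringsAsFactors = FALSE)
    list(genomes = genomes,
         taxonomy = do.call(rbind, tax),
         truth = list(
           carriage = if (length(carr)) do.call(rbind, carr) else empty_carr,
           markers = do.call(rbind, marks),
           strain_mutation_rate = 0.005))
  })
}

#' @noRd
inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  big <- paste0(reads, collapse = "")
  nb <- nchar(big)
  ne <- stats::rbinom(1L, nb, error_rate)
  if (ne > 0L) {
    ch <- strsplit(big, "")[[1]]
    pos <- sample.int(nb, ne)
    idx <- match(ch[pos], c("A", "C", "G", "T"))
    ch[pos] <- c("A", "C", "G", "T")[(idx - 1L + sample(1:3, ne, replace = TRUE)) %% 4L + 1L]
    big <- paste0(ch, collapse = "")
  }
  lens <- nchar(reads)
  ends <- cumsum(lens)
  out <- substring(big, ends - lens + 1L, ends)
  names(out) <- names(reads)
  out
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Strain-presence logic for one species in one sample. Returns indices of
# present strains. The planted diversity effect is realized by construction:
# bacteriocin-positive samples carry one forced carrier strain plus
# `diversity_effect` extra strains over the baseline draw; negative samples
# have carrier strains swapped out at unchanged baseline size.
#' @noRd
draw_present_strains <- function(strain_ids, carrier_ids, positive, config) {
  k <- length(strain_ids)
  base <- which(stats::runif(k) < config$strain_presence_prob)
  if (length(base) == 0L) base <- sample.int(k, 1L)
  is_carrier <- strain_ids %in% carrier_ids
  if (!any(is_carrier)) return(strain_ids[base])
  if (positive) {
    if (!any(is_carrier[base])) {
      forced <- sample(which(is_carrier), 1L)
      noncar <- base[!is_carrier[base]]
      if (length(noncar) > 0L) base <- base[base != noncar[sample.int(length(noncar), 1L)]]
      base <- union(base, forced)
    }
    extra <- setdiff(seq_len(k), base)
    n_add <- min(round(config$diversity_effect), length(extra))
    if (n_add > 0L) base <- union(base, sample(extra, n_add))
  } else {
    carr_in <- base[is_carrier[base]]
    for (b in carr_in) {
      repl <- setdiff(which(!is_carrier), base)
      base <- base[base != b]
      if (length(repl) > 0L) base <- union(base, sample(repl, 1L))
    }
    if (length(base) == 0L) return(integer(0)) # all strains are carriers
  }
  strain_ids[sort(base)]
}

#' Simulate age-labeled metagenomes from a genome collection
#'
#' Each sample draws an age uniformly inside its group's range, species
#' weights from a Dirichlet distribution (lower concentration for infants),
#' and a latent bacteriocin-positive state. Positive samples include the
#' carrier strains plus `diversity_effect` extra strains for carrier species;
#' negative samples exclude carrier strains. In infant samples the weights of
#' bacteriocin-carrier genomes are multiplied by `infant_enrichment_factor`.
#' Reads are uniform substrings of the present genomes (either strand) with
#' substitution errors at `error_rate`; each read id encodes its source genome,
#' offset and strand.
#'
#' @param config A [synthetic_config()].
#' @param collection Output of [make_genome_collection()].
#' @param outdir Optional directory; when given, per-sample FASTQ files and a
#'   metadata table are written there.
#' @param callback Optional `function(sample_id, reads, meta_row)`; when given,
#'   reads are streamed to the callback and not retained in the return value
#'   (memory-bounded processing of large simulations).
#' @return List with `samples` (named list of read vectors; empty when
#'   `callback` is used), `metadata` (sample_id, age, group, superclass,
#'   bacteriocin_positive, file), and `truth` (per-sample species weights and
#'   present strains).
#' @export
simulate_metagenomes <- function(config, collection, outdir = NULL,
                                 callback = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(collection$genomes) == 0L) stop("empty genome set")
  if (config$reads_per_sample < 1000L) stop("reads_per_sample must be >= 1000")
  tax <- collection$taxonomy
  species <- unique(tax$species)
  S <- length(species)
  carriage <- collection$truth$carriage
  carrier_genomes <- unique(carriage$genome_id)
  L <- config$genome_length
  rl <- config$read_length
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  groups <- rep(names(AGE_GROUP_RANGES),
                times = config$n_samples_per_group[names(AGE_GROUP_RANGES)])
  n_samp <- length(groups)
  sample_ids <- sprintf("s%03d", seq_len(n_samp))

  samples <- list()
  meta <- list()
  truth <- list()
  withr::with_seed(config$seed + 303L, {
    for (i in seq_len(n_samp)) {
      grp <- groups[i]
      rng <- AGE_GROUP_RANGES[[grp]]
      age <- sample_range(rng[1], rng[2])
      infant <- grp == "infant"
      positive <- stats::runif(1) < config$carrier_sample_prob
      conc <- if (infant) config$infant_alpha_diversity else config$adult_alpha_diversity
      w <- stats::rgamma(S, shape = conc / S, rate = 1)
      w[w <= 0] <- 1e-12
      w <- w / sum(w)
      # present strains and per-genome weights; if a negative draw leaves no
      # species with any non-carrier strain (every genome a carrier), the
      # sample cannot be bacteriocin-negative and is redrawn as positive
      repeat {
        gw <- numeric(0)
        present_all <- character(0)
        for (s in seq_len(S)) {
          gids <- tax$genome_id[tax$species == species[s]]
          pres <- draw_present_strains(gids, carrier_genomes, positive, config)
          if (length(pres) == 0L) next
          wt <- rep(w[s] / length(pres), length(pres))
          names(wt) <- pres
          gw <- c(gw, wt)
          present_all <- c(present_all, pres)
        }
        if (length(gw) > 0L) break
        positive <- TRUE
      }
      if (infant && config$infant_enrichment_factor > 1) {
        boost <- names(gw) %in% carrier_genomes
        gw[boost] <- gw[boost] * config$infant_enrichment_factor
      }
      gw <- gw / sum(gw)
      counts <- as.vector(stats::rmultinom(1L, config$reads_per_sample, gw))
      reads <- character(0)
      for (gi in which(counts > 0L)) {
        gid <- names(gw)[gi]
        starts <- sample.int(L - rl + 1L, counts[gi], replace = TRUE)
        rr <- substring(collection$genomes[[gid]], starts, starts + rl - 1L)
        strands <- stats::runif(counts[gi]) < 0.5
        if (any(strands)) rr[strands] <- revcomp(rr[strands])
        names(rr) <- sprintf("%s_r%06d|g=%s|pos=%d|strand=%s",
                             sample_ids[i], seq_along(rr) + length(reads),
                             gid, starts - 1L, ifelse(strands, "-", "+"))
        reads <- c(reads, rr)
      }
      reads <- inject_errors(reads, config$error_rate)
      reads <- reads[sample.int(length(reads))] # shuffle source order
      fpath <- NA_character_
      if (!is.null(outdir)) {
        fpath <- paste0(sample_ids[i], ".fastq") # relative to outdir
        write_fastq(reads, file.path(outdir, fpath))
      }
      meta[[i]] <- data.frame(
        sample_id = sample_ids[i], age = age, group = grp,
        superclass = if (infant) "infant-like" else "adult-like",
        bacteriocin_positive = positive, file = fpath, stringsAsFactors = FALSE)
      truth[[sample_ids[i]]] <- list(species_weights = stats::setNames(w, species),
                                     present_strains = present_all,
                                     positive = positive)
      if (is.null(callback)) {
        samples[[sample_ids[i]]] <- reads
      } else {
        callback(sample_ids[i], reads, meta[[i]])
      }
    }
  })
  metadata <- do.call(rbind, meta)
  if (!is.null(outdir)) write_tsv(metadata, file.path(outdir, "metadata.tsv"))
  list(samples = samples, metadata = metadata, truth = truth)
}

#' Construct a synthetic contig carrying a full bacteriocin operon
#'
#' Plants a bacteriocin gene, an immunity gene and a secretion (ABC
#' transporter-like) gene as reverse-translated ORFs on a random contig,
#' together with a categorized reference protein set, for testing the operon
#' scan end to end.
#'
#' @param seed Integer seed.
#' @param contig_length Contig length in bases.
#' @param gene_lengths Named integer vector of protein lengths (residues) for
#'   bacteriocin, immunity, secretion.
#' @param spacing Intergenic spacing in bases.
#' @param include Character vector of the gene categories actually planted
#'   (the reference set always covers all three).
#' @return List: `contig` (named character), `reference_proteins` (named,
#'   with `category=` header tokens), `db` (the bacteriocin protein, with
#'   `cluster=` token), `clusters` (one-row assignment), `truth` (planted
#'   coordinates, 0-based half-open, including the stop codon).
#' @export
make_synthetic_operon <- function(seed = 1L, contig_length = 30000L,
                                  gene_lengths = c(bacteriocin = 60L,
                                                   immunity = 80L,
                                                   secretion = 110L),
                                  spacing = 200L,
                                  include = c("bacteriocin", "immunity",
                                              "secretion")) {
  stopifnot(contig_length >= 3L * (sum(gene_lengths + 1L) * 3L + spacing))
  withr::with_seed(seed + 404L, {
    contig <- random_dna(contig_length)
    cats <- names(gene_lengths)
    proteins <- stats::setNames(vapply(gene_lengths, function(len) {
      paste0(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = "")
    }, ""), cats)
    pos <- contig_length %/% 3L
    truth <- list()
    for (cat in cats) {
      if (cat %in% include) {
        gene <- paste0(reverse_translate(proteins[[cat]]), "TAA")
        substr(contig, pos + 1L, pos + nchar(gene)) <- gene
        truth[[cat]] <- c(start = pos, end = pos + nchar(gene))
      }
      pos <- pos + 3L * (gene_lengths[[cat]] + 1L) + spacing
    }
    refs <- stats::setNames(unname(proteins),
                            sprintf("ref_%s category=%s", cats, cats))
    db <- stats::setNames(proteins[["bacteriocin"]],
                          "bac001_v1 class=II cluster=bac001")
    clusters <- data.frame(id = "bac001_v1", cluster = "bac001",
                           representative = "bac001_v1",
                           stringsAsFactors = FALSE)
    list(contig = c(contig1 = contig), reference_proteins = refs, db = db,
         clusters = clusters, truth = truth)
  })
}
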