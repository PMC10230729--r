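# K-mer read-to-genome classification and community profiles: species
# abundance tables, Aitchison-transformed PCA, Shannon diversity, top-family
# summaries.

#' Build a canonical k-mer index over a genome collection
#'
#' Every k-mer of every genome is indexed with an owner: the genome if unique
#' to it, the species if shared only within one species, or an ambiguous
#' marker if shared across species. K-mers are canonicalized as the
#' lexicographic minimum of the k-mer and its reverse complement.
#'
#' @param genomes Named character vector of genome sequences (unique names).
#' @param taxonomy Taxonomy table mapping `genome_id` to `species`.
#' @param k Odd k-mer size in 15-31 (default 31).
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(genomes, taxonomy, k = 31L) {
  if (anyDuplicated(names(genomes))) stop("duplicate genome ids")
  sp <- taxonomy$species[match(names(genomes), taxonomy$genome_id)]
  if (anyNA(sp)) stop("taxonomy must cover every genome")
  sp_ids <- as.integer(factor(sp, levels = unique(sp)))
  ptr <- .kmer_index_build_cpp(unname(genomes), sp_ids, as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), genome_ids = names(genomes),
                 species = sp), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  st <- .kmer_index_stats_cpp(x$ptr)
  cat(sprintf(
    "kmer_index: k=%d, %d genomes, %.0f k-mers (%.0f genome-owned, %.0f species-shared, %.0f ambiguous)\n",
    st$k, st$n_genomes, st$n_kmers, st$n_genome_owned, st$n_species_owned,
    st$n_ambiguous))
  invisible(x)
}

#' Classify reads against a k-mer index
#'
#' Owner votes are tallied over each read's canonical k-mers; species-shared
#' and ambiguous k-mers carry no genome-level vote. A read is assigned to the
#' genome with a strict plurality of votes; ties, zero votes, or reads shorter
#' than k are unassigned.
#'
#' @param reads Named character vector of read sequences (or a FASTA/FASTQ
#'   path).
#' @param index A [build_index()] object.
#' @return Data frame: read_id, genome (NA when unassigned), species.
#' @export
classify_reads <- function(reads, index) {
  stopifnot(inherits(index, "kmer_index"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_reads(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  gi <- .kmer_classify_cpp(index$ptr, unname(reads))
  data.frame(read_id = names(reads),
             genome = index$genome_ids[gi],
             species = index$species[gi],
             stringsAsFactors = FALSE)
}

#' Save / load a k-mer index as a plain-text key-value file
#'
#' Format: a `#bacmine_kmer_index` magic header, `k`, genome ids with species,
#' then one sorted `k-mer<TAB>owner` line per indexed k-mer (positive owner =
#' genome number, negative = species number, `NA` = ambiguous).
#'
#' @param index A [build_index()] object.
#' @param path File path.
#' @return `path` invisibly; `load_index` returns a `kmer_index`.
#' @export
save_index <- function(index, path) {
  d <- .kmer_index_dump_cpp(index$ptr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("#bacmine_kmer_index v1", paste0("k=", d$k),
               paste0("genomes=", paste(index$genome_ids, collapse = ",")),
               paste0("species=", paste(index$species, collapse = ","))), con)
  writeLines(paste(d$kmer, ifelse(is.na(d$owner), "NA", d$owner), sep = "\t"), con)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#bacmine_kmer_index")) stop("not a bacmine k-mer index")
  k <- as.integer(sub("^k=", "", lines[2L]))
  gids <- strsplit(sub("^genomes=", "", lines[3L]), ",")[[1]]
  sp <- strsplit(sub("^species=", "", lines[4L]), ",")[[1]]
  body <- strsplit(lines[-(1:4)], "\t", fixed = TRUE)
  kmers <- vapply(body, `[`, "", 1L)
  owners <- suppressWarnings(as.integer(vapply(body, `[`, "", 2L)))
  sp_ids <- as.integer(factor(sp, levels = unique(sp)))
  ptr <- .kmer_index_restore_cpp(kmers, owners, k, sp_ids)
  structure(list(ptr = ptr, k = k, genome_ids = gids, species = sp),
            class = "kmer_index")
}

#' Centered log-ratio (Aitchison) transform of a count matrix
#'
#' Zero counts receive a pseudocount before closure; each row of the result
#' sums to zero.
#'
#' @param counts Samples x taxa count matrix.
#' @param pseudocount Added to zero cells (default 0.5).
#' @return Transformed matrix of the same shape.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  m <- as.matrix(counts)
  m[m == 0] <- pseudocount
  rel <- m / rowSums(m)
  lg <- log(rel)
  sweep(lg, 1L, rowMeans(lg))
}

#' Community profile from read classifications
#'
#' Aggregates per-sample genome assignments into species read counts and
#' relative abundances, computes the Shannon index per sample, the first two
#' principal components of the Aitchison-transformed profiles, and a
#' family-level summary of the 10 most abundant families averaged per group.
#'
#' @param classifications Named list (by sample) of [classify_reads()] tables.
#' @param taxonomy Taxonomy table (genome_id, species, family).
#' @param groups Optional named vector mapping sample ids to group labels for
#'   the family summary.
#' @param pseudocount Passed to [clr_transform()].
#' @return List: `counts` (samples x species), `relative` (rows sum to 1),
#'   `shannon`, `pca` (PC1/PC2 coordinates; samples with zero assigned reads
#'   are excluded with a warning), `family_summary`.
#' @export
community_profile <- function(classifications, taxonomy, groups = NULL,
                              pseudocount = 0.5) {
  species <- unique(taxonomy$species)
  counts <- t(vapply(classifications, function(cl) {
    tab <- table(factor(cl$species, levels = species))
    as.integer(tab)
  }, integer(length(species))))
  colnames(counts) <- species
  rownames(counts) <- names(classifications)
  assigned <- rowSums(counts)
  rel <- counts / pmax(assigned, 1L)
  shannon <- apply(rel, 1L, function(p) {
    p <- p[p > 0]
    if (length(p) == 0L) return(0)
    -sum(p * log(p))
  })
  ok <- assigned > 0L
  pca <- NULL
  if (sum(ok) >= 2L) {
    if (!all(ok))
      warning("excluding samples with zero assigned reads from PCA: ",
              paste(rownames(counts)[!ok], collapse = ", "))
    clr <- clr_transform(counts[ok, , drop = FALSE], pseudocount)
    pc <- stats::prcomp(clr, center = TRUE, scale. = FALSE)
    ncol_pc <- min(2L, ncol(pc$x))
    pca <- pc$x[, seq_len(ncol_pc), drop = FALSE]
  }
  fam <- taxonomy$family[match(colnames(counts), taxonomy$species)]
  fam_counts <- t(rowsum(t(rel), fam))
  family_summary <- NULL
  if (!is.null(groups)) {
    grp <- groups[rownames(fam_counts)]
    by_grp <- rowsum(fam_counts, grp) / as.vector(table(grp)[sort(unique(grp))])
    top <- names(sort(colMeans(fam_counts), decreasing = TRUE))
    top <- top[seq_len(min(10L, length(top)))]
    family_summary <- by_grp[, top, drop = FALSE]
  }
  list(counts = counts, relative = rel, shannon = shannon, pca = pca,
       family_summary = family_summary)
}
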