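# Translated search of reads / genomes / contigs against a bacteriocin
# protein database, plus the per-sample abundance statistic.

#' @noRd
db_ids <- function(db) sub("\\s.*$", "", names(db))

#' @noRd
db_classes <- function(db) {
  ifelse(grepl("class=III\\b", names(db)), "III",
  ifelse(grepl("class=II\\b", names(db)), "II",
  ifelse(grepl("class=I\\b", names(db)), "I", NA_character_)))
}

#' @noRd
run_translated_search <- function(queries, db, params, mode, min_ungapped) {
  stopifnot(length(db) > 0L)
  raw <- .search_translated_cpp(unname(queries), unname(db),
                                params$substitution_matrix,
                                params$gap_open, params$gap_extend,
                                identical(mode, "seed"), as.integer(min_ungapped), 1L)
  n_db <- sum(nchar(db))
  hits <- data.frame(
    query = raw$query, frame = raw$frame, subject = raw$subject,
    raw_score = raw$raw_score,
    qstart = raw$qstart, qend = raw$qend,
    sstart = raw$sstart, send = raw$send,
    stringsAsFactors = FALSE)
  hits$bit_score <- bit_score(hits$raw_score, params)
  m <- raw$query_mlen[hits$query]
  hits$evalue <- evalue(hits$bit_score, m, n_db)
  hits <- hits[hits$evalue <= params$evalue_threshold, , drop = FALSE]
  # nucleotide coordinates of the match on the original strand (0-based half-open)
  L <- nchar(queries)[hits$query]
  off <- abs(hits$frame) - 1L
  fwd <- hits$frame > 0L
  hits$nt_start <- ifelse(fwd, off + 3L * hits$qstart, L - (off + 3L * hits$qend))
  hits$nt_end <- ifelse(fwd, off + 3L * hits$qend, L - (off + 3L * hits$qstart))
  hits$query_id <- names(queries)[hits$query]
  hits$subject_id <- db_ids(db)[hits$subject]
  hits$subject_class <- db_classes(db)[hits$subject]
  rownames(hits) <- NULL
  hits
}

#' Search metagenome reads against a bacteriocin protein database
#'
#' Six-frame translated search of every read against the database; hits with
#' E-value above `params$evalue_threshold` are removed; the best hit per
#' (read, protein) pair is kept. The per-sample bacteriocin gene abundance is
#' the number of distinct reads with at least one surviving hit divided by the
#' total number of reads; per-class abundances restrict to hits on class
#' I/II/III proteins, and per-protein columns count distinct reads hitting
#' that protein.
#'
#' @param reads Named character vector of read sequences, or a path to a
#'   FASTA/FASTQ file.
#' @param db Named character vector of bacteriocin proteins (headers may carry
#'   a `class=I|II|III` token), or a path to a protein FASTA.
#' @param params A [scoring_params()] object.
#' @param mode `"seed"` (4-mer seeded with ungapped prefilter, then full
#'   Smith-Waterman on candidates) or `"full"` (exhaustive dynamic
#'   programming against every database protein).
#' @param min_ungapped Minimum ungapped extension score for a seed to trigger
#'   full alignment in `"seed"` mode.
#' @return List with `hits` (filtered hit table), `n_reads`, `unique_reads`
#'   (distinct matching reads), `unique_by_class` (named count per class),
#'   and `reads_per_bacteriocin` (distinct matching reads per database
#'   protein id).
#' @export
search_reads <- function(reads, db, params = scoring_params(),
                         mode = c("seed", "full"), min_ungapped = 40L) {
  mode <- match.arg(mode)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_reads(reads)
  if (is.character(db) && length(db) == 1L && file.exists(db))
    db <- read_fasta(db)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  hits <- run_translated_search(reads, db, params, mode, min_ungapped)
  ids <- db_ids(db)
  per_bac <- vapply(split(hits$query_id, factor(hits$subject_id, levels = ids)),
                    function(x) length(unique(x)), 0L)
  by_class <- vapply(c(I = "I", II = "II", III = "III"), function(cl) {
    length(unique(hits$query_id[!is.na(hits$subject_class) & hits$subject_class == cl]))
  }, 0L)
  list(hits = hits,
       n_reads = length(reads),
       unique_reads = length(unique(hits$query_id)),
       unique_by_class = by_class,
       reads_per_bacteriocin = per_bac)
}

#' Search long nucleotide sequences (genomes, contigs) against a protein database
#'
#' Same scoring contract as [search_reads()], applied to long sequences. Hits
#' report the nucleotide coordinates of the matching region on the queried
#' sequence (0-based half-open, on the original strand) for use by the genome
#' screen and the operon scan.
#'
#' @inheritParams search_reads
#' @param sequences Named character vector of nucleotide sequences, or a path
#'   to a FASTA file.
#' @return Hit table (data frame); zero rows when `db` is empty.
#' @export
search_sequences <- function(sequences, db, params = scoring_params(),
                             mode = c("seed", "full"), min_ungapped = 40L) {
  mode <- match.arg(mode)
  if (is.character(sequences) && length(sequences) == 1L && file.exists(sequences))
    sequences <- read_fasta(sequences)
  if (is.character(db) && length(db) == 1L && file.exists(db))
    db <- read_fasta(db)
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  if (length(db) == 0L) {
    return(data.frame(query = integer(), frame = integer(), subject = integer(),
                      raw_score = integer(), qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(), bit_score = numeric(),
                      evalue = numeric(), nt_start = integer(), nt_end = integer(),
                      query_id = character(), subject_id = character(),
                      subject_class = character(), stringsAsFactors = FALSE))
  }
  run_translated_search(sequences, db, params, mode, min_ungapped)
}

#' Assemble per-sample search results into an abundance matrix
#'
#' @param results Named list of [search_reads()] results, one per sample.
#' @return An object of class `abundance_matrix`: list with `fractions`
#'   (samples x bacteriocins matrix of unique-matching-read fractions),
#'   `total_reads`, `unique_reads`, `class_fractions` (samples x classes) and
#'   `abundance` (overall per-sample bacteriocin gene abundance).
#' @export
abundance_matrix <- function(results) {
  stopifnot(length(results) > 0L, !is.null(names(results)))
  bac_ids <- names(results[[1L]]$reads_per_bacteriocin)
  frac <- do.call(rbind, lapply(results, function(r) r$reads_per_bacteriocin / r$n_reads))
  dimnames(frac) <- list(names(results), bac_ids)
  cls <- do.call(rbind, lapply(results, function(r) r$unique_by_class / r$n_reads))
  dimnames(cls) <- list(names(results), c("I", "II", "III"))
  structure(list(
    fractions = frac,
    total_reads = vapply(results, function(r) r$n_reads, 0L),
    unique_reads = vapply(results, function(r) r$unique_reads, 0L),
    class_fractions = cls,
    abundance = vapply(results, function(r) r$unique_reads / r$n_reads, 0)
  ), class = "abundance_matrix")
}

#' Write a filtered hit table as a blast-outfmt-6-style TSV
#'
#' Columns follow the 12-column blast tabular field order (alignment-detail
#' columns that this engine does not compute are left `NA`) plus a `frame`
#' column.
#'
#' @param hits Hit table from [search_reads()] or [search_sequences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = NA_real_, length = hits$qend - hits$qstart,
    mismatch = NA_integer_, gapopen = NA_integer_,
    qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send,
    evalue = hits$evalue, bitscore = hits$bit_score,
    frame = hits$frame, stringsAsFactors = FALSE)
  write_tsv(out, path)
}
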