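# Operon scan: locate bacteriocin genes on contigs, extract +/-10 kb
# neighborhoods, call and translate ORFs, and annotate them against a
# categorized reference protein set into a presence report.

#' Locate bacteriocin loci on contigs
#'
#' Contigs are screened against the cluster member proteins with the
#' translated search; hits surviving the E-value filter are grouped per
#' (contig, cluster) and overlapping hits from cluster co-members are merged
#' into one locus (best E-value kept).
#'
#' @param contigs Named character vector of contig sequences.
#' @param clusters Cluster assignment (columns id, cluster) restricting and
#'   labelling the database proteins.
#' @param db Named character vector of bacteriocin proteins.
#' @param params A [scoring_params()] object.
#' @return Data frame: contig_id, cluster, strand, start, end (0-based
#'   half-open nucleotide interval), evalue.
#' @export
find_loci <- function(contigs, clusters, db, params = scoring_params()) {
  stopifnot(length(contigs) > 0L)
  member_db <- db[db_ids(db) %in% clusters$id]
  empty <- data.frame(contig_id = character(), cluster = character(),
                      strand = character(), start = integer(), end = integer(),
                      evalue = numeric(), stringsAsFactors = FALSE)
  if (length(member_db) == 0L) return(empty)
  hits <- search_sequences(contigs, member_db, params)
  if (nrow(hits) == 0L) return(empty)
  hits$cluster <- clusters$cluster[match(hits$subject_id, clusters$id)]
  out <- list()
  for (key in unique(paste(hits$query_id, hits$cluster))) {
    h <- hits[paste(hits$query_id, hits$cluster) == key, , drop = FALSE]
    h <- h[order(h$nt_start), , drop = FALSE]
    cur <- h[1L, ]
    flush <- function(cur) data.frame(
      contig_id = cur$query_id, cluster = cur$cluster,
      strand = ifelse(cur$frame > 0L, "+", "-"),
      start = cur$nt_start, end = cur$nt_end, evalue = cur$evalue,
      stringsAsFactors = FALSE)
    for (r in seq_len(nrow(h))[-1L]) {
      if (h$nt_start[r] < cur$nt_end) { # overlap: merge, keep best E
        cur$nt_end <- max(cur$nt_end, h$nt_end[r])
        if (h$evalue[r] < cur$evalue) {
          cur$evalue <- h$evalue[r]; cur$frame <- h$frame[r]
        }
      } else {
        out[[length(out) + 1L]] <- flush(cur)
        cur <- h[r, ]
      }
    }
    out[[length(out) + 1L]] <- flush(cur)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$contig_id, res$cluster, res$start), , drop = FALSE]
}

#' Extract the neighborhood window around a locus
#'
#' The window spans up to `flank` bases on each side of the locus, truncated
#' at the contig ends. The offset map converts window coordinates back to
#' contig coordinates (`contig = window + offset`).
#'
#' @param contig Contig sequence (character scalar).
#' @param locus One-row data frame from [find_loci()] (columns start, end).
#' @param flank Maximum flank size in bases (default 10000).
#' @return List: `sequence`, `offset` (0-based contig coordinate of window
#'   position 0), `window` (start, end on the contig, 0-based half-open).
#' @export
extract_window <- function(contig, locus, flank = 10000L) {
  len <- nchar(contig)
  stopifnot(locus$start >= 0L, locus$end <= len)
  ws <- max(0L, locus$start - as.integer(flank))
  we <- min(len, locus$end + as.integer(flank))
  list(sequence = substr(contig, ws + 1L, we), offset = ws, window = c(ws, we))
}

#' Extract open reading frames from a window
#'
#' ORFs run ATG-to-stop on both strands and must be at least `min_length_aa`
#' residues (stop excluded). Within one reading frame only the longest ORF per
#' stop is reported (the first ATG after the previous stop), which suppresses
#' nested same-frame ORFs. ORFs without a stop codon inside the window are not
#' reported. Alternative start codons are off by default.
#'
#' @param window Window list from [extract_window()] (or a plain sequence, in
#'   which case the offset is 0).
#' @param min_length_aa Minimum peptide length (default 30).
#' @param alternative_starts Also accept GTG/TTG starts when `TRUE`.
#' @return Data frame: start, end (0-based half-open contig coordinates of the
#'   coding sequence including the stop codon), strand, length_aa, peptide.
#' @export
extract_orfs <- function(window, min_length_aa = 30L, alternative_starts = FALSE) {
  if (is.character(window)) window <- list(sequence = window, offset = 0L)
  s <- window$sequence
  L <- nchar(s)
  stopifnot(L >= 3L)
  frames <- translate_six_frames(s)
  rc <- revcomp(s)
  start_codons <- if (alternative_starts) c("ATG", "GTG", "TTG") else "ATG"
  rows <- list()
  for (f in seq_along(frames)) {
    pep <- frames[[f]]
    if (nchar(pep) == 0L) next
    aa <- strsplit(pep, "")[[1]]
    fwd <- f <= 3L
    off <- (f - 1L) %% 3L
    strand_seq <- if (fwd) s else rc
    stops <- which(aa == "*")
    prev <- 0L
    for (st in stops) {
      if (st - 1L >= prev + 1L) {
        seg <- seq(prev + 1L, st - 1L)
        codons <- substring(strand_seq, off + 3L * (seg - 1L) + 1L,
                            off + 3L * (seg - 1L) + 3L)
        first_start <- seg[which(codons %in% start_codons)][1L]
        if (!is.na(first_start)) {
          plen <- st - first_start
          if (plen >= min_length_aa) {
            nt_from <- off + 3L * (first_start - 1L) # 0-based on frame strand
            nt_to <- off + 3L * st                   # includes stop codon
            if (fwd) { cs <- nt_from; ce <- nt_to }
            else { cs <- L - nt_to; ce <- L - nt_from }
            rows[[length(rows) + 1L]] <- data.frame(
              start = window$offset + cs, end = window$offset + ce,
              strand = if (fwd) "+" else "-", length_aa = plen,
              peptide = paste0(aa[first_start:(st - 1L)], collapse = ""),
              stringsAsFactors = FALSE)
          }
        }
      }
      prev <- st
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      length_aa = integer(), peptide = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res[order(res$start, res$strand), , drop = FALSE]
}

#' @noRd
ref_categories <- function(reference_proteins) {
  m <- regmatches(names(reference_proteins),
                  regexpr("category=(bacteriocin|immunity|secretion)",
                          names(reference_proteins)))
  if (length(m) < length(reference_proteins))
    stop("every reference protein header must carry a ",
         "category=bacteriocin|immunity|secretion token")
  sub("^category=", "", m)
}

#' Annotate ORFs against a categorized reference protein set
#'
#' Each ORF peptide is locally aligned against every reference protein; a
#' category is present (`+`) if any ORF hits a protein of that category with
#' an E-value below `evalue_threshold` (search space: summed ORF peptide
#' length x summed reference length). Categories with no reference proteins
#' supplied are reported `NA` (not evaluable), distinct from `-`.
#'
#' @param orfs Data frame from [extract_orfs()].
#' @param reference_proteins Named character vector; headers must carry a
#'   `category=bacteriocin|immunity|secretion` token.
#' @param params A [scoring_params()] object (its `evalue_threshold` is the
#'   presence cutoff).
#' @return List: `flags` (named character: "+", "-", or NA per category),
#'   `best_hits` (data frame with the best hit per category), `hits` (all
#'   passing hits).
#' @export
annotate_orfs <- function(orfs, reference_proteins, params = scoring_params()) {
  cats <- ref_categories(reference_proteins)
  all_cats <- c("bacteriocin", "immunity", "secretion")
  flags <- stats::setNames(rep(NA_character_, 3L), all_cats)
  flags[all_cats %in% cats] <- "-"
  hits <- list()
  if (nrow(orfs) > 0L && length(reference_proteins) > 0L) {
    m <- sum(nchar(orfs$peptide))
    n <- sum(nchar(reference_proteins))
    ref_ids <- sub("\\s.*$", "", names(reference_proteins))
    for (i in seq_len(nrow(orfs))) {
      for (j in seq_along(reference_proteins)) {
        sc <- align_protein(orfs$peptide[i], reference_proteins[[j]], params)$score
        bits <- bit_score(sc, params)
        ev <- evalue(bits, m, n)
        if (ev < params$evalue_threshold) {
          hits[[length(hits) + 1L]] <- data.frame(
            orf = i, orf_start = orfs$start[i], orf_strand = orfs$strand[i],
            reference = ref_ids[j], category = cats[j],
            bit_score = bits, evalue = ev, stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(orf = integer(), orf_start = integer(), orf_strand = character(),
               reference = character(), category = character(),
               bit_score = numeric(), evalue = numeric(), stringsAsFactors = FALSE)
  best <- list()
  for (cat in all_cats[!is.na(flags)]) {
    h <- hits[hits$category == cat, , drop = FALSE]
    if (nrow(h) > 0L) {
      flags[cat] <- "+"
      best[[cat]] <- h[which.min(h$evalue), , drop = FALSE]
    }
  }
  best <- if (length(best)) do.call(rbind, best) else NULL
  list(flags = flags, best_hits = best, hits = hits)
}

#' Scan contigs for bacteriocin operon neighborhoods
#'
#' End-to-end contig scan: locate bacteriocin loci, extract the +/-`flank`
#' neighborhood of each, call ORFs, and annotate them against the categorized
#' reference set; one report row per locus (Table-style `+`/`-`/NA flags per
#' category).
#'
#' @inheritParams find_loci
#' @inheritParams extract_orfs
#' @param reference_proteins See [annotate_orfs()].
#' @param flank Window flank in bases (default 10000).
#' @return Data frame: contig_id, cluster, locus start/end, strand, evalue,
#'   and bacteriocin/immunity/secretion flag columns.
#' @export
operon_scan <- function(contigs, clusters, db, reference_proteins,
                        params = scoring_params(), flank = 10000L,
                        min_length_aa = 30L) {
  loci <- find_loci(contigs, clusters, db, params)
  if (nrow(loci) == 0L)
    return(data.frame(contig_id = character(), cluster = character(),
                      start = integer(), end = integer(), strand = character(),
                      evalue = numeric(), bacteriocin = character(),
                      immunity = character(), secretion = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    loc <- loci[i, ]
    win <- extract_window(contigs[[loc$contig_id]], loc, flank)
    orfs <- extract_orfs(win, min_length_aa)
    ann <- annotate_orfs(orfs, reference_proteins, params)
    cbind(loc, data.frame(bacteriocin = ann$flags[["bacteriocin"]],
                          immunity = ann$flags[["immunity"]],
                          secretion = ann$flags[["secretion"]],
                          stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
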