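# Translated-search scoring core: six-frame translation, local protein
# alignment, bit scores and Karlin-Altschul E-values.

#' Scoring parameters for the translated protein search
#'
#' Defaults follow common blastx practice: BLOSUM62, gap open 11, gap extend 1,
#' and ungapped Karlin-Altschul parameters (lambda = 0.267 nats, K = 0.041)
#' applied to gapped scores as an approximation. The raw score S of a local
#' alignment converts to a bit score S' = (lambda * S - ln K) / ln 2, and the
#' E-value of a hit is E = m * n * 2^(-S') where m is the summed translated
#' query length and n the summed database length (no edge-effect correction).
#'
#' @param substitution_matrix Integer substitution matrix with residue
#'   dimnames; must contain a wildcard `X` row. Default BLOSUM62.
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend` score units.
#' @param lambda,K Karlin-Altschul scale (nats per score unit) and search-space
#'   constant.
#' @param evalue_threshold Hits with E-value above this are discarded.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(substitution_matrix = NULL, gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041,
                           evalue_threshold = 1e-5) {
  if (is.null(substitution_matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    substitution_matrix <- e$BLOSUM62
  }
  stopifnot(is.matrix(substitution_matrix), !is.null(rownames(substitution_matrix)))
  if (!("X" %in% rownames(substitution_matrix)))
    stop("substitution matrix must contain a wildcard 'X' row")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be non-negative costs")
  if (evalue_threshold <= 0) stop("evalue_threshold must be positive")
  structure(list(
    substitution_matrix = matrix(as.integer(substitution_matrix),
                                 nrow = nrow(substitution_matrix),
                                 dimnames = dimnames(substitution_matrix)),
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
    lambda = lambda, K = K, evalue_threshold = evalue_threshold
  ), class = "scoring_params")
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1..+3 translate the forward strand from offsets 0, 1, 2; frames
#' -1..-3 translate the reverse complement likewise. Trailing partial codons
#' are dropped, codons containing `N` (or any non-ACGT base) translate to `X`,
#' and stop codons are emitted as `*`. Sequences shorter than 3 nt yield empty
#' frames.
#'
#' @param sequence A single nucleotide sequence (character scalar).
#' @return Named character vector of 6 peptides (`+1`..`-3`).
#' @export
translate_six_frames <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  .translate_six_frames_cpp(sequence)[[1L]]
}

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman with affine gaps under the configured substitution matrix.
#' Residues outside the matrix alphabet are scored via the wildcard `X` row;
#' alignments never extend across a stop symbol `*`. Ties are broken
#' deterministically (lowest start coordinate, then shortest alignment).
#'
#' @param query,subject Non-empty peptide strings.
#' @param params A [scoring_params()] object.
#' @return List with `score` (raw integer score, >= 0) and 0-based half-open
#'   intervals `query_range`, `subject_range`.
#' @export
align_protein <- function(query, subject, params = scoring_params()) {
  stopifnot(nchar(query) > 0L, nchar(subject) > 0L)
  r <- .sw_align_cpp(query, subject, params$substitution_matrix,
                     params$gap_open, params$gap_extend)
  list(score = unname(r[["score"]]),
       query_range = c(r[["qstart"]], r[["qend"]]),
       subject_range = c(r[["sstart"]], r[["send"]]))
}

#' Convert raw alignment scores to bit scores
#'
#' @param raw_score Numeric vector of raw scores.
#' @param params A [scoring_params()] object.
#' @return Bit scores `(lambda * S - ln K) / ln 2`.
#' @export
bit_score <- function(raw_score, params = scoring_params()) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' Karlin-Altschul E-value for a bit score
#'
#' @param bits Bit score(s).
#' @param m Summed translated query length.
#' @param n Summed database length.
#' @return `m * n * 2^(-bits)`.
#' @export
evalue <- function(bits, m, n) {
  m * n * 2^(-bits)
}
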