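# Plain-text I/O helpers shared by all stages. Sequences live in ordinary
# named character vectors; Biostrings handles FASTA/FASTQ parsing.

#' Read a FASTA file into a named character vector
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences; names are full header lines.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  stats::setNames(as.character(x), names(x))
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Format is chosen by file extension (`.fastq`/`.fq` vs anything else).
#'
#' @param path Path to the reads file.
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "wb") # binary mode: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write reads to FASTQ with constant Q30 qualities
#'
#' No downstream stage consumes base qualities, so a constant quality string
#' is written.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n) strrep("?", n), "") # '?' = Q30
  writeLines(rbind(paste0("@", names(reads)), unname(reads), "+", qual), con)
  invisible(path)
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
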