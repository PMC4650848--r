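# Shared helpers: sequence utilities and FASTA/FASTQ I/O (Biostrings-backed).

DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse-complement character sequences
#' @param x character vector of DNA sequences
#' @return character vector
#' @keywords internal
rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTA reference into a named character vector
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta_ref <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta_ref <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read FASTQ into a reads table
#'
#' @param path FASTQ file (plain or gzipped)
#' @return `data.table` with columns `read_id`, `seq`, `qual`
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table::data.table(
    read_id = sub("\\s.*$", "", names(ss)),
    seq = as.character(ss),
    qual = as.character(S4Vectors::mcols(ss)$qualities)
  )
}

#' Write a reads table as FASTQ
#'
#' @param reads `data.table` with `read_id`, `seq`, `qual`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# deterministic child seeds below 2^31, derived from one user seed
child_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + (stage %% 1000L)
}

phred_char <- function(q) {
  vapply(q, function(qq) rawToChar(as.raw(qq + 33L)), character(1))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
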