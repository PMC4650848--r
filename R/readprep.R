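# Demultiplexing, filtering and trimming of raw GBS reads.
#
# A read is kept only when it starts with an exact sample barcode immediately
# followed by the four-base ApeKI cut-site remnant C[A/T]GC. Retained reads
# are stripped of their barcode (so they start at the remnant), N-screened
# over the first 72 bases of the original read, screened for adapter dimers,
# and trimmed to a fixed analysis length (64 bp including the remnant).

#' Read a barcode table
#'
#' @param path TSV with columns `sample` and `barcode`
#' @return named character vector `sample -> barcode`, validated (unique,
#'   4-8 bp, ACGT, prefix-free)
#' @export
read_barcode_table <- function(path) {
  if (!file.exists(path)) stopf("barcode file not found: %s", path)
  tab <- data.table::fread(path, colClasses = "character")
  if (!all(c("sample", "barcode") %in% names(tab)))
    stopf("barcode table must have columns 'sample' and 'barcode'")
  bc <- stats::setNames(tab$barcode, tab$sample)
  validate_barcodes(bc)
  bc
}

#' Demultiplex raw reads by barcode and cut-site remnant
#'
#' Assigns each read to the sample whose barcode exactly prefixes the read
#' and is immediately followed by `C[A|T]GC`; the barcode is removed from
#' assigned reads. Barcode matching is exact (no mismatch rescue); because
#' barcodes are prefix-free a read matches at most one sample.
#'
#' @param reads `data.table` with `read_id`, `seq`, `qual` (see
#'   [read_fastq()])
#' @param barcodes named character vector (see [read_barcode_table()])
#' @return list with `reads` (assigned reads: `read_id`, `sample_id`, `seq`,
#'   `qual`, `orig_offset` = number of barcode bases removed) and `stats`
#'   (a `prep_stats` list)
#' @export
demultiplex <- function(reads, barcodes) {
  validate_barcodes(barcodes)
  if (!all(c("read_id", "seq", "qual") %in% names(reads)))
    stopf("demultiplex: malformed reads table (need read_id/seq/qual)")
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad))
    stopf("demultiplex: FASTQ record %d has seq/qual length mismatch", bad[1])

  n <- nrow(reads)
  sample_id <- rep(NA_character_, n)
  bclen <- rep(NA_integer_, n)
  for (s in names(barcodes)) {
    hit <- is.na(sample_id) & startsWith(reads$seq, barcodes[[s]])
    sample_id[hit] <- s
    bclen[hit] <- nchar(barcodes[[s]])
  }
  with_barcode <- !is.na(sample_id)
  remnant <- substr(reads$seq, bclen + 1L, bclen + 4L)
  good_remnant <- with_barcode &
    (substr(remnant, 1L, 1L) == "C") &
    (substr(remnant, 2L, 2L) %in% c("A", "T")) &
    (substr(remnant, 3L, 4L) == "GC")

  kept <- data.table::data.table(
    read_id = reads$read_id[good_remnant],
    sample_id = sample_id[good_remnant],
    seq = substr(reads$seq[good_remnant], bclen[good_remnant] + 1L,
                 nchar(reads$seq[good_remnant])),
    qual = substr(reads$qual[good_remnant], bclen[good_remnant] + 1L,
                  nchar(reads$qual[good_remnant])),
    orig_offset = bclen[good_remnant]
  )
  stats <- list(
    total_reads = n,
    with_barcode = sum(with_barcode),
    with_remnant = sum(good_remnant),
    discarded_N = 0L,
    discarded_dimer = 0L,
    discarded_short = 0L,
    retained_per_sample = table(factor(kept$sample_id,
                                       levels = names(barcodes)))
  )
  class(stats) <- "prep_stats"
  list(reads = kept, stats = stats)
}

#' Quality-filter and trim demultiplexed reads
#'
#' Drops reads with an `N` among the first 72 bases of the original
#' (barcode-included) read; drops adapter-contaminated reads -- any read in
#' which at least `dimer_min_match` bases of the common adapter start
#' within the first `trim_len` bases. This catches adapter/adapter dimers
#' (adapter immediately after the remnant) and, just as importantly,
#' read-through into the adapter on short restriction fragments, which
#' otherwise plants systematic non-genomic bases inside the fixed analysis
#' window. Survivors are trimmed to `trim_len` bases counted from the CWGC
#' remnant; reads shorter than `trim_len` are dropped.
#'
#' @param demux output of [demultiplex()] (or a compatible reads table)
#' @param trim_len analysis length, default 64 bp (remnant included)
#' @param n_window original-read window screened for N, default 72
#' @param adapter common adapter sequence
#' @param dimer_min_match minimum adapter prefix match to call
#'   dimer/read-through contamination
#' @return list with `reads` (trimmed) and updated `stats`
#' @export
quality_filter_and_trim <- function(demux, trim_len = 64L, n_window = 72L,
                                    adapter = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG",
                                    dimer_min_match = 12L) {
  reads <- if (is.list(demux) && !is.data.frame(demux)) demux$reads else demux
  stats <- if (is.list(demux) && !is.data.frame(demux)) demux$stats else NULL
  if (nrow(reads) == 0L) {
    return(list(reads = reads, stats = stats))
  }
  off <- if ("orig_offset" %in% names(reads)) reads$orig_offset else 0L
  # N screen on original read coordinates: first (n_window - offset) kept bases
  n_span <- pmax(0L, n_window - off)
  has_n <- grepl("N", substr(reads$seq, 1L, n_span), fixed = TRUE)
  # dimer / read-through: the adapter prefix occurs within the analysis window
  ad_pos <- regexpr(substr(adapter, 1L, dimer_min_match), reads$seq,
                    fixed = TRUE)
  is_dimer <- !has_n & ad_pos > 0L & ad_pos <= trim_len
  too_short <- !has_n & !is_dimer & nchar(reads$seq) < trim_len
  keep <- !has_n & !is_dimer & !too_short

  out <- reads[keep]
  out[, seq := substr(seq, 1L, trim_len)]
  out[, qual := substr(qual, 1L, trim_len)]
  if (!is.null(stats)) {
    stats$discarded_N <- stats$discarded_N + sum(has_n)
    stats$discarded_dimer <- stats$discarded_dimer + sum(is_dimer)
    stats$discarded_short <- stats$discarded_short + sum(too_short)
    stats$retained_per_sample <- table(factor(
      out$sample_id, levels = names(stats$retained_per_sample)))
  }
  list(reads = out, stats = stats)
}

#' Format preparation statistics as a table
#' @param stats a `prep_stats` list
#' @return one-row `data.table` of the counting funnel
#' @export
prep_stats_table <- function(stats) {
  data.table::data.table(
    total_reads = stats$total_reads,
    with_barcode = stats$with_barcode,
    with_remnant = stats$with_remnant,
    discarded_N = stats$discarded_N,
    discarded_dimer = stats$discarded_dimer,
    discarded_short = stats$discarded_short,
    retained = sum(stats$retained_per_sample)
  )
}

#' @export
print.prep_stats <- function(x, ...) {
  cat("GBS read preparation:\n")
  cat(sprintf("  total reads        %d\n", x$total_reads))
  cat(sprintf("  with barcode       %d (%.1f%%)\n", x$with_barcode,
              100 * x$with_barcode / max(1, x$total_reads)))
  cat(sprintf("  with CWGC remnant  %d (%.1f%%)\n", x$with_remnant,
              100 * x$with_remnant / max(1, x$total_reads)))
  cat(sprintf("  dropped: N %d, dimer %d, short %d\n",
              x$discarded_N, x$discarded_dimer, x$discarded_short))
  cat(sprintf("  retained           %d\n", sum(x$retained_per_sample)))
  invisible(x)
}
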