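# Read mapping against the unigene reference.
#
# A minimal deterministic seed-and-extend mapper: 64-bp reads are seeded with
# tiled k-mers (k = 16 by default), candidate loci are verified by
# mismatch-only comparison and, failing that, by a small-window alignment
# allowing up to `max_indel` gap bases. Mapping quality is 60 for a unique
# placement, 0 for a tied best placement, and otherwise
# min(60, 5 * (best score - second best score)), so unique hits clear the
# downstream MQ >= 30 filter and ambiguous ones do not. Homoeologous copies
# are expected to co-map onto one unigene; separating them is the
# classifier's job, not the aligner's.

#' Build a k-mer reference index
#'
#' @param reference named character vector of unigene sequences, or a FASTA
#'   path
#' @param k seed length (default 16)
#' @return a `ref_index` list with `ids`, `lengths`, `seqs`, `k` and a
#'   `postings` table (`kmer`, `unigene`, `offset` 1-based, forward strand)
#' @export
build_index <- function(reference, k = 16L) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- read_fasta_ref(reference)
  if (length(reference) == 0L) stopf("build_index: empty reference")
  if (is.null(names(reference)) || any(names(reference) == ""))
    stopf("build_index: reference sequences must be named")
  if (anyDuplicated(names(reference)))
    stopf("build_index: duplicate unigene ids in reference")
  k <- as.integer(k)
  lens <- nchar(reference)
  short <- lens < k
  if (any(short))
    warning(sprintf("build_index: %d unigene(s) shorter than k=%d skipped",
                    sum(short), k))
  posting_list <- lapply(which(!short), function(i) {
    L <- lens[i]
    off <- seq_len(L - k + 1L)
    data.table::data.table(
      kmer = substring(reference[[i]], off, off + k - 1L),
      unigene = names(reference)[i],
      offset = off)
  })
  postings <- data.table::rbindlist(posting_list)
  postings <- postings[!grepl("[^ACGT]", kmer)]
  data.table::setkey(postings, kmer)
  structure(list(ids = names(reference), lengths = unname(lens),
                 seqs = unname(reference), k = k, postings = postings),
            class = "ref_index")
}

#' Look up a k-mer in the index
#' @param index a `ref_index`
#' @param kmer a k-length DNA string
#' @return `data.table` of postings (`unigene`, `offset`)
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "ref_index"))
  km <- kmer
  index$postings[list(km), .(unigene, offset), nomatch = NULL]
}

#' Map reads to the indexed reference
#'
#' @param reads `data.table` with `read_id`, `sample_id`, `seq`, `qual`
#'   (trimmed reads); `sample_id` optional for single-sample use
#' @param index a `ref_index` from [build_index()]
#' @param max_mismatches maximum mismatches accepted (default 4)
#' @param max_indel maximum total inserted+deleted bases (default 4)
#' @return `data.table` of alignment records: `read_id`, `sample_id`,
#'   `unigene`, `pos` (1-based), `strand`, `cigar`, `nm`, `mapq`, `seq`,
#'   `qual` (both in reference orientation); unmapped reads have `unigene`
#'   `NA`
#' @export
map_reads <- function(reads, index, max_mismatches = 4L, max_indel = 4L) {
  stopifnot(inherits(index, "ref_index"))
  if (nrow(reads) == 0L)
    return(data.table::data.table(
      read_id = character(), sample_id = character(), unigene = character(),
      pos = integer(), strand = character(), cigar = character(),
      nm = integer(), mapq = integer(), seq = character(), qual = character()))
  res <- data.table::as.data.table(
    .cpp_map_reads(index$seqs, reads$seq, index$k,
                   as.integer(max_mismatches), as.integer(max_indel)))
  out <- data.table::data.table(
    read_id = reads$read_id,
    sample_id = if ("sample_id" %in% names(reads)) reads$sample_id else "S1",
    unigene = ifelse(is.na(res$ref_idx), NA_character_,
                     index$ids[res$ref_idx]),
    pos = res$pos, strand = res$strand, cigar = res$cigar,
    nm = res$nm, mapq = res$mapq,
    seq = reads$seq, qual = reads$qual)
  rev <- which(out$strand == "-")
  if (length(rev)) {
    data.table::set(out, rev, "seq", rc(out$seq[rev]))
    data.table::set(out, rev, "qual",
                    vapply(strsplit(out$qual[rev], "", fixed = TRUE),
                           function(x) paste(rev(x), collapse = ""),
                           character(1)))
  }
  out
}

#' Map a single read
#' @param read a DNA string (length >= k)
#' @param index a `ref_index`
#' @inheritParams map_reads
#' @return one-row alignment record (see [map_reads()])
#' @export
map_read <- function(read, index, max_mismatches = 4L, max_indel = 4L) {
  if (nchar(read) < index$k)
    stopf("map_read: read shorter than seed length k=%d", index$k)
  map_reads(data.table::data.table(read_id = "r1", sample_id = "S1",
                                   seq = read, qual = strrep("I", nchar(read))),
            index, max_mismatches, max_indel)
}

#' Write alignments as SAM
#'
#' Emits a minimal single-end SAM file: @HD/@SQ/@RG header, FLAG 0/16/4,
#' with NM and RG tags. Sequences are stored in reference orientation as SAM
#' requires.
#'
#' @param alignments alignment table from [map_reads()]
#' @param reference named character vector of unigene sequences
#' @param path output SAM path
#' @return `path`, invisibly
#' @export
write_sam <- function(alignments, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)),
             con)
  for (s in unique(alignments$sample_id))
    writeLines(sprintf("@RG\tID:%s\tSM:%s", s, s), con)
  a <- alignments
  mapped <- !is.na(a$unigene)
  flag <- ifelse(!mapped, 4L, ifelse(a$strand == "-", 16L, 0L))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d\tRG:Z:%s",
                   a$read_id, flag,
                   ifelse(mapped, a$unigene, "*"),
                   ifelse(mapped, a$pos, 0L),
                   ifelse(mapped, a$mapq, 0L),
                   ifelse(mapped, a$cigar, "*"),
                   a$seq, a$qual,
                   ifelse(mapped, a$nm, 0L), a$sample_id)
  writeLines(lines, con)
  invisible(path)
}

#' Read alignments from SAM
#'
#' Accepts the fields the pipeline consumes (RNAME, POS, MAPQ, CIGAR, SEQ,
#' QUAL, NM, RG); the sample is taken from the RG tag, else from the read
#' group header, else `"S1"`.
#'
#' @param path SAM file
#' @param reference optional named character vector; when given, alignments
#'   referencing unknown unigenes raise an error
#' @return alignment `data.table` (see [map_reads()])
#' @export
read_sam <- function(path, reference = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L)
    return(data.table::data.table(
      read_id = character(), sample_id = character(), unigene = character(),
      pos = integer(), strand = character(), cigar = character(),
      nm = integer(), mapq = integer(), seq = character(), qual = character()))
  fields <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = 1:11)
  opt <- strsplit(sub("^([^\t]*\t){11}", "", paste0(body, "\t")), "\t",
                  fixed = TRUE)
  get_tag <- function(tags, prefix, default) {
    hit <- tags[startsWith(tags, prefix)]
    if (length(hit)) sub(prefix, "", hit[1]) else default
  }
  nm <- vapply(opt, get_tag, character(1), prefix = "NM:i:", default = "0")
  rg <- vapply(opt, get_tag, character(1), prefix = "RG:Z:", default = "S1")
  flag <- as.integer(fields[[2]])
  mapped <- bitwAnd(flag, 4L) == 0L
  out <- data.table::data.table(
    read_id = fields[[1]],
    sample_id = rg,
    unigene = ifelse(mapped, fields[[3]], NA_character_),
    pos = ifelse(mapped, as.integer(fields[[4]]), NA_integer_),
    strand = ifelse(!mapped, NA_character_,
                    ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")),
    cigar = ifelse(mapped, fields[[6]], NA_character_),
    nm = ifelse(mapped, as.integer(nm), NA_integer_),
    mapq = ifelse(mapped, as.integer(fields[[5]]), NA_integer_),
    seq = fields[[10]],
    qual = fields[[11]])
  if (!is.null(reference)) {
    unknown <- setdiff(stats::na.omit(unique(out$unigene)), names(reference))
    if (length(unknown))
      stopf("read_sam: SAM references unknown unigene '%s'", unknown[1])
  }
  out
}

#' Mapping statistics in the style of `samtools flagstat`
#' @param alignments alignment table
#' @return list with `total`, `mapped`, `mapped_fraction`, `per_sample`
#' @export
flagstat_summary <- function(alignments) {
  mapped <- !is.na(alignments$unigene)
  list(total = nrow(alignments),
       mapped = sum(mapped),
       mapped_fraction = if (nrow(alignments)) mean(mapped) else NA_real_,
       per_sample = alignments[, .(total = .N, mapped = sum(!is.na(unigene))),
                               by = sample_id])
}

#' Sort alignments by reference coordinate
#' @param alignments alignment table
#' @return sorted copy (mapped records first, by unigene then position)
#' @export
sort_alignments <- function(alignments) {
  a <- data.table::copy(alignments)[!is.na(unigene)]
  data.table::setorder(a, unigene, pos)
  a
}
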