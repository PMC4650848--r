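# Downstream characterization of called mutations: substitution spectrum,
# allelic density per unigene, ORF-based synonymous/non-synonymous calls,
# coverage/depth summaries, mutation frequency, saturation and
# extrapolation arithmetic.

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")
ALL_SUBS <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
              "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Directed substitution spectrum of EMS SNPs
#'
#' Counts the twelve directed substitutions on the reference strand as
#' called, splits them into transitions and transversions, and reports
#' percentages to one decimal.
#'
#' @param snps `data.table` with single-base `ref` and `alt` columns
#'   (non-SNP records are skipped and tallied)
#' @return a `spectrum_table` list: `counts` (12 directed substitutions),
#'   `transitions`, `transversions`, `pct_transitions`,
#'   `pct_transversions`, `pct` per substitution, `skipped`
#' @export
mutation_spectrum <- function(snps) {
  is_snp <- nchar(snps$ref) == 1L & nchar(snps$alt) == 1L &
    snps$ref %in% DNA_BASES4 & snps$alt %in% DNA_BASES4 &
    snps$ref != snps$alt
  sub <- paste0(snps$ref[is_snp], ">", snps$alt[is_snp])
  counts <- table(factor(sub, levels = ALL_SUBS))
  ts <- sum(counts[TRANSITIONS])
  tv <- sum(counts) - ts
  total <- ts + tv
  out <- list(
    counts = counts,
    transitions = ts, transversions = tv,
    pct_transitions = round(100 * ts / max(1, total), 1),
    pct_transversions = round(100 * tv / max(1, total), 1),
    pct = round(100 * as.numeric(counts) / max(1, total), 1),
    gc_to_at = sum(counts[c("G>A", "C>T")]),
    pct_gc_to_at = round(100 * sum(counts[c("G>A", "C>T")]) / max(1, total), 1),
    skipped = sum(!is_snp))
  names(out$pct) <- ALL_SUBS
  class(out) <- "spectrum_table"
  out
}

#' Alleles (EMS SNPs) per unigene
#'
#' @param events `data.table` of EMS events with a `unigene` column
#' @return list with `per_unigene` counts, `histogram` of binned shares
#'   (1, 2, 3-5, 6-10, 11+), `mean` (1 decimal), `n_unigenes`, `total`
#' @export
alleles_per_unigene <- function(events) {
  per <- events[, .(n = .N), by = unigene]
  bins <- cut(per$n, breaks = c(0, 1, 2, 5, 10, Inf),
              labels = c("1", "2", "3-5", "6-10", "11+"))
  list(per_unigene = per,
       histogram = table(bins),
       mean = round(nrow(events) / max(1L, nrow(per)), 1),
       n_unigenes = nrow(per),
       total = nrow(events))
}

#' Find the longest open reading frame of a unigene
#'
#' The ORF is defined as the longest stop-codon-free codon stretch over all
#' six frames (three forward, three on the reverse complement); no ATG
#' anchor is required. Returned coordinates are 1-based on the forward
#' (unigene) strand.
#'
#' @param seq a DNA string
#' @return list with `start`, `end`, `strand`, `frame`, `length` (bp); the
#'   definition is recorded in `definition`
#' @export
longest_orf <- function(seq) {
  L <- nchar(seq)
  best <- list(start = NA_integer_, end = NA_integer_, strand = "+",
               frame = NA_integer_, length = 0L)
  stops <- c("TAA", "TAG", "TGA")
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    for (frame in 0:2) {
      n_cod <- (L - frame) %/% 3L
      if (n_cod < 1L) next
      starts <- frame + 1L + 3L * (seq_len(n_cod) - 1L)
      codons <- substring(s, starts, starts + 2L)
      is_stop <- codons %in% stops
      # longest run of non-stop codons
      r <- rle(is_stop)
      if (all(r$values)) next
      run_ends <- cumsum(r$lengths)
      run_starts <- run_ends - r$lengths + 1L
      good <- which(!r$values)
      gi <- good[which.max(r$lengths[good])]
      c1 <- run_starts[gi]; c2 <- run_ends[gi]
      len <- 3L * (c2 - c1 + 1L)
      if (len > best$length) {
        a <- starts[c1]; b <- starts[c2] + 2L
        if (strand == "+") {
          best <- list(start = a, end = b, strand = "+", frame = frame,
                       length = len)
        } else {
          best <- list(start = L - b + 1L, end = L - a + 1L, strand = "-",
                       frame = frame, length = len)
        }
      }
    }
  }
  best$definition <- "longest stop-free codon stretch over 6 frames (no ATG anchor)"
  best
}

#' Classify a SNP as synonymous, non-synonymous or non-coding
#'
#' Uses the unigene's longest ORF (see [longest_orf()]); SNPs outside it
#' are non-coding, SNPs inside are translated with the standard genetic
#' code and compared at the amino-acid level.
#'
#' @param seq unigene sequence
#' @param pos 1-based SNP position
#' @param ref,alt single reference/alternate bases (reference strand)
#' @param orf optional precomputed [longest_orf()] result
#' @return one of "synonymous", "non-synonymous", "non-coding",
#'   "unclassified" (ambiguous codon)
#' @export
orf_classify <- function(seq, pos, ref, alt, orf = NULL) {
  if (pos < 1L || pos > nchar(seq)) stopf("orf_classify: SNP outside unigene")
  if (substr(seq, pos, pos) != ref)
    stopf("orf_classify: reference base mismatch at position %d", pos)
  if (is.null(orf)) orf <- longest_orf(seq)
  if (is.na(orf$start) || pos < orf$start || pos > orf$end)
    return("non-coding")
  if (orf$strand == "+") {
    off <- pos - orf$start            # 0-based offset in ORF
    cod_start <- orf$start + 3L * (off %/% 3L)
    codon_ref <- substr(seq, cod_start, cod_start + 2L)
    codon_alt <- codon_ref
    substr(codon_alt, off %% 3L + 1L, off %% 3L + 1L) <- alt
  } else {
    rs <- rc(seq)
    rpos <- nchar(seq) - pos + 1L
    rstart <- nchar(seq) - orf$end + 1L
    off <- rpos - rstart
    cod_start <- rstart + 3L * (off %/% 3L)
    codon_ref <- substr(rs, cod_start, cod_start + 2L)
    codon_alt <- codon_ref
    substr(codon_alt, off %% 3L + 1L, off %% 3L + 1L) <- rc(alt)
  }
  if (grepl("[^ACGT]", codon_ref) || grepl("[^ACGT]", codon_alt))
    return("unclassified")
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[codon_ref]]
  aa_alt <- code[[codon_alt]]
  if (identical(aa_ref, aa_alt)) "synonymous" else "non-synonymous"
}

#' Per-unigene coverage and depth summary
#'
#' Coverage per unigene is the fraction of bases covered by mapped reads
#' (end-to-end and overlapping alignments merged into maximal regions).
#' Average depth per unigene divides the number of reads falling in all
#' regions by the number of regions; regions with fewer than `min_depth`
#' reads are excluded before averaging when `min_depth > 0`.
#'
#' @param alignments mapped alignment table
#' @param reference named character vector of unigene sequences
#' @param min_depth region read-count floor (default 0 = keep all; the
#'   companion histograms use 10 as in GBS practice)
#' @return `data.table` per unigene: `pct_coverage`, `n_regions`,
#'   `reads_in_regions`, `avg_depth`, plus `regions` attribute
#'   (`data.table`: unigene, start, end, reads)
#' @export
coverage_depth_summary <- function(alignments, reference, min_depth = 0L) {
  a <- alignments[!is.na(unigene)]
  if (nrow(a) == 0L)
    return(data.table::data.table(unigene = character(),
                                  pct_coverage = numeric(),
                                  n_regions = integer(),
                                  reads_in_regions = integer(),
                                  avg_depth = numeric()))
  a[, span := ref_span(cigar)]
  out_list <- list()
  reg_list <- list()
  for (u in unique(a$unigene)) {
    au <- a[unigene == u]
    ir <- IRanges::IRanges(start = au$pos, end = au$pos + au$span - 1L)
    regions <- IRanges::reduce(ir)
    hits <- IRanges::countOverlaps(regions, ir)
    keep <- if (min_depth > 0L) hits >= min_depth else rep(TRUE, length(regions))
    regions <- regions[keep]; hits <- hits[keep]
    if (length(regions) == 0L) next
    covered <- sum(IRanges::width(regions))
    reg_list[[u]] <- data.table::data.table(
      unigene = u, start = IRanges::start(regions),
      end = IRanges::end(regions), reads = hits)
    out_list[[u]] <- data.table::data.table(
      unigene = u,
      pct_coverage = 100 * covered / nchar(reference[[u]]),
      n_regions = length(regions),
      reads_in_regions = sum(hits),
      avg_depth = sum(hits) / length(regions))
  }
  out <- data.table::rbindlist(out_list)
  data.table::setattr(out, "regions", data.table::rbindlist(reg_list))
  out[]
}

# reference span consumed by a CIGAR string (M and D ops)
ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MID]", cg))[[1]]
    len <- as.integer(sub("[MID]", "", ops))
    op <- sub("[0-9]+", "", ops)
    sum(len[op %in% c("M", "D")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Histogram of unigenes by percent-coverage and depth class
#'
#' @param summary output of [coverage_depth_summary()]
#' @return list with `coverage_classes` (deciles 0-10 ... 91-100) and
#'   `depth_classes` (<=10, 11-50, 51-100, 101-500, 501-1000, >1000)
#' @export
coverage_class_histogram <- function(summary) {
  cov_bins <- cut(summary$pct_coverage,
                  breaks = c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100),
                  include.lowest = TRUE)
  depth_bins <- cut(summary$avg_depth,
                    breaks = c(0, 10, 50, 100, 500, 1000, Inf),
                    labels = c("<=10", "11-50", "51-100", "101-500",
                               "501-1000", ">1000"))
  list(coverage_classes = table(cov_bins), depth_classes = table(depth_bins))
}

#' Mutation frequency in kilobases per mutation
#'
#' @param total_covered_bp total reference bases covered by mutant reads
#' @param n_mutations number of mutational changes
#' @return one mutation per `value` Kb (1 decimal); `Inf` with a warning if
#'   `n_mutations` is zero
#' @export
mutation_frequency <- function(total_covered_bp, n_mutations) {
  if (total_covered_bp <= 0) stopf("mutation_frequency: covered bp must be > 0")
  if (n_mutations == 0) {
    warning("mutation_frequency: zero mutations; frequency is infinite")
    return(Inf)
  }
  round(total_covered_bp / n_mutations / 1000, 1)
}

#' Saturation analysis by sequential sample addition
#'
#' Samples are pooled in ascending order of mapped read count (the standard
#' protocol: start with the plant with the fewest mapped reads); after each
#' addition the number of distinct unigenes hit, the mean percent coverage
#' and the mean average depth are recomputed on the pooled alignments.
#'
#' @param alignments mapped multi-sample alignment table
#' @param reference named character vector of unigene sequences
#' @return `data.table`: `step`, `sample_id`, `reads`, `unigenes`,
#'   `mean_pct_coverage`, `mean_avg_depth`
#' @export
saturation_curve <- function(alignments, reference) {
  a <- alignments[!is.na(unigene)]
  ord <- a[, .N, by = sample_id][order(N, sample_id)]
  if (nrow(ord) < 2L) stopf("saturation_curve: need >= 2 samples")
  res <- vector("list", nrow(ord))
  for (i in seq_len(nrow(ord))) {
    pool <- a[sample_id %in% ord$sample_id[seq_len(i)]]
    cs <- coverage_depth_summary(pool, reference)
    res[[i]] <- data.table::data.table(
      step = i, sample_id = ord$sample_id[i], reads = nrow(pool),
      unigenes = nrow(cs),
      mean_pct_coverage = mean(cs$pct_coverage),
      mean_avg_depth = mean(cs$avg_depth))
  }
  data.table::rbindlist(res)
}

#' Effective and extrapolated mutation counts
#'
#' `effective = round(n_snps * nonsyn_fraction * (1 - error_rate))`;
#' scaling to full unigene coverage truncates `effective /
#' coverage_fraction`; scaling to the whole unigene set multiplies the
#' untruncated full-coverage value by `n_unigenes_total / n_unigenes_hit`
#' and truncates.
#'
#' @param n_snps EMS SNP count
#' @param nonsyn_fraction fraction of changes in non-synonymous positions
#' @param error_rate mutation-calling error rate (proportion, not percent)
#' @param coverage_fraction mean fraction of unigene sequence covered
#' @param n_unigenes_hit,n_unigenes_total unigene counts for genome-wide
#'   scaling (optional)
#' @return list with `effective`, `full_coverage` and (when the unigene
#'   counts are given) `genome_wide`
#' @export
extrapolate_effective <- function(n_snps, nonsyn_fraction, error_rate,
                                  coverage_fraction = NULL,
                                  n_unigenes_hit = NULL,
                                  n_unigenes_total = NULL) {
  if (nonsyn_fraction <= 0 || nonsyn_fraction > 1)
    stopf("extrapolate_effective: nonsyn_fraction must be in (0, 1]")
  out <- list(effective = round(n_snps * nonsyn_fraction * (1 - error_rate)))
  if (!is.null(coverage_fraction)) {
    if (coverage_fraction <= 0)
      stopf("extrapolate_effective: coverage_fraction must be > 0")
    full_exact <- out$effective / coverage_fraction
    out$full_coverage <- trunc(full_exact)
    if (!is.null(n_unigenes_hit) && !is.null(n_unigenes_total))
      out$genome_wide <- trunc(full_exact * n_unigenes_total / n_unigenes_hit)
  }
  out
}
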