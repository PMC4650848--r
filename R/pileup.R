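# Multi-sample pileup and diploid genotype calling.
#
# The genotype model is deliberately diploid even though the organism is
# hexaploid: reads from all three homoeologous copies collapse onto one
# unigene, so fixed homoeologous differences present as heterozygous calls
# in every sample -- exactly the cross-sample signal the classifier uses to
# separate them from single-plant induced mutations.

#' Multi-sample pileup over sorted alignments
#'
#' Walks every aligned read's CIGAR and accumulates per-position, per-sample
#' base observations (with base qualities), insertion/deletion observations
#' (attached to the reference base preceding the event, left-aligned), and
#' per-position read coverage with mapping-quality accumulators. Base calls
#' below `min_base_quality` are excluded from observation counts (they still
#' count as covering reads for mapping-quality purposes).
#'
#' @param alignments alignment table (see [map_reads()]); must be
#'   coordinate-sorted
#' @param reference named character vector of unigene sequences
#' @param min_base_quality Phred floor for counted bases (default 13)
#' @return a `pileup` list: `snv`, `indel`, `cover` tables, `samples`,
#'   `reference`
#' @export
pileup <- function(alignments, reference, min_base_quality = 13L) {
  a <- alignments[!is.na(unigene)]
  if (nrow(a) == 0L) stopf("pileup: no mapped alignments")
  if (is.unsorted(match(a$unigene, unique(a$unigene))) ||
      a[, any(diff(pos) < 0L), by = unigene][, any(V1)])
    stopf("pileup: alignments are not coordinate-sorted; sort with sort_alignments()")
  samples <- sort(unique(a$sample_id))
  uids <- names(reference)
  ui <- match(a$unigene, uids)
  if (anyNA(ui)) stopf("pileup: alignment references unknown unigene")
  si <- match(a$sample_id, samples)
  raw <- .cpp_pileup(ui, a$pos, si, a$seq, a$qual, a$cigar, a$mapq,
                     as.integer(min_base_quality))
  snv <- data.table::as.data.table(raw$snv)
  snv[, `:=`(unigene = uids[ref_idx], sample_id = samples[sample_idx],
             base = DNA_BASES4[base + 1L])]
  snv[, c("ref_idx", "sample_idx") := NULL]
  indel <- data.table::as.data.table(raw$indel)
  if (nrow(indel)) {
    indel[, `:=`(unigene = uids[ref_idx], sample_id = samples[sample_idx])]
    # canonical (left-aligned) representation so that identical events from
    # differently-placed alignments aggregate to one allele
    norm <- left_align_indels(reference, indel$unigene, indel$pos,
                              indel$type, indel$len, indel$seq)
    indel[, `:=`(pos = norm$pos, seq = norm$seq)]
    indel <- indel[, .(count = .N),
                   by = .(unigene, pos, sample_id, type, len, seq, qual)]
  } else {
    indel <- data.table::data.table(
      unigene = character(), pos = integer(), sample_id = character(),
      type = character(), len = integer(), seq = character(),
      qual = integer(), count = integer())
  }
  cover <- data.table::as.data.table(raw$cover)
  cover[, unigene := uids[ref_idx]][, ref_idx := NULL]
  structure(list(snv = snv, indel = indel, cover = cover,
                 samples = samples, reference = reference),
            class = "pileup")
}

#' Left-align indel representations against the reference
#'
#' Shifts each insertion/deletion to its leftmost equivalent placement (the
#' canonical VCF normalization): an insertion whose last inserted base
#' equals the anchor base rotates left; a deletion whose flanking bases
#' repeat shifts left. Anchors are 1-based positions of the base preceding
#' the event.
#'
#' @param reference named character vector of unigene sequences
#' @param unigene,pos,type,len,seq parallel vectors describing the events
#'   (`type` "I"/"D", `seq` the inserted bases for insertions)
#' @return list with normalized `pos` and `seq`
#' @export
left_align_indels <- function(reference, unigene, pos, type, len, seq) {
  n <- length(pos)
  pos <- as.integer(pos)
  for (i in seq_len(n)) {
    rs <- reference[[unigene[i]]]
    a <- pos[i]
    if (type[i] == "I") {
      s <- seq[i]; w <- nchar(s)
      while (a >= 1L && substr(rs, a, a) == substr(s, w, w)) {
        s <- paste0(substr(rs, a, a), substr(s, 1L, w - 1L))
        a <- a - 1L
      }
      if (a < 1L) { a <- pos[i]; s <- seq[i] } # cannot anchor before start
      seq[i] <- s
    } else {
      w <- len[i]
      while (a >= 2L && substr(rs, a, a) == substr(rs, a + w, a + w))
        a <- a - 1L
    }
    pos[i] <- a
  }
  list(pos = pos, seq = seq)
}

# genotype-likelihood core. obs: data.table(site_id, sample_id, class
# ("ref"/"alt"), qual, count). Returns per (site_id, sample_id): log10
# likelihoods, GT, GQ and the phred-scaled posterior of 0/0.
genotype_core <- function(obs) {
  o <- obs[class %in% c("ref", "alt")]
  o[, e := 10^(-qual / 10)]
  o[, `:=`(
    l00 = count * log10(ifelse(class == "ref", 1 - e, e / 3)),
    l01 = count * log10((1 - e) / 2 + e / 6),
    l11 = count * log10(ifelse(class == "alt", 1 - e, e / 3)))]
  g <- o[, .(ll00 = sum(l00), ll01 = sum(l01), ll11 = sum(l11)),
         by = .(site_id, sample_id)]
  g[, m := pmax(ll00, ll01, ll11)]
  g[, `:=`(p00 = 10^(ll00 - m), p01 = 10^(ll01 - m), p11 = 10^(ll11 - m))]
  g[, z := p00 + p01 + p11]
  g[, `:=`(post00 = p00 / z, post01 = p01 / z, post11 = p11 / z)]
  g[, gt := c("0/0", "0/1", "1/1")[max.col(cbind(post00, post01, post11),
                                           ties.method = "first")]]
  g[, postmax := pmax(post00, post01, post11)]
  g[, gq := as.integer(round(pmin(99, -10 * log10(pmax(1e-10, 1 - postmax))))) ]
  g[, qual00 := pmin(999, -10 * log10(pmax(1e-100, post00)))]
  g[, .(site_id, sample_id, ll00, ll01, ll11, gt, gq, qual00)]
}

#' Genotype a single pileup site
#'
#' Diploid genotype from REF/ALT observation counts under a per-base error
#' model: likelihoods L(0/0), L(0/1), L(1/1) from base qualities, GT by
#' maximum posterior with a uniform prior, GQ the phred-scaled posterior
#' mass of the non-called genotypes (capped at 99).
#'
#' @param obs `data.table` with columns `sample_id`, `class` ("ref"/"alt"),
#'   `qual` (Phred), `count`
#' @return `data.table` with `sample_id`, `gt`, `gq` and `qual00`
#'   (phred-scaled posterior that the sample is 0/0)
#' @export
genotype_site <- function(obs) {
  o <- data.table::as.data.table(obs)
  o[, site_id := 1L]
  genotype_core(o)[, .(sample_id, gt, gq, qual00)]
}

#' Genotype all candidate variant sites of a pileup
#'
#' A site is a candidate when at least one retained observation differs from
#' the reference base (or an indel is observed). The ALT allele is the most
#' frequent non-reference allele across all samples; additional alleles are
#' dropped (their observation count is reported in `dropped_alleles`).
#' Per-sample GT is `./.` for samples without retained observations at the
#' site. Site QUAL is the summed phred-scaled posterior that each covered
#' sample is 0/0; MQ is the root-mean-square mapping quality of covering
#' reads; DP and NS count retained observations and samples with data.
#'
#' @param pile a [pileup()] object
#' @return a `variant_calls` list: `sites` table (`unigene`, `pos`, `ref`,
#'   `alt`, `variant_type`, `qual`, `dp`, `ns`, `mq`), `geno` table
#'   (`site_id`, `sample_id`, `gt`, `gq`, `dp`), `samples`,
#'   `dropped_alleles` count
#' @export
genotype_sites <- function(pile) {
  stopifnot(inherits(pile, "pileup"))
  refbase <- function(u, p) substr(pile$reference[u], p, p)
  snv <- data.table::copy(pile$snv)
  snv[, ref := substring(pile$reference[unigene], pos, pos)]

  # candidate alleles per site
  alt_snv <- snv[base != ref,
                 .(count = sum(count), kind = "SNP"),
                 by = .(unigene, pos, allele = base)]
  alt_ind <- if (nrow(pile$indel)) {
    pile$indel[, .(count = sum(count), kind = "INDEL"),
               by = .(unigene, pos, allele = paste0(type, len, ":", seq))]
  } else {
    data.table::data.table(unigene = character(), pos = integer(),
                           allele = character(), count = integer(),
                           kind = character())
  }
  alt_all <- rbind(alt_snv, alt_ind)
  if (nrow(alt_all) == 0L)
    stopf("genotype_sites: no candidate variant sites")
  data.table::setorder(alt_all, unigene, pos, -count, allele)
  best <- alt_all[, .SD[1], by = .(unigene, pos)]
  dropped <- sum(alt_all$count) - sum(best$count)

  sites <- best[, .(unigene, pos, allele, kind)]
  sites[, site_id := .I]
  sites[, ref := substring(pile$reference[unigene], pos, pos)]

  # observation classes for the likelihood: ref base vs chosen alt allele
  snv2 <- sites[, .(site_id, unigene, pos, allele, kind, ref)][
    snv, on = c("unigene", "pos"), nomatch = NULL]
  snv2[, class := data.table::fcase(
    base == i.ref, "ref",
    kind == "SNP" & base == allele, "alt",
    default = "other")]
  ind2 <- sites[kind == "INDEL"][
    pile$indel[, .(unigene, pos, sample_id, type, len, seq, qual, count)],
    on = c("unigene", "pos"), nomatch = NULL]
  ind2[, class := ifelse(paste0(type, len, ":", seq) == allele,
                         "alt", "other")]
  obs <- rbind(
    snv2[, .(site_id, sample_id, class, qual, count)],
    ind2[, .(site_id, sample_id, class, qual, count)])

  geno_core <- genotype_core(obs[class != "other"])
  dp_tab <- obs[, .(dp = sum(count)), by = .(site_id, sample_id)]
  ad_tab <- obs[class == "alt", .(ad = sum(count)), by = .(site_id, sample_id)]

  # full genotype grid: uncovered samples are ./.
  grid <- data.table::CJ(site_id = sites$site_id, sample_id = pile$samples)
  geno <- geno_core[grid, on = c("site_id", "sample_id")]
  geno <- dp_tab[geno, on = c("site_id", "sample_id")]
  geno <- ad_tab[geno, on = c("site_id", "sample_id")]
  geno[is.na(dp), dp := 0L]
  geno[is.na(ad), ad := 0L]
  geno[dp == 0L | is.na(gt), `:=`(gt = "./.", gq = NA_integer_,
                                  qual00 = NA_real_)]

  site_stats <- geno[gt != "./.",
                     .(qual = round(sum(pmin(999, qual00)), 1),
                       ns = .N, dp_used = sum(dp)), by = site_id]
  dp_site <- dp_tab[, .(dp = sum(dp)), by = site_id]
  mq_tab <- pile$cover[sites[, .(site_id, unigene, pos)],
                       on = c("unigene", "pos"), nomatch = NULL]
  mq_tab <- mq_tab[, .(mq = round(sqrt(mq2_sum / n_reads), 2)), by = site_id]

  sites <- site_stats[sites, on = "site_id"]
  sites <- dp_site[sites, on = "site_id"]
  sites <- mq_tab[sites, on = "site_id"]
  sites[is.na(qual), qual := 0]
  sites[is.na(ns), ns := 0L]
  sites[is.na(dp), dp := 0L]

  # VCF-style REF/ALT strings
  sites[, variant_type := data.table::fcase(
    kind == "SNP", "SNP",
    startsWith(allele, "I"), "INS",
    startsWith(allele, "D"), "DEL")]
  sites[, alt := allele]
  sites[variant_type == "SNP", `:=`(ref_vcf = ref, alt_vcf = allele)]
  ins_i <- which(sites$variant_type == "INS")
  if (length(ins_i)) {
    anchor <- substring(pile$reference[sites$unigene[ins_i]],
                        sites$pos[ins_i], sites$pos[ins_i])
    insseq <- sub("^I[0-9]+:", "", sites$allele[ins_i])
    data.table::set(sites, ins_i, "ref_vcf", anchor)
    data.table::set(sites, ins_i, "alt_vcf", paste0(anchor, insseq))
  }
  del_i <- which(sites$variant_type == "DEL")
  if (length(del_i)) {
    w <- as.integer(sub("^D([0-9]+):.*$", "\\1", sites$allele[del_i]))
    refstr <- substring(pile$reference[sites$unigene[del_i]],
                        sites$pos[del_i], sites$pos[del_i] + w)
    data.table::set(sites, del_i, "ref_vcf", refstr)
    data.table::set(sites, del_i, "alt_vcf",
                    substring(refstr, 1L, 1L))
  }
  out_sites <- sites[, .(site_id, unigene, pos, ref = ref_vcf, alt = alt_vcf,
                         variant_type, qual, dp, ns, mq)]
  data.table::setorder(out_sites, unigene, pos)
  out_geno <- geno[, .(site_id, sample_id, gt, gq, dp, ad)]
  structure(list(sites = out_sites, geno = out_geno,
                 samples = pile$samples, dropped_alleles = dropped),
            class = "variant_calls")
}

#' Write variant calls as VCF 4.2
#'
#' INFO keys DP, NS, MQ; FORMAT GT:GQ:DP:AD (AD = alternate-allele
#' observation count); one column per sample.
#'
#' @param calls a `variant_calls` object
#' @param path output path
#' @param info_extra optional character vector (one element per row of
#'   `calls$sites`, in that order) appended verbatim to each INFO field
#' @return `path`, invisibly
#' @export
write_vcf <- function(calls, path, info_extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=polymut",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth across samples\">",
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of samples with data\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Alternate allele observation count\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class: EMS_SNP, EMS_INDEL, homoeologous, intervarietal or filtered\">",
    "##INFO=<ID=CARRIER,Number=1,Type=String,Description=\"Mutant plant carrying an EMS variant\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$samples), collapse = "\t")), con)
  g <- data.table::dcast(
    calls$geno[, .(site_id, sample_id,
                   f = paste0(gt, ":", ifelse(is.na(gq), ".", gq), ":", dp,
                              ":", ad))],
    site_id ~ sample_id, value.var = "f")
  data.table::setcolorder(g, c("site_id", calls$samples))
  s <- calls$sites
  m <- g[s[, .(site_id)], on = "site_id"]
  extra <- if (is.null(info_extra)) "" else paste0(";", info_extra)
  lines <- paste(
    s$unigene, s$pos, ".", s$ref, s$alt, s$qual, ".",
    paste0(sprintf("DP=%d;NS=%d;MQ=%s", s$dp, s$ns, s$mq), extra),
    "GT:GQ:DP:AD",
    do.call(paste, c(as.list(m[, !"site_id"]), sep = "\t")),
    sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a multi-sample VCF into a `variant_calls` object
#'
#' Parses the field subset the classifier consumes: CHROM/POS/REF/ALT/QUAL,
#' INFO DP/NS/MQ, and per-sample GT/GQ/DP from FORMAT.
#'
#' @param path VCF file
#' @return a `variant_calls` object
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1L) stopf("read_vcf: missing #CHROM header line")
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stopf("read_vcf: no variant records")
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(f) != 9L + length(samples))
    stopf("read_vcf: malformed VCF line %d (field count)",
          which(lengths(strsplit(body, "\t")) != 9L + length(samples))[1])
  info_get <- function(info, key) {
    has <- grepl(paste0("(^|;)", key, "="), info)
    out <- rep(NA_character_, length(info))
    out[has] <- sub(paste0("^.*(^|;)", key, "=([^;]*).*$"), "\\2", info[has])
    out
  }
  info <- f[[8]]
  sites <- data.table::data.table(
    site_id = seq_along(body),
    unigene = f[[1]], pos = as.integer(f[[2]]),
    ref = f[[4]], alt = f[[5]],
    qual = as.numeric(f[[6]]),
    dp = as.integer(info_get(info, "DP")),
    ns = as.integer(info_get(info, "NS")),
    mq = as.numeric(info_get(info, "MQ")))
  if (anyNA(sites$pos))
    stopf("read_vcf: malformed POS at line %d", which(is.na(sites$pos))[1])
  for (k in c("dp", "ns", "mq"))
    if (anyNA(sites[[k]]))
      stopf("read_vcf: missing INFO field %s", toupper(k))
  sites[, variant_type := data.table::fcase(
    nchar(ref) == 1L & nchar(alt) == 1L, "SNP",
    nchar(ref) < nchar(alt), "INS",
    default = "DEL")]
  fmt <- strsplit(f[[9]], ":", fixed = TRUE)
  gt_i <- vapply(fmt, function(x) match("GT", x), integer(1))
  gq_i <- vapply(fmt, function(x) match("GQ", x), integer(1))
  dp_i <- vapply(fmt, function(x) match("DP", x), integer(1))
  ad_i <- vapply(fmt, function(x) match("AD", x), integer(1))
  if (anyNA(gt_i)) stopf("read_vcf: FORMAT lacks GT")
  geno_list <- lapply(seq_along(samples), function(j) {
    cells <- strsplit(f[[9L + j]], ":", fixed = TRUE)
    pick <- function(i) vapply(seq_along(cells), function(r) {
      v <- cells[[r]]
      if (is.na(i[r]) || i[r] > length(v)) "." else v[i[r]]
    }, character(1))
    data.table::data.table(
      site_id = seq_along(body), sample_id = samples[j],
      gt = pick(gt_i),
      gq = suppressWarnings(as.integer(pick(gq_i))),
      dp = suppressWarnings(as.integer(pick(dp_i))),
      ad = suppressWarnings(as.integer(pick(ad_i))))
  })
  geno <- data.table::rbindlist(geno_list)
  geno[is.na(dp), dp := 0L]
  structure(list(sites = sites, geno = geno, samples = samples,
                 dropped_alleles = NA_integer_),
            class = "variant_calls")
}
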