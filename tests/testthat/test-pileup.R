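# helper: build an alignment table from explicit read placements
mkaln <- function(unigene, pos, seq, sample_id = "S1", qual = NULL,
                  cigar = NULL, mapq = 60L) {
  n <- max(length(unigene), length(pos), length(seq))
  data.table::data.table(
    read_id = sprintf("r%04d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    unigene = rep_len(unigene, n),
    pos = rep_len(as.integer(pos), n),
    strand = "+",
    cigar = if (is.null(cigar)) paste0(nchar(rep_len(seq, n)), "M")
            else rep_len(cigar, n),
    nm = 0L,
    mapq = rep_len(as.integer(mapq), n),
    seq = rep_len(seq, n),
    qual = if (is.null(qual)) strrep("I", nchar(rep_len(seq, n)))
           else rep_len(qual, n))
}

test_that("a uniform REF pileup has the right depth and no variant alleles", {
  ref <- c(u1 = "ACGTACGTACGTACGTACGTACGT")
  aln <- mkaln("u1", 1, rep(substr(ref[["u1"]], 1, 20), 10))
  p <- pileup(aln, ref)
  dp <- p$snv[, .(dp = sum(count)), by = pos]
  expect_true(all(dp$dp == 10L))
  expect_equal(nrow(dp), 20L)
  expect_error(genotype_sites(p), "no candidate")
})

test_that("a 5/5 REF/ALT sample is called heterozygous by likelihood symmetry", {
  ref <- c(u1 = paste0(strrep("ACGT", 8), strrep("TGCA", 3)))
  rd_ref <- substr(ref[["u1"]], 1, 20)
  rd_alt <- rd_ref
  substr(rd_alt, 10, 10) <- "A"  # ref C -> A
  aln <- mkaln("u1", 1, c(rep(rd_ref, 5), rep(rd_alt, 5)))
  calls <- genotype_sites(pileup(aln, ref))
  expect_equal(nrow(calls$sites), 1L)
  expect_equal(calls$sites$pos, 10L)
  expect_equal(calls$sites$ref, "C")
  expect_equal(calls$sites$alt, "A")
  g <- calls$geno[gt != "./."]
  expect_equal(g$gt, "0/1")
  expect_equal(g$dp, 10L)
})

test_that("genotype calls at high depth match planted zygosity", {
  ref <- c(u1 = strrep("ACGTTGCAGT", 6))
  rd_ref <- substr(ref[["u1"]], 11, 40)
  rd_alt <- rd_ref
  substr(rd_alt, 5, 5) <- "A"
  hom <- mkaln("u1", 11, rep(rd_alt, 12), sample_id = "H")
  het <- mkaln("u1", 11, c(rep(rd_alt, 6), rep(rd_ref, 6)), sample_id = "E")
  none <- mkaln("u1", 11, rep(rd_ref, 12), sample_id = "R")
  calls <- genotype_sites(pileup(rbind(hom, het, none), ref))
  g <- calls$geno[calls$sites[pos == 15L], on = "site_id"]
  expect_equal(g[sample_id == "H", gt], "1/1")
  expect_equal(g[sample_id == "E", gt], "0/1")
  expect_equal(g[sample_id == "R", gt], "0/0")
  expect_true(all(g$gq > 30))
})

test_that("uncovered samples are ./. and NS counts only covered samples", {
  ref <- c(u1 = strrep("ACGTTGCAGT", 6))
  rd <- substr(ref[["u1"]], 1, 30)
  alt <- rd; substr(alt, 3, 3) <- "T"
  a <- rbind(mkaln("u1", 1, rep(alt, 10), sample_id = "A"),
             mkaln("u1", 31, rep(substr(ref[["u1"]], 31, 60), 5),
                   sample_id = "B"))
  calls <- genotype_sites(pileup(a, ref))
  s <- calls$sites[pos == 3L]
  expect_equal(s$ns, 1L)
  g <- calls$geno[site_id == s$site_id]
  expect_equal(g[sample_id == "B", gt], "./.")
  expect_true(is.na(g[sample_id == "B", gq]))
})

test_that("site QUAL is monotonically non-decreasing in ALT observation count", {
  quals <- vapply(1:8, function(k) {
    obs <- data.table::data.table(
      sample_id = "S1",
      class = c(rep("ref", 10L), rep("alt", k)),
      qual = 40L, count = 1L)
    genotype_site(obs)$qual00
  }, numeric(1))
  expect_true(all(diff(quals) >= 0))
})

test_that("genotype posteriors match an exhaustive per-read enumeration oracle", {
  set.seed(101)
  n_agree_gt <- 0L
  for (i in 1:1000) {
    depth <- sample(1:12, 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    bases <- sample(c(ref, alt), depth, replace = TRUE,
                    prob = c(runif(1), runif(1)))
    quals <- sample(13:40, depth, replace = TRUE)
    if (!any(bases == alt)) bases[1] <- alt
    o <- oracle_genotype(bases, quals, ref, alt)
    obs <- data.table::data.table(
      sample_id = "S1", class = ifelse(bases == ref, "ref", "alt"),
      qual = quals, count = 1L)
    g <- genotype_site(obs)
    expect_identical(g$gt, o$gt)
    expect_equal(g$qual00, min(999, -10 * log10(max(1e-100, o$post["0/0"]))),
                 tolerance = 1e-6, ignore_attr = TRUE)
    n_agree_gt <- n_agree_gt + as.integer(g$gt == o$gt)
  }
  expect_equal(n_agree_gt, 1000L)
})

test_that("pileup depths equal a brute-force CIGAR-walk recount", {
  sp <- small_pipeline()
  got <- sp$pile$snv[, .(dp = sum(count)), by = .(unigene, pos, sample_id)]
  want <- oracle_depth(sp$alignments)
  data.table::setkey(got, unigene, pos, sample_id)
  data.table::setkey(want, unigene, pos, sample_id)
  expect_equal(nrow(got), nrow(want))
  merged <- merge(got, want, by = c("unigene", "pos", "sample_id"))
  expect_equal(nrow(merged), nrow(got))
  expect_identical(merged$dp.x, merged$dp.y)
})

test_that("unsorted alignments are rejected with advice to sort", {
  ref <- c(u1 = strrep("ACGTTGCAGT", 6))
  a <- mkaln("u1", c(31, 1), c(substr(ref[["u1"]], 31, 50),
                               substr(ref[["u1"]], 1, 20)))
  expect_error(pileup(a, ref), "sort")
})

test_that("indel representations are left-aligned to canonical form", {
  ref <- c(u1 = "ACGTTTTTGCAGGGGACGT")
  # deletion of one T inside the T homopolymer (bases 4-8) shifts to anchor 3
  la <- left_align_indels(ref, "u1", pos = 7L, type = "D", len = 1L, seq = "")
  expect_equal(la$pos, 3L)
  # insertion of G inside the G run (bases 12-15) shifts to anchor 11
  la2 <- left_align_indels(ref, "u1", pos = 14L, type = "I", len = 1L,
                           seq = "G")
  expect_equal(la2$pos, 11L)
  expect_equal(la2$seq, "G")
  # non-repetitive context does not move
  la3 <- left_align_indels(ref, "u1", pos = 9L, type = "D", len = 1L, seq = "")
  expect_equal(la3$pos, 9L)
})

test_that("VCF writing and reading round-trips sites and genotypes", {
  sp <- small_pipeline()
  calls <- sp$calls
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  back <- read_vcf(path)
  expect_equal(back$samples, calls$samples)
  expect_equal(nrow(back$sites), nrow(calls$sites))
  expect_equal(back$sites$unigene, calls$sites$unigene)
  expect_equal(back$sites$pos, calls$sites$pos)
  expect_equal(back$sites$ref, calls$sites$ref)
  expect_equal(back$sites$alt, calls$sites$alt)
  expect_equal(back$sites$dp, calls$sites$dp)
  expect_equal(back$sites$ns, calls$sites$ns)
  # genotypes: map original site_id -> file order
  ord <- match(paste(back$sites$unigene, back$sites$pos),
               paste(calls$sites$unigene, calls$sites$pos))
  g1 <- calls$geno[data.table::data.table(site_id = calls$sites$site_id[ord]),
                   on = "site_id"]
  g1[, site_id := rep(seq_along(ord), each = length(calls$samples))]
  data.table::setkey(g1, site_id, sample_id)
  g2 <- data.table::copy(back$geno)
  data.table::setkey(g2, site_id, sample_id)
  expect_identical(g2$gt, g1$gt)
  expect_identical(g2$dp, g1$dp)
  expect_identical(g2$gq, g1$gq)
})

test_that("the emitted VCF is readable by an independent VCF parser", {
  skip_if_not_installed("vcfR")
  sp <- small_pipeline()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sp$calls, path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_equal(nrow(v@fix), nrow(sp$calls$sites))
  expect_equal(as.integer(v@fix[, "POS"]), sp$calls$sites$pos)
  gt <- vcfR::extract.gt(v, element = "GT")
  s1 <- sp$calls$samples[1]
  mine <- sp$calls$geno[sample_id == s1][order(site_id), gt]
  expect_identical(unname(gt[, s1]), ifelse(mine == "./.", NA_character_, mine))
})
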