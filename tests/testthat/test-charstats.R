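test_that("the substitution spectrum splits transitions and transversions correctly", {
  # a single C>T change is a pure transition
  one <- mutation_spectrum(data.table::data.table(ref = "C", alt = "T"))
  expect_equal(one$pct_transitions, 100)
  expect_equal(one$transitions, 1L)

  # constructed table with the published transition/transversion split
  snps <- data.table::data.table(
    ref = c(rep("C", 4386), rep("G", 4202), rep("A", 700), rep("T", 379),
            rep("C", 2393), rep("G", 1852)),
    alt = c(rep("T", 4386), rep("A", 4202), rep("G", 700), rep("C", 379),
            rep("A", 2393), rep("T", 1852)))
  sp <- mutation_spectrum(snps)
  expect_equal(sp$transitions, 9667L)
  expect_equal(sp$transversions, 4245L)
  expect_equal(sp$pct_transitions, 69.5)
  expect_equal(sp$pct_transversions, 30.5)
  # conservation: the 12 directed counts sum to the SNP total
  expect_equal(sum(sp$counts), nrow(snps))
})

test_that("non-SNP records are skipped and tallied, not counted", {
  snps <- data.table::data.table(ref = c("A", "A", "AT"), alt = c("G", "AGG", "A"))
  sp <- mutation_spectrum(snps)
  expect_equal(sum(sp$counts), 1L)
  expect_equal(sp$skipped, 2L)
})

test_that("alleles per unigene reproduce the published mean of two per unigene", {
  # 13,912 SNPs over 6,961 unigenes: 6,951 unigenes with 2, 10 with 1
  events <- data.table::data.table(
    unigene = c(rep(sprintf("u%04d", 1:6951), each = 2),
                sprintf("u%04d", 6952:6961)))
  ap <- alleles_per_unigene(events)
  expect_equal(ap$total, 13912L)
  expect_equal(ap$n_unigenes, 6961L)
  expect_equal(ap$mean, 2.0)
  expect_equal(sum(ap$per_unigene$n), ap$total)
  expect_equal(as.integer(sum(ap$histogram)), ap$n_unigenes)
})

test_that("degenerate allele distributions collapse to one histogram cell", {
  events <- data.table::data.table(unigene = rep("u1", 7))
  ap <- alleles_per_unigene(events)
  expect_equal(as.integer(ap$histogram["6-10"]), 1L)
  expect_equal(sum(ap$histogram), 1)
})

test_that("codon-level calls match known synonymous and non-synonymous examples", {
  # 16 stop-free codons in the first forward frame dominate all other frames
  codons <- c("ATG", "GCT", "ACA", "GAA", "CTT", "GCT", "AAA", "CTT",
              "AAA", "CAT", "GCT", "TTC", "TTC", "TCA", "TGC", "TCA")
  seq <- paste0(paste(codons, collapse = ""), "TAA")
  orf <- longest_orf(seq)
  expect_equal(orf$strand, "+")
  expect_equal(orf$start, 1L)
  expect_equal(orf$end, 48L)
  # GCT -> GCC at the third codon position: Ala -> Ala, synonymous
  expect_equal(orf_classify(seq, 6L, "T", "C"), "synonymous")
  # ATG -> ATA: Met -> Ile, non-synonymous
  expect_equal(orf_classify(seq, 3L, "G", "A"), "non-synonymous")
  # a mismatching stated reference base is an input error
  expect_error(orf_classify(seq, 3L, "T", "A"), "mismatch")
})

test_that("ORF classification agrees with a translate-and-compare oracle", {
  set.seed(303)
  mismatches <- 0L
  for (i in 1:1000) {
    seq <- random_seq(sample(120:300, 1))
    pos <- sample(nchar(seq), 1)
    ref <- substr(seq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- orf_classify(seq, pos, ref, alt)
    want <- oracle_orf_classify(seq, pos, ref, alt)
    if (!identical(got, want)) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("percent coverage equals covered bases over unigene length", {
  ref <- c(u1 = paste(rep("ACGT", 25), collapse = ""))  # 100 bp
  aln <- data.table::data.table(
    read_id = c("r1", "r2"), sample_id = "S1", unigene = "u1",
    pos = c(11L, 41L), strand = "+", cigar = c("20M", "8M"), nm = 0L,
    mapq = 60L, seq = c(strrep("A", 20), strrep("A", 8)),
    qual = c(strrep("I", 20), strrep("I", 8)))
  cs <- coverage_depth_summary(aln, ref)
  expect_equal(cs$pct_coverage, 28)  # 20 + 8 disjoint covered bases
  expect_equal(cs$n_regions, 2L)
  expect_equal(cs$avg_depth, 1)     # 2 reads over 2 regions
})

test_that("coverage and depth summaries match a per-base brute-force recount", {
  sp <- small_pipeline()
  aln <- sp$alignments[!is.na(unigene)]
  cs <- coverage_depth_summary(aln, sp$sim$reference$unigenes)
  oc <- oracle_coverage(aln, sp$sim$reference$unigenes)
  m <- merge(cs, oc, by = "unigene")
  expect_equal(nrow(m), nrow(cs))
  expect_equal(m$pct_coverage, m$pct)
  # reads-in-regions conservation: every mapped read falls in some region
  expect_equal(sum(cs$reads_in_regions), nrow(aln))
})

test_that("regions below the depth floor are excluded before averaging", {
  ref <- c(u1 = strrep("ACGT", 50))
  deep <- data.table::data.table(
    read_id = sprintf("d%02d", 1:12), sample_id = "S1", unigene = "u1",
    pos = 1L, strand = "+", cigar = "40M", nm = 0L, mapq = 60L,
    seq = strrep("A", 40), qual = strrep("I", 40))
  shallow <- data.table::data.table(
    read_id = "s1", sample_id = "S1", unigene = "u1",
    pos = 101L, strand = "+", cigar = "40M", nm = 0L, mapq = 60L,
    seq = strrep("A", 40), qual = strrep("I", 40))
  cs <- coverage_depth_summary(rbind(deep, shallow), ref, min_depth = 10L)
  expect_equal(cs$n_regions, 1L)
  expect_equal(cs$pct_coverage, 20)   # only the deep 40-bp region remains
  expect_equal(cs$avg_depth, 12)
})

test_that("mutation frequency reproduces the published arithmetic", {
  expect_equal(mutation_frequency(72558853, 14130), 5.1)
  expect_equal(mutation_frequency(72558853, 28348), 2.6)
  expect_equal(mutation_frequency(1000, 1), 1.0)
  expect_warning(f <- mutation_frequency(1000, 0), "infinite")
  expect_identical(f, Inf)
})

test_that("saturation is flat for duplicate samples and additive for disjoint ones", {
  ref <- c(u1 = strrep("ACGT", 30), u2 = strrep("TGCA", 30))
  mk <- function(s, u) data.table::data.table(
    read_id = paste0(s, u, 1:3), sample_id = s, unigene = u, pos = 1L,
    strand = "+", cigar = "30M", nm = 0L, mapq = 60L,
    seq = strrep("A", 30), qual = strrep("I", 30))
  dup <- rbind(mk("A", "u1"), mk("B", "u1"))
  sc_dup <- saturation_curve(dup, ref)
  expect_equal(sc_dup$unigenes, c(1L, 1L))
  dis <- rbind(mk("A", "u1"), mk("B", "u2"))
  sc_dis <- saturation_curve(dis, ref)
  expect_equal(sc_dis$unigenes, c(1L, 2L))
  # pooled recomputation oracle on a simulated run
  sp <- small_pipeline()
  aln <- sp$alignments[!is.na(unigene)]
  sc <- saturation_curve(aln, sp$sim$reference$unigenes)
  expect_true(all(diff(sc$unigenes) >= 0))
  expect_equal(sc$unigenes[nrow(sc)],
               data.table::uniqueN(aln$unigene))
  ord <- aln[, .N, by = sample_id][order(N, sample_id), sample_id]
  pool2 <- aln[sample_id %in% ord[1:2]]
  expect_equal(sc$unigenes[2], data.table::uniqueN(pool2$unigene))
})

test_that("effective-mutation extrapolation reproduces the published chain", {
  ex <- extrapolate_effective(13912, 0.63, 0.0133, coverage_fraction = 0.28,
                              n_unigenes_hit = 79123,
                              n_unigenes_total = 178494)
  expect_equal(ex$effective, 8648)
  expect_equal(ex$full_coverage, 30885)
  expect_equal(ex$genome_wide, 69675)
  id <- extrapolate_effective(100, 1, 0, coverage_fraction = 1,
                              n_unigenes_hit = 10, n_unigenes_total = 10)
  expect_equal(id$effective, 100)
  expect_equal(id$full_coverage, 100)
  expect_equal(id$genome_wide, 100)
  expect_error(extrapolate_effective(10, 0.5, 0.1, coverage_fraction = 0),
               "coverage_fraction")
})
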