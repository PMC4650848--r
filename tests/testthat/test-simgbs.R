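test_that("zero divergence and intervarietal rate give identical copies and empty truth", {
  cfg <- sim_config(n_unigenes = 5L, homoeolog_divergence = 0,
                    intervarietal_rate = 0, seed = 3L)
  ref <- simulate_reference(cfg)
  for (u in names(ref$unigenes)) {
    cps <- ref$copies[unigene == u, seq]
    expect_identical(cps, rep(ref$unigenes[[u]], 3L))
  }
  expect_equal(nrow(ref$truth$homoeo_sites), 0L)
  expect_equal(nrow(ref$truth$intervarietal_sites), 0L)
})

test_that("pairwise copy divergence matches the configured rate", {
  cfg <- sim_config(n_unigenes = 50L, unigene_len_range = c(300L, 900L),
                    homoeolog_divergence = 0.01, intervarietal_rate = 0,
                    seed = 5L)
  ref <- simulate_reference(cfg)
  tot <- 0L; mism <- 0L
  for (u in names(ref$unigenes)) {
    cps <- ref$copies[unigene == u, seq]
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      a <- strsplit(cps[pair[1]], "")[[1]]
      b <- strsplit(cps[pair[2]], "")[[1]]
      tot <- tot + length(a)
      mism <- mism + sum(a != b)
    }
  }
  p_hat <- mism / tot
  sd3 <- 3 * sqrt(0.01 * 0.99 / tot)
  expect_lt(abs(p_hat - 0.01), sd3)
  # every planted site is recorded: recount mismatches against the truth list
  expect_equal(mism, ref$truth$homoeo_sites[, 2 * .N])
})

test_that("the same seed reproduces reference, truth and reads byte-identically", {
  cfg <- sim_config(n_unigenes = 8L, n_mutant_plants = 2L,
                    n_wildtype_plants = 1L, ems_snps_per_plant = 5L,
                    ems_indels_per_plant = 1L, seed = 99L)
  s1 <- simulate_gbs(cfg)
  s2 <- simulate_gbs(cfg)
  expect_identical(s1$reference$unigenes, s2$reference$unigenes)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$sequenced$reads, s2$sequenced$reads)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(homoeolog_divergence = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(trim_len = 120), "trim_len")
  expect_error(sim_config(n_unigenes = 0), "n_unigenes")
  cfg <- sim_config(n_unigenes = 2L, unigene_len_range = c(5L, 5L))
  expect_error(simulate_reference(cfg), "degenerate")
})

test_that("plants receive exactly the configured EMS load, avoiding planted sites", {
  ss <- small_sim()
  sim <- ss$sim; cfg <- ss$cfg
  ev <- sim$truth$ems_events
  counts <- ev[, .(snps = sum(type == "SNP"), indels = sum(type != "SNP")),
               by = plant]
  expect_true(all(counts$snps == cfg$ems_snps_per_plant))
  expect_true(all(counts$indels == cfg$ems_indels_per_plant))
  expect_true(all(startsWith(counts$plant, "M")))
  # no collision with homoeologous or intervarietal sites, no duplicates
  occupied <- rbind(sim$truth$homoeo_sites[, .(unigene, pos)],
                    sim$truth$intervarietal_sites[, .(unigene, pos)])
  expect_equal(nrow(ev[occupied, on = c("unigene", "pos"), nomatch = NULL]), 0L)
  expect_equal(anyDuplicated(ev[, .(unigene, pos)]), 0L)
  # deletion sizes 1-3 bp, insertion sizes 1-4 bp
  expect_true(all(ev[type == "DEL", len] %in% 1:3))
  expect_true(all(ev[type == "INS", len] %in% 1:4))
})

test_that("zero EMS load leaves mutant chromatids identical to the reference copies", {
  cfg <- sim_config(n_unigenes = 4L, n_mutant_plants = 2L,
                    n_wildtype_plants = 0L, ems_snps_per_plant = 0L,
                    ems_indels_per_plant = 0L, seed = 12L)
  ref <- simulate_reference(cfg)
  mut <- plant_ems(ref, cfg)
  cp <- ref$copies
  data.table::setkey(cp, unigene, copy_idx)
  expect_identical(mut$chromatids$seq,
                   cp[.(mut$chromatids$unigene, mut$chromatids$copy_idx), seq])
})

test_that("the GC->AT spectrum knob is honoured at its boundary and in expectation", {
  cfg1 <- sim_config(n_unigenes = 20L, n_mutant_plants = 1L,
                     n_wildtype_plants = 0L, ems_snps_per_plant = 200L,
                     ems_indels_per_plant = 0L, ems_gc_to_at_fraction = 1,
                     seed = 21L)
  mut1 <- plant_ems(simulate_reference(cfg1), cfg1)
  ev1 <- mut1$truth$ems_events
  expect_true(all((ev1$ref == "G" & ev1$alt == "A") |
                    (ev1$ref == "C" & ev1$alt == "T")))

  cfg2 <- sim_config(n_unigenes = 200L, n_mutant_plants = 5L,
                     n_wildtype_plants = 0L, ems_snps_per_plant = 2000L,
                     ems_indels_per_plant = 0L, ems_gc_to_at_fraction = 0.43,
                     seed = 22L)
  mut2 <- plant_ems(simulate_reference(cfg2), cfg2)
  ev2 <- mut2$truth$ems_events
  frac <- ev2[, mean((ref == "G" & alt == "A") | (ref == "C" & alt == "T"))]
  sd3 <- 3 * sqrt(0.43 * 0.57 / nrow(ev2))
  expect_lt(abs(frac - 0.43), sd3)
})

test_that("an impossible mutation load raises an error", {
  cfg <- sim_config(n_unigenes = 1L, unigene_len_range = c(30L, 30L),
                    n_mutant_plants = 1L, n_wildtype_plants = 0L,
                    ems_snps_per_plant = 500L, ems_indels_per_plant = 0L,
                    seed = 2L)
  ref <- simulate_reference(cfg)
  expect_error(plant_ems(ref, cfg), "eligible")
})

test_that("sequences without a cut site yield no reads", {
  cfg <- sim_config(seed = 1L, junk_fraction = 0, base_error_rate = 0)
  chrom <- data.table::data.table(
    plant = "M01", unigene = "UG00001", copy_idx = 1L, chromatid = 1L,
    seq = strrep("AT", 200L)) # no GCWGC anywhere
  mut <- list(chromatids = chrom,
              plants = data.table::data.table(plant = "M01", role = "mutant"))
  sq <- digest_and_sequence(mut, c(M01 = "ACGT"), cfg)
  expect_equal(nrow(sq$reads), 0L)
})

test_that("error-free reads are exact fragment substrings of the planted chromatids", {
  cfg <- sim_config(n_unigenes = 10L, n_mutant_plants = 2L,
                    n_wildtype_plants = 1L, ems_snps_per_plant = 10L,
                    ems_indels_per_plant = 1L, base_error_rate = 0,
                    junk_fraction = 0, seed = 31L)
  sim <- simulate_gbs(cfg)
  reads <- sim$sequenced$reads
  expect_true(all(!reads$junk))
  ch <- sim$mutated$chromatids
  pad <- paste0(cfg$adapter, strrep("A", 200L))
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    bc <- sim$barcodes[[reads$plant[i]]]
    body <- substr(reads$seq[i], nchar(bc) + 1L, nchar(reads$seq[i]))
    meta <- strsplit(reads$read_id[i], "|", fixed = TRUE)[[1]]
    seqs <- ch[plant == meta[2] & unigene == meta[3], seq]
    seqs <- c(seqs, as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs))))
    # insert may be shorter than the read and padded with adapter + poly-A:
    # accept if some prefix of the body is a fragment substring and the
    # remainder equals the padding prefix
    for (k in nchar(body):1) {
      tail_ok <- k == nchar(body) ||
        substr(body, k + 1L, nchar(body)) == substr(pad, 1L, nchar(body) - k)
      if (!tail_ok) next
      if (any(vapply(seqs, grepl, logical(1),
                     pattern = substr(body, 1L, k), fixed = TRUE)))
        return(TRUE)
    }
    FALSE
  }, logical(1))
  expect_true(all(ok))
})

test_that("total read count follows the Poisson fragment-depth model", {
  cfg <- sim_config(n_unigenes = 50L, n_mutant_plants = 1L,
                    n_wildtype_plants = 0L, ems_snps_per_plant = 0L,
                    ems_indels_per_plant = 0L, mean_depth_per_fragment = 20,
                    junk_fraction = 0, base_error_rate = 0, seed = 41L)
  sim <- simulate_gbs(cfg)
  n_frag <- nrow(sim$sequenced$fragments)
  lambda_tot <- 20 * n_frag
  expect_lt(abs(nrow(sim$sequenced$reads) - lambda_tot),
            3 * sqrt(lambda_tot))
})

test_that("barcode validation enforces uniqueness, length and prefix-freeness", {
  vb <- polymut:::validate_barcodes
  expect_error(vb(character(0)), "empty")
  expect_error(vb(c(a = "ACGT", b = "ACGT")), "unique")
  expect_error(vb(c(a = "ACG")), "4-8")
  expect_error(vb(c(a = "ACGT", b = "ACGTA")), "prefix")
  expect_silent(vb(default_barcodes(paste0("P", 1:24))))
})
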