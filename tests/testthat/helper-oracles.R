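# Independent oracles and shared fixtures for the test suite.
# Oracles deliberately use different algorithms/data paths than the
# implementation they check.

suppressMessages({
  library(data.table)
})

# ---- shared small simulated experiment (computed once per test run) ----
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(n_unigenes = 25L, n_mutant_plants = 3L,
                      n_wildtype_plants = 1L, ems_snps_per_plant = 15L,
                      ems_indels_per_plant = 2L, seed = 11L)
    .fixture_env$small <- list(cfg = cfg, sim = simulate_gbs(cfg))
  }
  .fixture_env$small
}

small_pipeline <- function() {
  if (is.null(.fixture_env$small_pipe)) {
    ss <- small_sim()
    sim <- ss$sim
    dm <- demultiplex(sim$sequenced$reads[, .(read_id, seq, qual)],
                      sim$barcodes)
    tr <- quality_filter_and_trim(dm)
    idx <- build_index(sim$reference$unigenes)
    aln <- map_reads(tr$reads, idx)
    pile <- pileup(sort_alignments(aln), sim$reference$unigenes)
    calls <- genotype_sites(pile)
    .fixture_env$small_pipe <- list(sim = sim, demux = dm, trimmed = tr,
                                    index = idx, alignments = aln,
                                    pile = pile, calls = calls)
  }
  .fixture_env$small_pipe
}

# ---- genotype-likelihood oracle: explicit enumeration ----
# For each read independently, enumerate (sampled chromatid x observed base)
# outcomes and sum the probability of outcomes consistent with the observed
# base; multiply across reads. Uses no shared code with genotype_core().
oracle_genotype <- function(bases, quals, ref, alt) {
  geno_alleles <- list(`0/0` = c(ref, ref), `0/1` = c(ref, alt),
                       `1/1` = c(alt, alt))
  lik <- vapply(geno_alleles, function(al) {
    p <- 1
    for (i in seq_along(bases)) {
      e <- 10^(-quals[i] / 10)
      pr <- 0
      for (chrom in 1:2) {
        for (obs in c("A", "C", "G", "T")) {
          p_obs <- if (obs == al[chrom]) 1 - e else e / 3
          if (obs == bases[i]) pr <- pr + 0.5 * p_obs
        }
      }
      p <- p * pr
    }
    p
  }, numeric(1))
  post <- lik / sum(lik)
  list(lik = lik, post = post,
       gt = names(post)[which.max(post)])
}

# ---- pileup depth oracle: per-read CIGAR walk in R ----
# Recounts, for every (unigene, position, sample), the number of retained
# base observations, independently of the C++ accumulation.
oracle_depth <- function(alignments, min_bq = 13L) {
  rows <- list()
  a <- alignments[!is.na(unigene)]
  for (i in seq_len(nrow(a))) {
    cg <- a$cigar[i]
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDS]", cg))[[1]]
    lens <- as.integer(sub("[MIDS]", "", ops))
    op <- sub("[0-9]+", "", ops)
    fp <- a$pos[i]; rp <- 1L
    qs <- utf8ToInt(a$qual[i]) - 33L
    recs <- list()
    for (j in seq_along(op)) {
      if (op[j] == "M") {
        keep <- qs[rp:(rp + lens[j] - 1L)] >= min_bq
        if (any(keep))
          recs[[j]] <- data.table(pos = (fp:(fp + lens[j] - 1L))[keep])
        fp <- fp + lens[j]; rp <- rp + lens[j]
      } else if (op[j] == "D") {
        fp <- fp + lens[j]
      } else { # I and S consume read only
        rp <- rp + lens[j]
      }
    }
    if (length(recs))
      rows[[i]] <- data.table(unigene = a$unigene[i],
                              sample_id = a$sample_id[i],
                              rbindlist(recs))
  }
  rbindlist(rows)[, .(dp = .N), by = .(unigene, pos, sample_id)]
}

# ---- coverage oracle: per-base logical vector ----
oracle_coverage <- function(alignments, reference) {
  a <- alignments[!is.na(unigene)]
  out <- list()
  for (u in unique(a$unigene)) {
    L <- nchar(reference[[u]])
    covered <- logical(L)
    au <- a[unigene == u]
    for (i in seq_len(nrow(au))) {
      cg <- au$cigar[i]
      ops <- regmatches(cg, gregexpr("[0-9]+[MID]", cg))[[1]]
      lens <- as.integer(sub("[MID]", "", ops))
      op <- sub("[0-9]+", "", ops)
      span <- sum(lens[op %in% c("M", "D")])
      covered[au$pos[i]:(au$pos[i] + span - 1L)] <- TRUE
    }
    out[[u]] <- data.table(unigene = u, covered_bases = sum(covered),
                           pct = 100 * sum(covered) / L)
  }
  rbindlist(out)
}

# ---- ORF classification oracle: whole-protein translate and compare ----
oracle_orf_classify <- function(seq, pos, ref, alt) {
  orf <- longest_orf(seq)
  if (is.na(orf$start) || pos < orf$start || pos > orf$end)
    return("non-coding")
  mut <- seq
  substr(mut, pos, pos) <- alt
  extract <- function(s) {
    o <- substr(s, orf$start, orf$end)
    if (orf$strand == "-")
      o <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(o)))
    o
  }
  p_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(extract(seq)), no.init.codon = TRUE))
  p_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(extract(mut)), no.init.codon = TRUE))
  if (identical(p_ref, p_alt)) "synonymous" else "non-synonymous"
}

# ---- exhaustive mapping oracle: try every position of every unigene ----
oracle_best_locus <- function(read, reference) {
  m <- nchar(read)
  best <- NULL
  rc1 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  for (u in names(reference)) {
    s <- reference[[u]]
    L <- nchar(s)
    if (L < m) next
    for (str in c("+", "-")) {
      rd <- if (str == "+") read else rc1
      for (p in 1:(L - m + 1L)) {
        mm <- sum(strsplit(rd, "")[[1]] != strsplit(substr(s, p, p + m - 1L),
                                                    "")[[1]])
        if (is.null(best) || mm < best$mm)
          best <- list(unigene = u, pos = p, strand = str, mm = mm, ties = 1L)
        else if (mm == best$mm) best$ties <- best$ties + 1L
      }
    }
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# ---- constructed variant_calls objects for classifier tests ----
# gts: named list site_name -> named character vector sample -> GT
make_calls <- function(gts, gq = 90L, qual = 100, dp_per_sample = 20L,
                       mq = 60, ref = "A", alt = "G") {
  samples <- sort(unique(unlist(lapply(gts, names))))
  sites <- data.table(
    site_id = seq_along(gts),
    unigene = paste0("UG", sprintf("%05d", seq_along(gts))),
    pos = 100L + seq_along(gts),
    ref = ref, alt = alt,
    variant_type = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP",
                          ifelse(nchar(alt) > nchar(ref), "INS", "DEL")),
    qual = qual, mq = mq)
  geno <- rbindlist(lapply(seq_along(gts), function(i) {
    g <- gts[[i]]
    data.table(site_id = i, sample_id = names(g), gt = unname(g),
               gq = ifelse(g == "./.", NA_integer_, as.integer(gq)),
               dp = ifelse(g == "./.", 0L, dp_per_sample),
               ad = data.table::fcase(unname(g) == "0/1",
                                      as.integer(dp_per_sample / 2),
                                      unname(g) == "1/1",
                                      as.integer(dp_per_sample),
                                      default = 0L))
  }))
  cov <- geno[gt != "./.", .(dp = sum(dp), ns = .N), by = site_id]
  sites <- cov[sites, on = "site_id"]
  sites[is.na(dp), `:=`(dp = 0L, ns = 0L)]
  setcolorder(sites, c("site_id", "unigene", "pos", "ref", "alt",
                       "variant_type", "qual", "dp", "ns", "mq"))
  structure(list(sites = sites[], geno = geno, samples = samples,
                 dropped_alleles = 0L),
            class = "variant_calls")
}
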