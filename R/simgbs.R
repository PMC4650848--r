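# Synthetic hexaploid GBS experiment with known ground truth.
#
# The generative model: a set of unigenes (the reference transcriptome), three
# homoeologous copies per unigene (fixed subgenome differences), intervarietal
# substitutions shared by every plant, and per-plant EMS events (SNPs with a
# GC->AT-biased spectrum plus 1-3 bp deletions / 1-4 bp insertions). Each
# plant carries two chromatids per homoeologous copy so that heterozygous and
# homozygous EMS states are distinguishable. Libraries are ApeKI (GCWGC)
# reduced-representation: fragments between cut sites, sequenced from cut
# ends as barcode + CWGC-remnant-led reads.

#' Simulation configuration
#'
#' Collects and validates all knobs of the synthetic GBS experiment.
#'
#' @param n_unigenes number of unigenes in the reference transcriptome
#' @param unigene_len_range length-2 integer vector, min/max unigene length (bp)
#' @param homoeolog_divergence expected pairwise substitution rate between two
#'   homoeologous copies of the same unigene
#' @param intervarietal_rate per-bp rate of substitutions (relative to the
#'   unigene reference) shared by all plants and all three copies
#' @param n_mutant_plants,n_wildtype_plants sample sizes
#' @param ems_snps_per_plant,ems_indels_per_plant EMS events planted per
#'   mutant plant
#' @param ems_gc_to_at_fraction fraction of EMS SNPs that are G>A or C>T
#' @param ems_het_fraction fraction of EMS events planted heterozygous (one
#'   chromatid of one copy); the rest mutate both chromatids
#' @param ems_insertion_fraction fraction of EMS INDELs that are insertions
#' @param read_len raw read length (bp), including the barcode
#' @param trim_len analysis read length after barcode removal (bp), counted
#'   from the CWGC remnant
#' @param mean_depth_per_fragment Poisson mean read count per restriction
#'   fragment per chromatid
#' @param base_error_rate per-base sequencing error probability
#' @param junk_fraction fraction of the final FASTQ made of junk reads
#'   (no barcode / bad remnant / N-containing / adapter dimer)
#' @param adapter common adapter sequence used for dimer simulation and
#'   read padding
#' @param seed integer seed; a fixed seed gives byte-identical outputs
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_unigenes = 200L,
                       unigene_len_range = c(300L, 900L),
                       homoeolog_divergence = 0.02,
                       intervarietal_rate = 0.005,
                       n_mutant_plants = 5L,
                       n_wildtype_plants = 2L,
                       ems_snps_per_plant = 60L,
                       ems_indels_per_plant = 6L,
                       ems_gc_to_at_fraction = 0.43,
                       ems_het_fraction = 0.89,
                       ems_insertion_fraction = 0.36,
                       read_len = 100L,
                       trim_len = 64L,
                       mean_depth_per_fragment = 20,
                       base_error_rate = 0.001,
                       junk_fraction = 0.05,
                       adapter = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG",
                       seed = 42L) {
  cfg <- list(
    n_unigenes = as.integer(n_unigenes),
    unigene_len_range = as.integer(unigene_len_range),
    homoeolog_divergence = homoeolog_divergence,
    intervarietal_rate = intervarietal_rate,
    n_mutant_plants = as.integer(n_mutant_plants),
    n_wildtype_plants = as.integer(n_wildtype_plants),
    ems_snps_per_plant = as.integer(ems_snps_per_plant),
    ems_indels_per_plant = as.integer(ems_indels_per_plant),
    ems_gc_to_at_fraction = ems_gc_to_at_fraction,
    ems_het_fraction = ems_het_fraction,
    ems_insertion_fraction = ems_insertion_fraction,
    read_len = as.integer(read_len),
    trim_len = as.integer(trim_len),
    mean_depth_per_fragment = mean_depth_per_fragment,
    base_error_rate = base_error_rate,
    junk_fraction = junk_fraction,
    adapter = as.character(adapter),
    seed = as.integer(seed)
  )
  rates <- c("homoeolog_divergence", "intervarietal_rate",
             "ems_gc_to_at_fraction", "ems_het_fraction",
             "ems_insertion_fraction", "base_error_rate", "junk_fraction")
  for (r in rates) {
    if (!is.numeric(cfg[[r]]) || cfg[[r]] < 0 || cfg[[r]] > 1)
      stopf("sim_config: '%s' must lie in [0, 1]", r)
  }
  if (cfg$n_unigenes < 1L) stopf("sim_config: n_unigenes must be >= 1")
  if (length(cfg$unigene_len_range) != 2L || any(cfg$unigene_len_range < 1L) ||
      cfg$unigene_len_range[1] > cfg$unigene_len_range[2])
    stopf("sim_config: invalid unigene_len_range")
  if (cfg$trim_len > cfg$read_len)
    stopf("sim_config: trim_len must not exceed read_len")
  if (cfg$mean_depth_per_fragment < 0)
    stopf("sim_config: mean_depth_per_fragment must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Write / read a simulation configuration as YAML
#' @param config a `sim_config`
#' @param path YAML file
#' @return `path` (write) or a `sim_config` (read)
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

# substitute single bases at 1-based positions within one sequence string
apply_subs <- function(seq, pos, alt) {
  if (length(pos) == 0L) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  s[pos] <- alt
  paste(s, collapse = "")
}

#' Simulate the unigene reference and its homoeologous copies
#'
#' Generates `n_unigenes` random unigene sequences, then derives three
#' homoeologous copies per unigene. Homoeologous sites are drawn at per-bp
#' rate `1.5 * homoeolog_divergence` and each assigns an alternate base to
#' exactly one copy, so the expected pairwise divergence between two copies
#' equals `homoeolog_divergence`. Intervarietal sites (rate
#' `intervarietal_rate`) substitute the same alternate base into all three
#' copies. The two site classes never share a position.
#'
#' @param config a [sim_config()]
#' @return list with `unigenes` (named character vector), `copies`
#'   (`data.table`: `unigene`, `copy_idx`, `seq`) and `truth`
#'   (list of `homoeo_sites` and `intervarietal_sites` tables; 1-based
#'   positions)
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$unigene_len_range < 20L))
    stopf("simulate_reference: degenerate configuration (unigene length < 20)")
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_unigenes
  lens <- sample(seq(config$unigene_len_range[1], config$unigene_len_range[2]),
                 n, replace = TRUE)
  ids <- sprintf("UG%05d", seq_len(n))
  unigenes <- vapply(lens, random_dna, character(1))
  names(unigenes) <- ids

  p_site <- 1.5 * config$homoeolog_divergence
  homo_list <- vector("list", n)
  intv_list <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]
    bases <- strsplit(unigenes[i], "", fixed = TRUE)[[1]]
    is_homo <- runif(L) < p_site
    is_intv <- !is_homo & runif(L) < config$intervarietal_rate
    hp <- which(is_homo)
    ip <- which(is_intv)
    if (length(hp)) {
      refb <- bases[hp]
      altb <- vapply(refb, function(b) sample(setdiff(DNA_BASES4, b), 1L),
                     character(1), USE.NAMES = FALSE)
      homo_list[[i]] <- data.table::data.table(
        unigene = ids[i], pos = hp, ref = refb, alt = altb,
        copies = sample(1:3, length(hp), replace = TRUE))
    }
    if (length(ip)) {
      refb <- bases[ip]
      altb <- vapply(refb, function(b) sample(setdiff(DNA_BASES4, b), 1L),
                     character(1), USE.NAMES = FALSE)
      intv_list[[i]] <- data.table::data.table(
        unigene = ids[i], pos = ip, ref = refb, alt = altb)
    }
  }
  homoeo <- data.table::rbindlist(homo_list)
  intv <- data.table::rbindlist(intv_list)
  if (nrow(homoeo) == 0L)
    homoeo <- data.table::data.table(unigene = character(), pos = integer(),
                                     ref = character(), alt = character(),
                                     copies = integer())
  if (nrow(intv) == 0L)
    intv <- data.table::data.table(unigene = character(), pos = integer(),
                                   ref = character(), alt = character())

  copies <- data.table::CJ(unigene = ids, copy_idx = 1:3, sorted = FALSE)
  data.table::setorder(copies, unigene, copy_idx)
  copies[, seq := {
    u <- unigene; ci <- copy_idx
    mapply(function(u1, c1) {
      s <- unigenes[[u1]]
      iv <- intv[unigene == u1]
      if (nrow(iv)) s <- apply_subs(s, iv$pos, iv$alt)
      hm <- homoeo[unigene == u1 & copies == c1]
      if (nrow(hm)) s <- apply_subs(s, hm$pos, hm$alt)
      s
    }, u, ci, USE.NAMES = FALSE)
  }]
  list(unigenes = unigenes, copies = copies,
       truth = list(homoeo_sites = homoeo, intervarietal_sites = intv))
}

# apply one chromatid's EMS events (SNPs then indels, right-to-left) to seq
apply_events <- function(seq, ev) {
  snps <- ev[type == "SNP"]
  if (nrow(snps)) seq <- apply_subs(seq, snps$pos, snps$alt)
  ind <- ev[type != "SNP"][order(-pos)]
  for (j in seq_len(nrow(ind))) {
    p <- ind$pos[j]
    if (ind$type[j] == "DEL") {
      w <- ind$len[j]
      seq <- paste0(substr(seq, 1L, p - 1L), substr(seq, p + w, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1L, p), ind$ins_seq[j],
                    substr(seq, p + 1L, nchar(seq)))
    }
  }
  seq
}

#' Plant per-plant EMS mutations onto the homoeologous copies
#'
#' Each mutant plant receives exactly `ems_snps_per_plant` SNPs and
#' `ems_indels_per_plant` INDELs (deletions 1-3 bp, insertions 1-4 bp); a
#' configured fraction of SNPs is the canonical G>A / C>T alkylation product.
#' Events are placed on one uniformly chosen copy, heterozygous events on one
#' of its two chromatids, homozygous events on both. Event positions never
#' coincide with homoeologous or intervarietal sites, nor with each other
#' (including across plants). Wild-type plants receive no events.
#'
#' @param reference output of [simulate_reference()]
#' @param config a [sim_config()]
#' @return list with `chromatids` (`data.table`: `plant`, `unigene`,
#'   `copy_idx`, `chromatid`, `seq`), `plants` (`data.table`: `plant`,
#'   `role`) and `truth` (the `ems_events` table: 1-based positions in
#'   unigene coordinates, `type` in SNP/INS/DEL, `zygosity` het/hom)
#' @export
plant_ems <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 2L))
  mut <- sprintf("M%02d", seq_len(config$n_mutant_plants))
  wt <- sprintf("W%02d", seq_len(config$n_wildtype_plants))
  plants <- data.table::data.table(
    plant = c(mut, wt),
    role = c(rep("mutant", length(mut)), rep("wildtype", length(wt))))

  # eligible positions: everything not occupied by a planted reference site
  ids <- names(reference$unigenes)
  elig <- data.table::rbindlist(lapply(ids, function(u) {
    s <- strsplit(reference$unigenes[[u]], "", fixed = TRUE)[[1]]
    data.table::data.table(unigene = u, pos = seq_along(s), ref = s)
  }))
  occupied <- rbind(
    reference$truth$homoeo_sites[, .(unigene, pos)],
    reference$truth$intervarietal_sites[, .(unigene, pos)])
  if (nrow(occupied))
    elig <- elig[!occupied, on = c("unigene", "pos")]
  ulen <- data.table::data.table(unigene = ids,
                                 ulen = nchar(reference$unigenes))
  elig <- ulen[elig, on = "unigene"]
  data.table::setkey(elig, unigene, pos)
  elig[, avail := TRUE]

  take_positions <- function(idx) {
    elig[idx, avail := FALSE]
  }

  ev_list <- list()
  for (pl in mut) {
    # SNPs
    n_gc <- rbinom(1L, config$ems_snps_per_plant, config$ems_gc_to_at_fraction)
    pool_gc <- elig[avail == TRUE & ref %in% c("G", "C")]
    pool_all <- elig[avail == TRUE]
    if (nrow(pool_gc) < n_gc ||
        nrow(pool_all) < config$ems_snps_per_plant + config$ems_indels_per_plant)
      stopf("plant_ems: requested mutation count exceeds eligible positions")
    pick_gc <- pool_gc[sample(.N, n_gc)]
    pick_gc[, alt := ifelse(ref == "G", "A", "T")]
    take_positions(pick_gc[, .(unigene, pos)])
    n_other <- config$ems_snps_per_plant - n_gc
    pool_all <- elig[avail == TRUE]
    pick_ot <- pool_all[sample(.N, n_other)]
    pick_ot[, alt := vapply(ref, function(b) {
      choices <- setdiff(DNA_BASES4, b)
      if (b == "G") choices <- setdiff(choices, "A")
      if (b == "C") choices <- setdiff(choices, "T")
      sample(choices, 1L)
    }, character(1), USE.NAMES = FALSE)]
    take_positions(pick_ot[, .(unigene, pos)])
    snps <- rbind(pick_gc, pick_ot)[, .(unigene, pos, ref, alt)]
    snps[, `:=`(type = "SNP", len = 1L, ins_seq = "")]

    # INDELs: deletions need the full footprint free and a left anchor base
    n_ins <- rbinom(1L, config$ems_indels_per_plant, config$ems_insertion_fraction)
    n_del <- config$ems_indels_per_plant - n_ins
    indels <- list()
    for (t in seq_len(n_del)) {
      w <- sample(1:3, 1L)
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 1000L)
          stopf("plant_ems: could not place a deletion (reference too occupied)")
        cand <- elig[avail == TRUE][sample(.N, 1L)]
        p <- cand$pos
        foot <- elig[.(cand$unigene, p:(p + w - 1L))]
        ok <- p >= 2L && p + w - 1L <= cand$ulen && nrow(foot) == w &&
          !anyNA(foot$avail) && all(foot$avail)
        if (isTRUE(ok)) break
      }
      take_positions(foot[, .(unigene, pos)])
      indels[[length(indels) + 1L]] <- data.table::data.table(
        unigene = cand$unigene, pos = p, ref = "", alt = "",
        type = "DEL", len = w, ins_seq = "")
    }
    for (t in seq_len(n_ins)) {
      w <- sample(1:4, 1L)
      repeat {
        cand <- elig[avail == TRUE][sample(.N, 1L)]
        if (cand$pos >= 2L && cand$pos < cand$ulen) break
      }
      take_positions(cand[, .(unigene, pos)])
      indels[[length(indels) + 1L]] <- data.table::data.table(
        unigene = cand$unigene, pos = cand$pos, ref = "", alt = "",
        type = "INS", len = w, ins_seq = random_dna(w))
    }
    ev <- rbind(snps, data.table::rbindlist(indels), fill = TRUE)
    ev[, `:=`(plant = pl,
              copy_idx = sample(1:3, .N, replace = TRUE),
              zygosity = ifelse(runif(.N) < config$ems_het_fraction,
                                "het", "hom"))]
    ev[, chromatid := ifelse(zygosity == "hom", 0L,
                             sample(1:2, .N, replace = TRUE))]
    ev_list[[pl]] <- ev
  }
  ems <- data.table::rbindlist(ev_list)
  if (nrow(ems) == 0L)
    ems <- data.table::data.table(
      unigene = character(), pos = integer(), ref = character(),
      alt = character(), type = character(), len = integer(),
      ins_seq = character(), plant = character(), copy_idx = integer(),
      zygosity = character(), chromatid = integer())

  # materialize chromatids
  grid <- data.table::CJ(plant = plants$plant, unigene = ids, copy_idx = 1:3,
                         chromatid = 1:2, sorted = FALSE)
  data.table::setorder(grid, plant, unigene, copy_idx, chromatid)
  cp <- reference$copies
  data.table::setkey(cp, unigene, copy_idx)
  grid[, seq := cp[.(grid$unigene, grid$copy_idx), seq]]
  if (nrow(ems)) {
    data.table::setkey(grid, plant, unigene, copy_idx, chromatid)
    combos <- unique(ems[, .(plant, unigene, copy_idx)])
    for (g in seq_len(nrow(combos))) {
      for (h in 1:2) {
        ev <- ems[plant == combos$plant[g] & unigene == combos$unigene[g] &
                    copy_idx == combos$copy_idx[g] &
                    (chromatid == 0L | chromatid == h)]
        if (nrow(ev)) {
          ridx <- grid[.(combos$plant[g], combos$unigene[g],
                         combos$copy_idx[g], h), which = TRUE]
          data.table::set(grid, ridx, "seq",
                          apply_events(grid$seq[ridx], ev))
        }
      }
    }
  }
  list(chromatids = grid, plants = plants,
       truth = list(ems_events = ems))
}

# locate ApeKI (GCWGC) cut positions (1-based position of the leading G)
apeki_cuts <- function(seqs) {
  hits <- Biostrings::vmatchPattern("GCWGC", Biostrings::DNAStringSet(seqs),
                                    fixed = FALSE)
  lapply(hits, IRanges::start)
}

#' Restriction-digest the chromatids and sequence barcode-tagged reads
#'
#' Fragments are the intervals between successive GCWGC cut sites (the enzyme
#' cuts between the leading G and the CWGC remnant). Every cut end is
#' sequenced inward: reads are `barcode + CWGC-remnant-led fragment prefix`,
#' padded with adapter sequence or truncated to `read_len`. Read counts per
#' fragment are Poisson with mean `mean_depth_per_fragment`; internal
#' fragments are read from either end with equal probability. Sequencing
#' errors are injected per base at `base_error_rate` (error bases get Phred
#' quality 2-15, correct bases Q40), and a configurable fraction of junk
#' reads (no barcode, bad remnant, N-containing, adapter dimer) is appended.
#'
#' @param mutated output of [plant_ems()]
#' @param barcodes named character vector, `plant -> barcode` (4-8 bp,
#'   prefix-free)
#' @param config a [sim_config()]
#' @return list with `reads` (`data.table`: `read_id`, `seq`, `qual`, plus
#'   hidden truth columns `plant`, `junk`) and `fragments` (per-chromatid
#'   fragment table)
#' @export
digest_and_sequence <- function(mutated, barcodes, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_barcodes(barcodes)
  if (!all(mutated$plants$plant %in% names(barcodes)))
    stopf("digest_and_sequence: missing barcode for some plants")
  set.seed(child_seed(config$seed, 3L))

  ct <- data.table::copy(mutated$chromatids)
  ct[, row := .I]
  cuts <- apeki_cuts(ct$seq)
  ct[, L := nchar(seq)]

  frag_list <- vector("list", nrow(ct))
  for (i in seq_len(nrow(ct))) {
    cc <- cuts[[i]]
    L <- ct$L[i]
    if (length(cc) == 0L) next
    b <- c(0L, cc) # left boundary cut of each fragment (0 = molecule start)
    e <- c(cc, NA_integer_) # right boundary cut (NA = molecule end)
    frag_list[[i]] <- data.table::data.table(
      row = i, left_cut = b, right_cut = e)
  }
  frags <- data.table::rbindlist(frag_list)
  if (nrow(frags) == 0L) {
    return(list(reads = data.table::data.table(
      read_id = character(), seq = character(), qual = character(),
      plant = character(), junk = logical()),
      fragments = data.table::data.table()))
  }
  frags <- ct[, .(row, plant, unigene, copy_idx, chromatid, L, seq)][frags, on = "row"]
  # read starts exist only at cut ends
  frags[, fwd_ok := !is.na(left_cut) & left_cut > 0L]
  frags[, rev_ok := !is.na(right_cut)]
  frags <- frags[fwd_ok | rev_ok]
  frags[, n_reads := rpois(.N, config$mean_depth_per_fragment)]

  rd <- frags[n_reads > 0L,
              .(plant = rep(plant, n_reads), unigene = rep(unigene, n_reads),
                copy_idx = rep(copy_idx, n_reads),
                chromatid = rep(chromatid, n_reads),
                seqfull = rep(seq, n_reads), L = rep(L, n_reads),
                left_cut = rep(left_cut, n_reads),
                right_cut = rep(right_cut, n_reads),
                fwd_ok = rep(fwd_ok, n_reads), rev_ok = rep(rev_ok, n_reads))]
  rd[, fwd := ifelse(fwd_ok & rev_ok, runif(.N) < 0.5, fwd_ok)]
  # insert sequence: remnant-led fragment end, inward
  rd[, ins := ifelse(
    fwd,
    substr(seqfull, left_cut + 1L,
           ifelse(is.na(right_cut), L, pmin(right_cut + 3L, L))),
    NA_character_)]
  rev_idx <- which(!rd$fwd)
  if (length(rev_idx)) {
    sub <- rd[rev_idx]
    raw <- substr(sub$seqfull, ifelse(sub$left_cut > 0L, sub$left_cut + 1L, 1L),
                  sub$right_cut + 3L)
    data.table::set(rd, rev_idx, "ins", rc(raw))
  }
  rd[, start_in_copy := ifelse(fwd, left_cut + 1L, NA_integer_)]
  rd[, anchor_cut := ifelse(fwd, left_cut, right_cut)]

  bc <- barcodes[rd$plant]
  pad <- paste0(config$adapter, strrep("A", config$read_len))
  body_len <- config$read_len - nchar(bc)
  body <- substr(paste0(rd$ins, pad), 1L, body_len)
  rd[, seq := paste0(bc, body)]
  rd[, read_id := sprintf("sim%07d|%s|%s|%d|%d|%s|%d", .I, plant, unigene,
                          copy_idx, chromatid, ifelse(fwd, "+", "-"),
                          anchor_cut)]
  rd[, junk := FALSE]

  reads <- rd[, .(read_id, seq, plant, junk)]

  # junk reads
  jf <- config$junk_fraction
  n_junk <- if (jf > 0) round(nrow(reads) * jf / (1 - jf)) else 0L
  if (n_junk > 0L) {
    jt <- sample(c("nobc", "norem", "ncontain", "dimer"), n_junk, replace = TRUE)
    jseq <- character(n_junk)
    jpl <- sample(names(barcodes), n_junk, replace = TRUE)
    for (j in seq_len(n_junk)) {
      b <- barcodes[[jpl[j]]]
      rem <- paste0("C", sample(c("A", "T"), 1L), "GC")
      fill <- function(n) random_dna(n)
      jseq[j] <- switch(
        jt[j],
        nobc = paste0("N", fill(config$read_len - 1L)),
        norem = paste0(b, "CCGC", fill(config$read_len - nchar(b) - 4L)),
        ncontain = {
          s <- paste0(b, rem, fill(config$read_len - nchar(b) - 4L))
          substr(s, 40L, 40L) <- "N"
          s
        },
        dimer = substr(paste0(b, rem, config$adapter,
                              strrep("A", config$read_len)), 1L, config$read_len)
      )
    }
    junkdt <- data.table::data.table(
      read_id = sprintf("junk%05d|%s", seq_len(n_junk), jt),
      seq = jseq, plant = NA_character_, junk = TRUE)
    reads <- rbind(reads, junkdt)
  }

  # base errors + qualities
  reads[, qual := strrep("I", nchar(seq))] # Q40
  if (config$base_error_rate > 0) {
    n_err <- rbinom(nrow(reads), nchar(reads$seq), config$base_error_rate)
    err_rows <- which(n_err > 0L & !reads$junk)
    for (i in err_rows) {
      s <- reads$seq[i]; q <- reads$qual[i]
      ps <- sample(nchar(s), n_err[i])
      for (p in ps) {
        old <- substr(s, p, p)
        if (!old %in% DNA_BASES4) next
        substr(s, p, p) <- sample(setdiff(DNA_BASES4, old), 1L)
        substr(q, p, p) <- phred_char(sample(2:15, 1L))
      }
      data.table::set(reads, i, "seq", s)
      data.table::set(reads, i, "qual", q)
    }
  }

  fragments <- frags[, .(plant, unigene, copy_idx, chromatid,
                         start = ifelse(left_cut > 0L, left_cut + 1L, 1L),
                         end = ifelse(is.na(right_cut), L,
                                      pmin(right_cut + 3L, L)))]
  list(reads = reads[, .(read_id, seq, qual, plant, junk)],
       fragments = fragments)
}

#' Default prefix-free barcode set
#'
#' Deterministic 4-8 bp barcodes whose first four bases are pairwise
#' distinct, which guarantees that no barcode is a prefix of another.
#'
#' @param plant_ids character vector of sample names
#' @return named character vector `plant -> barcode`
#' @export
default_barcodes <- function(plant_ids) {
  n <- length(plant_ids)
  if (n > 24L) stopf("default_barcodes: at most 24 samples supported")
  stems <- c("ACGT", "CATG", "GTAC", "TGCA", "AAGG", "CCTT", "GGAA", "TTCC",
             "ACTG", "CAGT", "GTCA", "TGAC", "AGCT", "CTAG", "GACT", "TCGA",
             "AGTC", "CTGA", "GATC", "TCAG", "ATCG", "CGAT", "GCTA", "TAGC")
  sufs <- c("", "A", "CG", "TAC", "GGTA", "", "A", "CG", "TAC", "GGTA",
            "", "A", "CG", "TAC", "GGTA", "", "A", "CG", "TAC", "GGTA",
            "", "A", "CG", "TAC")
  bc <- paste0(stems[seq_len(n)], sufs[seq_len(n)])
  names(bc) <- plant_ids
  bc
}

validate_barcodes <- function(barcodes) {
  if (length(barcodes) == 0L) stopf("barcode table is empty")
  if (is.null(names(barcodes)) || any(names(barcodes) == ""))
    stopf("barcodes must be a named vector (sample -> barcode)")
  if (anyDuplicated(barcodes)) stopf("barcodes must be unique")
  if (any(nchar(barcodes) < 4L | nchar(barcodes) > 8L))
    stopf("barcodes must be 4-8 bp")
  if (any(!grepl("^[ACGT]+$", barcodes)))
    stopf("barcodes must use the ACGT alphabet")
  for (i in seq_along(barcodes)) for (j in seq_along(barcodes)) {
    if (i != j && startsWith(barcodes[[j]], barcodes[[i]]))
      stopf("barcode '%s' is a prefix of '%s'", barcodes[[i]], barcodes[[j]])
  }
  invisible(TRUE)
}

#' Run the full synthetic GBS experiment
#'
#' Convenience wrapper: [simulate_reference()], [plant_ems()],
#' [digest_and_sequence()] under one configuration, optionally writing the
#' reference FASTA, pooled FASTQ, barcode table, sample roles and
#' ground-truth TSVs to a directory.
#'
#' @param config a [sim_config()]
#' @param dir optional output directory
#' @return list with `reference`, `mutated`, `sequenced`, `barcodes`,
#'   `plants`, `truth` (homoeo/intervarietal/ems tables) and, when `dir` is
#'   given, `paths`
#' @export
simulate_gbs <- function(config = sim_config(), dir = NULL) {
  reference <- simulate_reference(config)
  mutated <- plant_ems(reference, config)
  barcodes <- default_barcodes(mutated$plants$plant)
  sequenced <- digest_and_sequence(mutated, barcodes, config)
  truth <- c(reference$truth, mutated$truth)
  out <- list(reference = reference, mutated = mutated, sequenced = sequenced,
              barcodes = barcodes, plants = mutated$plants, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      reference = file.path(dir, "unigenes.fa"),
      fastq = file.path(dir, "reads.fq"),
      barcodes = file.path(dir, "barcodes.tsv"),
      roles = file.path(dir, "roles.tsv"),
      truth_homoeo = file.path(dir, "truth_homoeologous.tsv"),
      truth_intervarietal = file.path(dir, "truth_intervarietal.tsv"),
      truth_ems = file.path(dir, "truth_ems.tsv"))
    write_fasta_ref(reference$unigenes, paths$reference)
    write_fastq(sequenced$reads[, .(read_id, seq, qual)], paths$fastq)
    data.table::fwrite(data.table::data.table(sample = names(barcodes),
                                              barcode = unname(barcodes)),
                       paths$barcodes, sep = "\t")
    data.table::fwrite(mutated$plants, paths$roles, sep = "\t")
    data.table::fwrite(truth$homoeo_sites, paths$truth_homoeo, sep = "\t")
    data.table::fwrite(truth$intervarietal_sites, paths$truth_intervarietal,
                       sep = "\t")
    data.table::fwrite(truth$ems_events, paths$truth_ems, sep = "\t")
    out$paths <- paths
  }
  out
}
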