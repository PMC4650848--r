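# Consensus-chromosome physical mapping: anchor mutation-bearing unigenes
# to chromosome-arm regions (R1 proximal / R2 middle / R3 distal) via
# mapped ESTs and normalize per-region mutation loads by EST density.

#' Read a chromosome-arm region map
#'
#' @param path TSV with columns `group` (1-7), `arm` (S/L), `region`
#'   (R1/R2/R3), `frac_start`, `frac_end` (fraction-length interval),
#'   `mapped_ests` and optionally `observed_mutations`
#' @return validated `data.table`
#' @export
read_region_map <- function(path = system.file("extdata",
                                               "wheat_consensus_region_map.tsv",
                                               package = "polymut")) {
  rm_ <- data.table::fread(path)
  need <- c("group", "arm", "region", "frac_start", "frac_end", "mapped_ests")
  if (!all(need %in% names(rm_)))
    stopf("read_region_map: missing column(s) %s",
          paste(setdiff(need, names(rm_)), collapse = ", "))
  if (!all(rm_$region %in% c("R1", "R2", "R3")))
    stopf("read_region_map: region ids must be R1/R2/R3")
  cnt <- rm_[, .N, by = .(group, arm)]
  if (any(cnt$N != 3L))
    stopf("read_region_map: every arm needs exactly three regions")
  if (any(rm_$frac_start < 0 | rm_$frac_end > 1 | rm_$frac_start >= rm_$frac_end))
    stopf("read_region_map: fraction intervals must be ordered within [0, 1]")
  if (any(rm_$mapped_ests < 0))
    stopf("read_region_map: mapped_ests must be >= 0")
  rm_
}

#' Assign unigenes to chromosome regions by EST similarity
#'
#' Each unigene is aligned locally against every EST; it inherits the
#' region of its best-scoring EST when that alignment reaches
#' `min_identity` over at least `min_length` aligned bases (an
#' identity/length stand-in for a BLAST e-value cutoff). Unigenes whose
#' two best hits score equally but disagree on the region are left
#' unassigned.
#'
#' @param unigene_seqs named character vector of unigene sequences
#' @param est_seqs named character vector of EST sequences
#' @param est_regions `data.table` with `est`, `group`, `arm`, `region`
#' @param min_identity minimum percent identity (default 95)
#' @param min_length minimum aligned length in bp (default 200)
#' @return `data.table`: `unigene`, `est`, `group`, `arm`, `region`,
#'   `score`, `identity`, `aln_length`; unassigned unigenes have NA fields
#' @export
assign_unigenes <- function(unigene_seqs, est_seqs, est_regions,
                            min_identity = 95, min_length = 200L) {
  if (length(est_seqs) == 0L) stopf("assign_unigenes: empty EST set")
  if (!all(names(est_seqs) %in% est_regions$est))
    stopf("assign_unigenes: every EST needs a region label")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  out <- vector("list", length(unigene_seqs))
  ests <- Biostrings::DNAStringSet(est_seqs)
  for (i in seq_along(unigene_seqs)) {
    u <- names(unigene_seqs)[i]
    aln <- Biostrings::pairwiseAlignment(
      ests, Biostrings::DNAString(unigene_seqs[[i]]),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    sc <- Biostrings::score(aln)
    wid <- Biostrings::nchar(aln)
    idn <- Biostrings::pid(aln, type = "PID1")
    pass <- idn >= min_identity & wid >= min_length
    rec <- data.table::data.table(
      unigene = u, est = NA_character_, group = NA_integer_,
      arm = NA_character_, region = NA_character_, score = NA_real_,
      identity = NA_real_, aln_length = NA_integer_)
    if (any(pass)) {
      smax <- max(sc[pass])
      best <- which(pass & sc == smax)
      regs <- est_regions[match(names(est_seqs)[best], est),
                          paste(group, arm, region)]
      if (length(unique(regs)) == 1L) {
        b <- best[1]
        er <- est_regions[est == names(est_seqs)[b]]
        rec <- data.table::data.table(
          unigene = u, est = names(est_seqs)[b], group = er$group[1],
          arm = er$arm[1], region = er$region[1], score = sc[b],
          identity = idn[b], aln_length = wid[b])
      }
    }
    out[[i]] <- rec
  }
  data.table::rbindlist(out)
}

#' Tally observed mutations per chromosome region
#'
#' @param assignments output of [assign_unigenes()]
#' @param ems_per_unigene `data.table` with `unigene` and `n` (EMS events)
#' @return `data.table`: `group`, `arm`, `region`, `observed_mutations`
#' @export
tally_region_observations <- function(assignments, ems_per_unigene) {
  a <- assignments[!is.na(region)]
  m <- ems_per_unigene[a, on = "unigene", nomatch = NULL]
  m[, .(observed_mutations = sum(n)), by = .(group, arm, region)]
}

#' Normalized per-region mutation loads
#'
#' Each region's observed mutation count is normalized by the number of
#' ESTs mapped to that region (reported to two decimals); arm totals sum
#' the three unrounded region values and chromosome totals sum the two
#' unrounded arm values, each rounded to two decimals at the end -- the
#' summation order that reproduces the published consensus-map arithmetic.
#'
#' @param region_map a [read_region_map()] table
#' @param observed optional `data.table` (`group`, `arm`, `region`,
#'   `observed_mutations`) overriding/augmenting the map's own counts
#' @return list with `regions` (adds `normalized`), `arms`
#'   (`mutations_per_arm`) and `chromosomes` (`mutations_per_chromosome`)
#' @export
region_loads <- function(region_map, observed = NULL) {
  rl <- data.table::copy(region_map)
  if (!is.null(observed)) {
    rl[, observed_mutations := NULL]
    rl <- observed[rl, on = c("group", "arm", "region")]
    rl[is.na(observed_mutations), observed_mutations := 0L]
  }
  if (!"observed_mutations" %in% names(rl))
    stopf("region_loads: no observed mutation counts")
  bad <- rl[observed_mutations > 0L & mapped_ests == 0L]
  if (nrow(bad))
    stopf("region_loads: region %d%s %s has observations but zero mapped ESTs",
          bad$group[1], bad$arm[1], bad$region[1])
  rl[, norm_raw := ifelse(mapped_ests > 0L,
                          observed_mutations / mapped_ests, 0)]
  rl[, normalized := round(norm_raw, 2)]
  arms <- rl[, .(mapped_ests = sum(mapped_ests),
                 observed_mutations = sum(observed_mutations),
                 arm_raw = sum(norm_raw),
                 mutations_per_arm = round(sum(norm_raw), 2)),
             by = .(group, arm)]
  chroms <- arms[, .(mutations_per_chromosome = round(sum(arm_raw), 2)),
                 by = group]
  list(regions = rl[, !"norm_raw"], arms = arms[, !"arm_raw"],
       chromosomes = chroms)
}
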