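# End-to-end orchestration with plain-file handoffs between stages, so any
# stage can be swapped for an external tool (e.g. BWA-produced SAM or a
# samtools VCF) without touching the others.

#' Build a pipeline run configuration
#'
#' Either `sim` is given (fully synthetic run: the reference, reads,
#' barcodes and roles are generated) or `fastq`/`reference`/`barcodes`/
#' `roles` point to existing files.
#'
#' @param out_dir output directory (created)
#' @param criteria criteria name: "stringent", "redefined" or "custom"
#' @param sim optional [sim_config()]
#' @param fastq,reference,barcodes,roles input paths for a non-simulated run
#' @param trim_len analysis read length (default 64)
#' @param seed integer seed for any stage randomness
#' @return a `run_config` list
#' @export
run_config <- function(out_dir, criteria = "stringent", sim = NULL,
                       fastq = NULL, reference = NULL, barcodes = NULL,
                       roles = NULL, trim_len = 64L, seed = 42L) {
  if (!criteria %in% c("stringent", "redefined", "custom"))
    stopf("run_config: criteria must be stringent/redefined/custom")
  if (is.null(sim)) {
    req <- list(fastq = fastq, reference = reference, barcodes = barcodes,
                roles = roles)
    miss <- names(req)[vapply(req, is.null, logical(1))]
    if (length(miss))
      stopf("run_config: missing input path(s) %s (no simulator configured)",
            paste(miss, collapse = ", "))
    for (nm in names(req))
      if (!file.exists(req[[nm]]))
        stopf("run_config: %s file not found: %s", nm, req[[nm]])
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  structure(list(out_dir = out_dir, criteria = criteria, sim = sim,
                 fastq = fastq, reference = reference, barcodes = barcodes,
                 roles = roles, trim_len = as.integer(trim_len),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full mutation-detection pipeline
#'
#' Stages: (optionally) simulate -> demultiplex/trim -> map -> pileup and
#' genotype -> filter and classify -> per-plant report. Each stage writes
#' its outputs under `out_dir` and its statistics into the returned (and
#' saved) run manifest; a failure aborts with a stage-named error.
#'
#' @param config a [run_config()]
#' @return the manifest list (also written to `out_dir/manifest.json`);
#'   simulated runs gain `truth_comparison` (see [compare_to_truth()])
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("polymut")),
                   seed = config$seed, criteria = config$criteria,
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  sim <- NULL
  if (!is.null(config$sim)) {
    sim <- stage("simulate", simulate_gbs(config$sim,
                                          dir = file.path(config$out_dir, "sim")))
    reference <- sim$reference$unigenes
    raw_reads <- sim$sequenced$reads[, .(read_id, seq, qual)]
    barcodes <- sim$barcodes
    roles <- stats::setNames(sim$plants$role, sim$plants$plant)
    manifest$stages$simulate <- list(
      n_unigenes = length(reference),
      n_reads = nrow(raw_reads),
      n_junk = sum(sim$sequenced$reads$junk),
      n_ems_events = nrow(sim$truth$ems_events),
      n_homoeologous_sites = nrow(sim$truth$homoeo_sites),
      n_intervarietal_sites = nrow(sim$truth$intervarietal_sites))
  } else {
    reference <- stage("inputs", read_fasta_ref(config$reference))
    raw_reads <- stage("inputs", read_fastq(config$fastq))
    barcodes <- stage("inputs", read_barcode_table(config$barcodes))
    rt <- stage("inputs", data.table::fread(config$roles))
    roles <- stats::setNames(rt$role, rt[[1]])
  }

  dm <- stage("demux", demultiplex(raw_reads, barcodes))
  tr <- stage("demux", quality_filter_and_trim(dm, trim_len = config$trim_len))
  data.table::fwrite(prep_stats_table(tr$stats),
                     file.path(config$out_dir, "prep_stats.tsv"), sep = "\t")
  manifest$stages$demux <- as.list(prep_stats_table(tr$stats))

  idx <- stage("map", build_index(reference))
  aln <- stage("map", map_reads(tr$reads, idx))
  fs <- flagstat_summary(aln)
  stage("map", write_sam(aln, reference, file.path(config$out_dir, "aligned.sam")))
  manifest$stages$map <- list(total = fs$total, mapped = fs$mapped,
                              mapped_fraction = round(fs$mapped_fraction, 4))

  pile <- stage("call", pileup(sort_alignments(aln), reference))
  calls <- stage("call", genotype_sites(pile))
  stage("call", write_vcf(calls, file.path(config$out_dir, "calls.vcf")))
  manifest$stages$call <- list(candidate_sites = nrow(calls$sites),
                               dropped_alleles = calls$dropped_alleles)

  crit <- criteria_set(config$criteria)
  filt <- stage("classify", apply_site_filters(calls, crit))
  cls <- stage("classify", classify_variants(filt$calls, roles, crit))
  err <- if (any(roles == "wildtype"))
    stage("classify", estimate_error_rate(filt$calls, roles, crit)) else NULL
  data.table::fwrite(filt$tally, file.path(config$out_dir, "filter_tally.tsv"),
                     sep = "\t")
  data.table::fwrite(cls, file.path(config$out_dir, "classified.tsv"),
                     sep = "\t")
  stage("classify", write_classified_vcf(filt$calls, cls,
                                         file.path(config$out_dir,
                                                   "classified.vcf")))
  manifest$stages$classify <- list(
    retained = nrow(cls),
    by_category = as.list(table(cls$category)),
    error_rate_pct = if (!is.null(err) && !err$undefined)
      round(err$rate_pct, 2) else NA)

  per_plant <- stage("report", summarize_by_plant(
    cls, plants = names(roles)[roles == "mutant"]))
  data.table::fwrite(per_plant$table,
                     file.path(config$out_dir, "per_plant.tsv"), sep = "\t")
  manifest$stages$report <- per_plant$totals

  if (!is.null(sim)) {
    cmp <- stage("validate", compare_to_truth(cls, sim$truth,
                                              reference = reference,
                                              pile = pile))
    manifest$truth_comparison <- cmp[c("ems_recall", "ems_precision",
                                       "n_truth_at_retained_sites",
                                       "n_ems_called", "homoeologous_as_ems",
                                       "homoeologous_shared_as_ems")]
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Compare classified variants with simulator ground truth
#'
#' Matches classified EMS calls against planted EMS events on
#' (unigene, VCF position, carrier plant): SNPs at their own position,
#' deletions at the anchor base before the deleted run, insertions at
#' their anchor base. Also cross-tabulates the truth class of every
#' retained site against the called category.
#'
#' @param classified output of [classify_variants()]
#' @param truth simulator truth list (`ems_events`, `homoeo_sites`,
#'   `intervarietal_sites`)
#' @param reference optional named character vector; when given, planted
#'   indels are left-aligned (see [left_align_indels()]) before matching so
#'   representation differences do not count as errors
#' @param pile optional [pileup()] object; when given, planted homoeologous
#'   sites are additionally split by whether their alternate allele is
#'   visible in more than one plant's read pool (`homoeologous_shared_as_ems`
#'   -- the classifier's specificity property applies to these)
#' @return list with `ems_recall`, `ems_precision` (both among sites that
#'   passed the filters), `confusion` (truth class x called category),
#'   `homoeologous_as_ems` (any planted homoeologous site called EMS),
#'   `homoeologous_shared_as_ems`, counts, and matched/missed event tables
#' @export
compare_to_truth <- function(classified, truth, reference = NULL, pile = NULL) {
  need <- c("unigene", "pos", "category")
  if (!all(need %in% names(classified)))
    stopf("compare_to_truth: classification lacks %s",
          paste(setdiff(need, names(classified)), collapse = ","))
  ems <- data.table::copy(truth$ems_events)
  if (nrow(ems)) {
    ems[, vcf_pos := data.table::fcase(type == "SNP", pos,
                                       type == "DEL", pos - 1L,
                                       type == "INS", pos)]
    if (!is.null(reference)) {
      ii <- which(ems$type != "SNP")
      if (length(ii)) {
        norm <- left_align_indels(
          reference, ems$unigene[ii], ems$vcf_pos[ii],
          ifelse(ems$type[ii] == "INS", "I", "D"), ems$len[ii],
          ems$ins_seq[ii])
        data.table::set(ems, ii, "vcf_pos", norm$pos)
      }
    }
  } else {
    return(list(ems_recall = NA_real_, ems_precision = NA_real_,
                undefined = TRUE,
                confusion = NULL, homoeologous_as_ems = 0L,
                n_truth_at_retained_sites = 0L, n_ems_called = 0L))
  }

  cl <- data.table::copy(classified)
  # truth class per retained site
  cl[, truth_class := "none"]
  cl[truth$intervarietal_sites, on = c("unigene", "pos"),
     truth_class := "intervarietal"]
  cl[truth$homoeo_sites, on = c("unigene", "pos"), truth_class := "homoeologous"]
  cl[ems[, .(unigene, pos = vcf_pos)], on = c("unigene", "pos"),
     truth_class := "ems"]
  confusion <- cl[, .N, by = .(truth_class, category)]

  called_ems <- cl[category %in% c("EMS_SNP", "EMS_INDEL")]
  matched <- called_ems[ems, on = c(unigene = "unigene", pos = "vcf_pos",
                                    plant = "plant"), nomatch = NULL]
  truth_at_sites <- ems[unique(cl[, .(unigene, pos)]),
                        on = c(unigene = "unigene", vcf_pos = "pos"),
                        nomatch = NULL]
  recall <- if (nrow(truth_at_sites))
    nrow(matched) / nrow(truth_at_sites) else NA_real_
  precision <- if (nrow(called_ems))
    nrow(matched) / nrow(called_ems) else NA_real_
  homoeo_leaks <- cl[truth_class == "homoeologous" &
                       category %in% c("EMS_SNP", "EMS_INDEL")]
  shared_leaks <- NA_integer_
  if (!is.null(pile) && nrow(truth$homoeo_sites)) {
    # a homoeologous site is "shared" when its alternate allele is observed
    # in the read pools of more than one plant
    alt_vis <- pile$snv[truth$homoeo_sites[, .(unigene, pos, base = alt)],
                        on = c("unigene", "pos", "base"), nomatch = NULL]
    shared <- alt_vis[, .(n_plants = data.table::uniqueN(sample_id)),
                      by = .(unigene, pos)][n_plants >= 2L]
    shared_leaks <- nrow(homoeo_leaks[shared[, .(unigene, pos)],
                                      on = c("unigene", "pos"),
                                      nomatch = NULL])
  }
  list(ems_recall = recall,
       ems_precision = precision,
       confusion = confusion,
       homoeologous_as_ems = nrow(homoeo_leaks),
       homoeologous_shared_as_ems = shared_leaks,
       n_truth_at_retained_sites = nrow(truth_at_sites),
       n_ems_called = nrow(called_ems),
       matched = matched,
       missed = ems[!called_ems, on = c(unigene = "unigene", vcf_pos = "pos")])
}
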