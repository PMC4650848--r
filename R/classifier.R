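# Separating EMS-induced mutations from homoeologous and intervarietal
# sequence changes.
#
# In a polyploid aligned against a collapsed unigene reference, a fixed
# difference among homoeologous copies appears as a heterozygous call in
# EVERY sample, and a cultivar-vs-reference (intervarietal) difference
# appears homozygous-alternate in every sample. A genuine induced mutation
# is private: exactly one mutant plant deviates from an otherwise uniform
# genotype across the covered samples. Classification therefore needs no
# subgenome-resolved alignment at all -- only cross-sample genotype
# patterns plus quality filters.

#' Build a filtering/classification criteria set
#'
#' The `stringent` set is QUAL >= 30, DP >= 10, MQ >= 30, reads from more
#' than one sample, and carrier GQ >= 30; `redefined` relaxes only the
#' carrier GQ threshold to 20.
#'
#' @param name "stringent", "redefined" or "custom"
#' @param min_qual,min_dp,min_mq,min_samples_with_reads,ems_min_gq threshold
#'   overrides (used with `name = "custom"`)
#' @return a `criteria_set` list
#' @export
criteria_set <- function(name = c("stringent", "redefined", "custom"),
                         min_qual = 30, min_dp = 10, min_mq = 30,
                         min_samples_with_reads = 2, ems_min_gq = 30) {
  name <- match.arg(name)
  if (name == "stringent") ems_min_gq <- 30
  if (name == "redefined") ems_min_gq <- 20
  cr <- list(name = name, min_qual = min_qual, min_dp = min_dp,
             min_mq = min_mq,
             min_samples_with_reads = min_samples_with_reads,
             ems_min_gq = ems_min_gq)
  if (any(unlist(cr[-1]) < 0)) stopf("criteria_set: thresholds must be >= 0")
  class(cr) <- "criteria_set"
  cr
}

#' Apply sequential site-level filters
#'
#' Retains sites with QUAL >= min_qual, DP >= min_dp, MQ >= min_mq and at
#' least `min_samples_with_reads` samples with covering reads (all
#' thresholds inclusive), tallying the count removed at each sequential
#' step.
#'
#' @param calls a `variant_calls` object
#' @param criteria a [criteria_set()]
#' @return list with `calls` (retained subset, still a `variant_calls`) and
#'   `tally` (`data.table`: step, removed, remaining)
#' @export
apply_site_filters <- function(calls, criteria = criteria_set("stringent")) {
  stopifnot(inherits(calls, "variant_calls"), inherits(criteria, "criteria_set"))
  s <- calls$sites
  for (f in c("qual", "dp", "mq", "ns"))
    if (!f %in% names(s) || anyNA(s[[f]]))
      stopf("apply_site_filters: missing required field '%s'", toupper(f))
  steps <- list(
    qual = s$qual >= criteria$min_qual,
    dp = s$dp >= criteria$min_dp,
    mq = s$mq >= criteria$min_mq,
    ns = s$ns >= criteria$min_samples_with_reads)
  keep <- rep(TRUE, nrow(s))
  tally <- data.table::data.table(step = character(), removed = integer(),
                                  remaining = integer())
  for (nm in names(steps)) {
    removed <- sum(keep & !steps[[nm]])
    keep <- keep & steps[[nm]]
    tally <- rbind(tally, data.table::data.table(
      step = nm, removed = removed, remaining = sum(keep)))
  }
  kept_ids <- s$site_id[keep]
  out <- list(sites = s[keep],
              geno = calls$geno[site_id %in% kept_ids],
              samples = calls$samples,
              dropped_alleles = calls$dropped_alleles)
  class(out) <- "variant_calls"
  list(calls = out, tally = tally, input_sites = nrow(s))
}

normalize_roles <- function(roles, samples) {
  if (is.data.frame(roles)) {
    nm <- if ("plant" %in% names(roles)) "plant" else "sample"
    roles <- stats::setNames(roles$role, roles[[nm]])
  }
  missing <- setdiff(samples, names(roles))
  if (length(missing))
    stopf("classify_variants: no declared role for sample '%s'", missing[1])
  bad <- setdiff(unique(roles), c("mutant", "wildtype"))
  if (length(bad)) stopf("classify_variants: unknown role '%s'", bad[1])
  roles[samples]
}

#' Classify retained variants
#'
#' Classification precedence per site (covered samples only; `./.` samples
#' are ignored):
#' 1. intervarietal -- every covered sample is 1/1;
#' 2. singleton deviation -- exactly one covered sample carries a genotype
#'    different from the uniform genotype of all other covered samples
#'    (requires at least two uniform others), and, for an alternate-carrying
#'    deviator, no other sample's reads contain the alternate allele (a
#'    change present in more than one plant's reads is homoeologous by
#'    definition, whatever the genotypes say). A deviating mutant plant with
#'    GQ >= `ems_min_gq` yields an EMS call (heterozygous for 0/1, else
#'    homozygous, including the sole-0/0-among-1/1 case); a deviating
#'    wild-type plant is routed to error-rate accounting, never to EMS; a
#'    deviating mutant below the GQ threshold falls through;
#' 3. homoeologous -- the alternate allele is present in two or more
#'    samples' reads (or, lacking read-level AD information, carried as
#'    0/1 or 1/1 by two or more covered samples);
#' 4. otherwise filtered.
#'
#' @param calls retained `variant_calls` (see [apply_site_filters()])
#' @param roles named character vector or data.frame mapping every sample to
#'   "mutant" or "wildtype"
#' @param criteria a [criteria_set()]
#' @return `data.table` of classified variants: site fields plus `category`
#'   (EMS_SNP / EMS_INDEL / homoeologous / intervarietal / filtered),
#'   `plant` and `zygosity` (EMS only), `gq_dev` (deviator genotype
#'   quality) and `reason` for filtered records
#' @export
classify_variants <- function(calls, roles, criteria = criteria_set("stringent")) {
  stopifnot(inherits(calls, "variant_calls"))
  roles <- normalize_roles(roles, calls$samples)
  g <- data.table::copy(calls$geno)[gt != "./."]
  if (!"ad" %in% names(g)) g[, ad := NA_integer_]
  pat <- g[, {
    tab <- table(gt)
    n_cov <- .N
    # samples whose READS contain the alternate allele; genotype-level
    # fallback when AD is unavailable (external VCF without the field)
    n_alt <- if (all(is.na(ad))) sum(gt %in% c("0/1", "1/1"))
             else sum(ad >= 1L, na.rm = TRUE)
    all11 <- all(gt == "1/1")
    singleton <- length(tab) == 2L && sum(tab == 1L) == 1L && n_cov >= 3L
    dev_gt <- NA_character_; dev_sample <- NA_character_
    dev_gq <- NA_integer_; uni_gt <- NA_character_
    if (singleton) {
      dev_gt <- names(tab)[tab == 1L]
      uni_gt <- names(tab)[tab != 1L]
      i <- which(gt == dev_gt)
      dev_sample <- sample_id[i]
      dev_gq <- gq[i]
    }
    .(n_cov = n_cov, n_alt = n_alt, all11 = all11, singleton = singleton,
      dev_gt = dev_gt, dev_sample = dev_sample, dev_gq = dev_gq,
      uni_gt = uni_gt)
  }, by = site_id]

  v <- pat[calls$sites, on = "site_id"]
  v[is.na(n_cov), `:=`(n_cov = 0L, n_alt = 0L, all11 = FALSE,
                       singleton = FALSE)]
  v[, `:=`(category = NA_character_, plant = NA_character_,
           zygosity = NA_character_, gq_dev = NA_integer_,
           reason = NA_character_)]

  # 1. intervarietal
  v[n_cov > 0L & all11 == TRUE, category := "intervarietal"]

  # 2. singleton deviation
  sing <- is.na(v$category) & v$singleton &
    # the 0/0 singleton only counts against a uniformly 1/1 background
    (v$dev_gt != "0/0" | v$uni_gt == "1/1") &
    # an alternate-carrying deviator must be the ONLY sample whose reads
    # show the alternate allele; otherwise the change is homoeologous
    (v$dev_gt == "0/0" | v$n_alt <= 1L)
  dev_role <- roles[v$dev_sample]
  wt_dev <- sing & dev_role == "wildtype"
  v[wt_dev, `:=`(category = "filtered", reason = "wildtype_deviation",
                 plant = dev_sample, gq_dev = dev_gq)]
  ems <- sing & dev_role == "mutant" & !is.na(v$dev_gq) &
    v$dev_gq >= criteria$ems_min_gq
  v[ems, `:=`(category = ifelse(variant_type == "SNP", "EMS_SNP", "EMS_INDEL"),
              plant = dev_sample,
              zygosity = ifelse(dev_gt == "0/1", "het", "hom"),
              gq_dev = dev_gq)]

  # 3. homoeologous
  v[is.na(category) & n_alt >= 2L, category := "homoeologous"]

  # 4. remainder
  v[is.na(category), `:=`(category = "filtered", reason = "no_pattern")]

  out <- v[, .(site_id, unigene, pos, ref, alt, variant_type, qual, dp, ns,
               mq, category, plant, zygosity, gq_dev, reason)]
  data.table::setattr(out, "criteria", criteria)
  out[]
}

#' Write a classified VCF
#'
#' Re-emits the retained calls as VCF with the assigned category in INFO
#' key `CLASS` (and the carrier plant in `CARRIER` for EMS variants).
#'
#' @param calls the retained `variant_calls` that were classified
#' @param classified output of [classify_variants()] on those calls
#' @param path output path
#' @return `path`, invisibly
#' @export
write_classified_vcf <- function(calls, classified, path) {
  cls <- classified[data.table::data.table(site_id = calls$sites$site_id),
                    on = "site_id"]
  info <- paste0("CLASS=", cls$category,
                 ifelse(is.na(cls$plant), "", paste0(";CARRIER=", cls$plant)))
  write_vcf(calls, path, info_extra = info)
}

#' Estimate the EMS-calling error rate from wild-type plants
#'
#' Wild-type plants carry no induced mutations, so any site whose sole
#' deviating sample is a wild-type plant measures the false-mutation-calling
#' process. The denominator is the number of retained variants at which
#' wild-type reads are present; the numerator counts those where a
#' wild-type plant is the single deviator from an otherwise uniform
#' genotype.
#'
#' @param calls retained `variant_calls`
#' @param roles sample role mapping (see [classify_variants()])
#' @param criteria a [criteria_set()] (GQ is not applied to the wild-type
#'   deviator; any 0/0, 0/1 or 1/1 singleton counts)
#' @return list with `rate_pct`, `numerator`, `denominator`, `undefined`
#' @export
estimate_error_rate <- function(calls, roles,
                                criteria = criteria_set("stringent")) {
  stopifnot(inherits(calls, "variant_calls"))
  roles <- normalize_roles(roles, calls$samples)
  wt <- names(roles)[roles == "wildtype"]
  if (length(wt) == 0L)
    stopf("estimate_error_rate: no wild-type samples declared")
  g <- calls$geno[gt != "./."]
  denom_sites <- unique(g[sample_id %in% wt, site_id])
  cls <- classify_variants(calls, roles, criteria)
  num_sites <- cls[reason %in% "wildtype_deviation", site_id]
  denominator <- length(denom_sites)
  numerator <- length(intersect(num_sites, denom_sites))
  if (denominator == 0L)
    return(list(rate_pct = NA_real_, numerator = 0L, denominator = 0L,
                undefined = TRUE))
  list(rate_pct = 100 * numerator / denominator,
       numerator = numerator, denominator = denominator, undefined = FALSE)
}

#' Per-plant summary of EMS calls
#'
#' @param classified output of [classify_variants()]
#' @param plants optional character vector fixing the plant order (e.g. all
#'   mutant plants, so that plants with zero calls appear)
#' @return list with `table` (per plant: `ems_snps`, `ems_indels`,
#'   `unigenes_hit`) and `totals` (totals, means, min, max)
#' @export
summarize_by_plant <- function(classified, plants = NULL) {
  ems <- classified[category %in% c("EMS_SNP", "EMS_INDEL")]
  if (is.null(plants)) plants <- sort(unique(ems$plant))
  tab <- ems[, .(ems_snps = sum(category == "EMS_SNP"),
                 ems_indels = sum(category == "EMS_INDEL"),
                 unigenes_hit = data.table::uniqueN(unigene)),
             by = plant]
  grid <- data.table::data.table(plant = plants)
  tab <- tab[grid, on = "plant"]
  for (cn in c("ems_snps", "ems_indels", "unigenes_hit"))
    tab[is.na(get(cn)), (cn) := 0L]
  totals <- list(
    ems_snps = sum(tab$ems_snps), ems_indels = sum(tab$ems_indels),
    mean_snps = mean(tab$ems_snps), mean_indels = mean(tab$ems_indels),
    min_snps = min(tab$ems_snps), max_snps = max(tab$ems_snps),
    unigenes_hit_total = data.table::uniqueN(ems$unigene))
  list(table = tab[], totals = totals)
}
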