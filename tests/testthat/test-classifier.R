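samples7 <- c(paste0("M0", 1:5), "W01", "W02")
roles7 <- stats::setNames(c(rep("mutant", 5), rep("wildtype", 2)), samples7)
uniform <- function(gt) stats::setNames(rep(gt, 7), samples7)
with_dev <- function(dev_sample, dev_gt, others = "0/0") {
  g <- uniform(others); g[dev_sample] <- dev_gt; g
}

test_that("site filters are inclusive at their thresholds and tally sequentially", {
  calls <- make_calls(list(uniform("0/1"), uniform("0/1"), uniform("0/1"),
                           uniform("0/1")))
  calls$sites[1, qual := 29.9]
  calls$sites[2, `:=`(qual = 30, dp = 10L, mq = 30, ns = 2L)]
  calls$sites[3, mq := 29.5]
  calls$sites[4, dp := 9L]
  f <- apply_site_filters(calls, criteria_set("stringent"))
  expect_equal(f$tally$removed, c(1L, 1L, 1L, 0L))
  expect_equal(f$tally$remaining[4], 1L)
  expect_equal(f$calls$sites$site_id, 2L)
  expect_equal(sum(f$tally$removed) + nrow(f$calls$sites), f$input_sites)
})

test_that("missing required fields are reported by name", {
  calls <- make_calls(list(uniform("0/1")))
  calls$sites[, mq := NULL]
  expect_error(apply_site_filters(calls), "MQ")
})

test_that("cross-sample genotype patterns classify as the field logic dictates", {
  calls <- make_calls(list(
    uniform("0/1"),                       # 1 all het -> homoeologous
    uniform("1/1"),                       # 2 all hom-alt -> intervarietal
    with_dev("M03", "0/1"),               # 3 single mutant het -> EMS het
    with_dev("M02", "1/1"),               # 4 single mutant hom -> EMS hom
    with_dev("M04", "0/0", others = "1/1"), # 5 sole REF carrier -> EMS hom
    with_dev("W01", "0/1"),               # 6 wild-type deviator -> error acct
    with_dev("M01", "0/1", others = "./."), # 7 only one covered sample
    stats::setNames(c("0/1", "0/1", "0/0", "0/0", "0/0", "0/0", "0/0"),
                    samples7)))           # 8 two alt carriers -> homoeologous
  cls <- classify_variants(calls, roles7, criteria_set("stringent"))
  expect_equal(cls[order(site_id), category],
               c("homoeologous", "intervarietal", "EMS_SNP", "EMS_SNP",
                 "EMS_SNP", "filtered", "filtered", "homoeologous"))
  expect_equal(cls[site_id == 3, .(plant, zygosity)],
               data.table::data.table(plant = "M03", zygosity = "het"))
  expect_equal(cls[site_id == 4, zygosity], "hom")
  expect_equal(cls[site_id == 5, .(plant, zygosity)],
               data.table::data.table(plant = "M04", zygosity = "hom"))
  expect_equal(cls[site_id == 6, reason], "wildtype_deviation")
  # partition invariant: every retained site got exactly one category
  expect_equal(nrow(cls), nrow(calls$sites))
  expect_false(anyNA(cls$category))
})

test_that("EMS calls respect the carrier GQ threshold; relaxing it is monotone", {
  gts <- list(with_dev("M01", "0/1"), with_dev("M02", "0/1"),
              with_dev("M03", "1/1"))
  calls <- make_calls(gts, gq = 25L)
  strict <- classify_variants(calls, roles7, criteria_set("stringent"))
  relaxed <- classify_variants(calls, roles7, criteria_set("redefined"))
  expect_equal(sum(grepl("EMS", strict$category)), 0L)
  expect_equal(sum(grepl("EMS", relaxed$category)), 3L)

  # property: on random genotype tables the redefined criteria never call
  # fewer EMS variants than the stringent criteria
  set.seed(202)
  for (i in 1:20) {
    g <- lapply(1:15, function(j) {
      stats::setNames(sample(c("0/0", "0/1", "1/1", "./."), 7, replace = TRUE,
                             prob = c(.5, .25, .15, .1)), samples7)
    })
    rcalls <- make_calls(g, gq = sample(10:60, 1))
    n30 <- sum(grepl("EMS", classify_variants(
      rcalls, roles7, criteria_set("stringent"))$category))
    n20 <- sum(grepl("EMS", classify_variants(
      rcalls, roles7, criteria_set("redefined"))$category))
    expect_gte(n20, n30)
  }
})

test_that("a deviating wild-type plant is never classified EMS", {
  calls <- make_calls(list(with_dev("W02", "1/1"), with_dev("W01", "0/0",
                                                            others = "1/1")))
  cls <- classify_variants(calls, roles7, criteria_set("redefined"))
  expect_false(any(grepl("EMS", cls$category)))
  expect_equal(cls$reason, rep("wildtype_deviation", 2))
})

test_that("the wild-type error rate is numerator/denominator x 100", {
  gts <- c(
    list(with_dev("W01", "0/1")),            # wild-type sole deviator
    replicate(9, uniform("0/1"), simplify = FALSE), # homoeologous, WT covered
    # last site: wild types uncovered -> not in the denominator
    list(c(M01 = "0/1", M02 = "0/0", M03 = "0/0", M04 = "0/0", M05 = "0/0")))
  calls <- make_calls(gts)
  er <- estimate_error_rate(calls, roles7)
  expect_equal(er$denominator, 10L)
  expect_equal(er$numerator, 1L)
  expect_equal(er$rate_pct, 10)
  expect_false(er$undefined)
})

test_that("the error rate is flagged undefined without wild-type coverage", {
  gts <- list(stats::setNames(c("0/1", "0/1", "0/1", "0/1", "0/1", "./.", "./."),
                              samples7))
  calls <- make_calls(gts)
  er <- estimate_error_rate(calls, roles7)
  expect_true(er$undefined)
  expect_error(estimate_error_rate(calls, stats::setNames(
    rep("mutant", 7), samples7)), "wild-type")
})

test_that("per-plant summaries conserve totals and count unigenes hit", {
  calls <- make_calls(list(with_dev("M01", "0/1"), with_dev("M01", "0/1"),
                           with_dev("M02", "1/1")))
  # two M01 events in the same unigene
  calls$sites[2, unigene := calls$sites$unigene[1]]
  cls <- classify_variants(calls, roles7, criteria_set("stringent"))
  ps <- summarize_by_plant(cls, plants = paste0("M0", 1:5))
  tab <- ps$table
  expect_equal(tab[plant == "M01", .(ems_snps, unigenes_hit)],
               data.table::data.table(ems_snps = 2L, unigenes_hit = 1L))
  expect_equal(tab[plant == "M03", ems_snps], 0L)
  expect_equal(ps$totals$ems_snps, sum(tab$ems_snps))
  expect_equal(ps$totals$max_snps, 2L)
})

test_that("the classified VCF carries the category in INFO key CLASS", {
  calls <- make_calls(list(with_dev("M03", "0/1"), uniform("0/1"),
                           uniform("1/1")))
  cls <- classify_variants(calls, roles7, criteria_set("stringent"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_classified_vcf(calls, cls, path)
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  info <- vapply(strsplit(body, "\t"), `[[`, character(1), 8L)
  expect_true(grepl("CLASS=EMS_SNP;CARRIER=M03", info[1], fixed = TRUE))
  expect_true(grepl("CLASS=homoeologous", info[2], fixed = TRUE))
  expect_true(grepl("CLASS=intervarietal", info[3], fixed = TRUE))
  # still parseable by the plain VCF reader
  back <- read_vcf(path)
  expect_equal(nrow(back$sites), 3L)
})

test_that("classification partitions the retained sites of a simulated run", {
  sp <- small_pipeline()
  filt <- apply_site_filters(sp$calls, criteria_set("stringent"))
  roles <- stats::setNames(sp$sim$plants$role, sp$sim$plants$plant)
  cls <- classify_variants(filt$calls, roles, criteria_set("stringent"))
  expect_equal(nrow(cls), nrow(filt$calls$sites))
  expect_false(anyNA(cls$category))
  counts <- table(cls$category)
  expect_equal(sum(counts), nrow(filt$calls$sites))
  # monotonicity on real calls
  n30 <- sum(grepl("EMS", cls$category))
  cls20 <- classify_variants(filt$calls, roles, criteria_set("redefined"))
  expect_gte(sum(grepl("EMS", cls20$category)), n30)
})
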