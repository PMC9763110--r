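# Sample-outlier rules, within-data frequency, and CNV-level filters.

mk_metrics <- function(lrr = seq(0.10, 0.17, by = 0.01),
                       baf = 0.04 + (0:7) / 1000,
                       wav = 0.03 + (0:7) / 1000,
                       cnv = c(1L, 2L, 3L, 2L, 3L, 1L, 2L, 4L),
                       kb = seq(100, 240, by = 20),
                       chrom_frac = 0.01 + (0:7) / 200,
                       cohort = "c1") {
  n <- length(lrr)
  data.table(sample_id = sprintf("S%02d", seq_len(n)), cohort_id = cohort,
             lrr_sd = lrr, baf_sd = baf, waviness = wav,
             cnv_count = cnv, kb_burden = kb, max_chrom_frac = chrom_frac,
             miss_ok = TRUE, het_ok = TRUE, sex_ok = TRUE, rel_ok = TRUE)
}

test_that("Q3 + 3*IQR cutoff uses type-7 quantiles within cohort", {
  # {1..7, 100}: Q1 = 2.75, Q3 = 6.25, IQR = 3.5, cutoff = 16.75
  m <- mk_metrics(lrr = c(1:7, 100))
  fl <- flag_sample_outliers(m)
  expect_equal(fl[pass == FALSE, sample_id], "S08")
  expect_match(fl[sample_id == "S08", reason], "lrr_sd_outlier")
  # cohorts are judged separately: the same values split across two cohorts
  m2 <- rbind(mk_metrics(lrr = c(1:7, 100), cohort = "c1"),
              mk_metrics(lrr = c(90:96, 100), cohort = "c2"))
  fl2 <- flag_sample_outliers(m2)
  expect_equal(fl2[pass == FALSE, .N], 1L)
})

test_that("each outlier metric, aneuploidy and genotype flags fail samples", {
  m <- mk_metrics(cnv = c(1L, 2L, 3L, 2L, 3L, 1L, 2L, 60L),
                  kb = c(100, 120, 140, 110, 130, 150, 100, 9000))
  fl <- flag_sample_outliers(m)
  expect_match(fl[sample_id == "S08", reason], "cnv_count_outlier")
  expect_match(fl[sample_id == "S08", reason], "kb_burden_outlier")

  m <- mk_metrics(chrom_frac = c(0.01 + (0:6) / 200, 0.25))
  fl <- flag_sample_outliers(m)
  expect_match(fl[sample_id == "S08", reason], "aneuploidy")

  m <- mk_metrics()
  m[3, het_ok := FALSE]
  fl <- flag_sample_outliers(m)
  expect_equal(fl[pass == FALSE, sample_id], "S03")
  expect_match(fl[sample_id == "S03", reason], "genotype_qc")
})

test_that("degenerate all-identical metrics fail everyone under >=", {
  # IQR = 0 collapses the cutoff to Q3; every sample sits at Q3
  fl <- flag_sample_outliers(mk_metrics(lrr = rep(0.1, 8)))
  expect_true(all(!fl$pass))
  expect_true(all(grepl("lrr_sd_outlier", fl$reason)))
  # with ordinary variation nobody is flagged
  expect_true(all(flag_sample_outliers(mk_metrics())$pass))
})

test_that("outlier flagging is invariant to sample order and needs >= 4 samples", {
  m <- mk_metrics(lrr = c(1:7, 100))
  perm <- m[sample.int(8)]
  fl1 <- flag_sample_outliers(m)
  fl2 <- flag_sample_outliers(perm)
  expect_equal(fl1[order(sample_id)], fl2[order(sample_id)])
  expect_error(flag_sample_outliers(m[1:3]), ">= 4 samples")
})

test_that("within-data frequency counts distinct samples per overlap cluster", {
  calls <- rbind(
    mk_calls(1000, 21000, sample_id = "S1"),
    mk_calls(1500, 21500, sample_id = "S2"),
    mk_calls(900, 20500, sample_id = "S3"),
    mk_calls(60000, 70000, sample_id = "S4")
  )
  fr <- cnv_frequency(calls, n_samples = 200)
  expect_equal(fr[start == 1000, freq], 3 / 200)   # 1.5% cluster
  expect_equal(fr[start == 60000, freq], 1 / 200)  # 0.5% singleton
  expect_error(cnv_frequency(calls, n_samples = 0), "positive")
})

test_that("40% reciprocal overlap does not cluster; same type required", {
  # [0,10000) vs [6000,16000): overlap 4000 = 40% of both
  calls <- rbind(mk_calls(0, 10000, sample_id = "S1"),
                 mk_calls(6000, 16000, sample_id = "S2"))
  fr <- cnv_frequency(calls, n_samples = 100)
  expect_equal(sort(fr$freq), c(0.01, 0.01))
  expect_equal(length(unique(fr$cluster)), 2L)
  # identical intervals but opposite types stay apart
  calls2 <- rbind(mk_calls(0, 10000, sample_id = "S1", type = "DEL"),
                  mk_calls(0, 10000, sample_id = "S2", type = "DUP"))
  fr2 <- cnv_frequency(calls2, n_samples = 100)
  expect_equal(length(unique(fr2$cluster)), 2L)
  # transitive chains merge through the middle call
  calls3 <- rbind(mk_calls(0, 10000, sample_id = "S1"),
                  mk_calls(4000, 14000, sample_id = "S2"),
                  mk_calls(8000, 18000, sample_id = "S3"))
  fr3 <- cnv_frequency(calls3, n_samples = 100)
  expect_equal(length(unique(fr3$cluster)), 1L)
  expect_equal(fr3$freq, rep(0.03, 3))
})

mk_annotation <- function() {
  list(
    chrom_lengths = c(chr1 = 100000L),
    special = data.table(chrom = "chr1", start = 90000L, end = 95000L,
                         label = "centromere"),
    segdups = data.table(chrom = "chr1", start = 0L, end = 10001L,
                         label = "segdup")
  )
}

test_that("CNV filters are independent OR'd exclusions with boundary behaviour", {
  ann <- mk_annotation()
  calls <- rbind(
    mk_calls(0, 20000),      # segdup covers 10001/20000 = 50.005% > 50% -> out
    mk_calls(30000, 39999),  # 9999 bp < 10 kb -> out
    mk_calls(50000, 60000),  # clean: 10 kb, 10 probes
    mk_calls(70000, 80000)   # clean but high frequency (planted below)
  )
  calls[, n_probes := c(20L, 20L, 10L, 10L)]
  calls[, freq := c(0.005, 0.005, 0.009, 0.02)]
  res <- filter_cnvs(calls, ann)
  expect_equal(res$calls$start, 50000L)
  rep <- res$report
  expect_equal(rep[start == 0, reason], "segdup")
  expect_equal(rep[start == 30000, reason], "min_length")
  expect_equal(rep[start == 70000, reason], "frequency")
  # exactly-50% segdup coverage is retained (strict >)
  half <- mk_calls(0, 20002)[, `:=`(n_probes = 20L, freq = 0.001)]
  expect_true(filter_cnvs(half, ann)$report$pass)
  # special regions use >= 50%
  spec_half <- mk_calls(85000, 95000)[, `:=`(n_probes = 10L, freq = 0.001)]
  expect_false(filter_cnvs(spec_half, ann)$report$pass)
  expect_equal(filter_cnvs(spec_half, ann)$report$reason, "special_region")
  # fewer than 10 probes removed
  few <- mk_calls(50000, 60000)[, `:=`(n_probes = 9L, freq = 0.001)]
  expect_equal(filter_cnvs(few, ann)$report$reason, "min_probes")
  expect_error(filter_cnvs(
    mk_calls(0, 20000, chrom = "chr9")[, `:=`(n_probes = 5L, freq = 0)], ann),
    "chr9")
})

test_that("reason accounting partitions inputs and keeps all reasons", {
  ann <- mk_annotation()
  set.seed(5)
  n <- 50
  s <- sample.int(80000L, n)
  calls <- mk_calls(s, pmin(100000L, s + sample(2000:30000, n, TRUE)))
  calls[, `:=`(n_probes = sample(c(5L, 20L), n, TRUE),
               freq = sample(c(0.005, 0.05), n, TRUE))]
  res <- filter_cnvs(calls, ann)
  rep <- res$report
  expect_equal(nrow(res$calls) + sum(rep$reason != ""), n)
  multi <- rep[grepl(";", reasons)]
  if (nrow(multi)) {
    expect_true(all(mapply(function(r, rs) startsWith(rs, r),
                           multi$reason, multi$reasons)))
  }
  # coverage fractions match the per-bp oracle
  for (i in seq_len(nrow(rep))) {
    expect_equal(rep$special_frac[i],
                 oracle_fraction(ann$special$start, ann$special$end,
                                 rep$start[i], rep$end[i], 100000L))
  }
})

test_that("tightening any single threshold is monotone", {
  ann <- mk_annotation()
  set.seed(6)
  n <- 80
  s <- sample.int(80000L, n)
  calls <- mk_calls(s, pmin(100000L, s + sample(2000:30000, n, TRUE)))
  calls[, `:=`(n_probes = sample(3:30, n, TRUE),
               freq = runif(n, 0, 0.03))]
  base <- nrow(filter_cnvs(calls, ann, filter_config())$calls)
  tighter <- list(
    filter_config(min_length_bp = 20000),
    filter_config(min_probes = 20),
    filter_config(max_frequency = 0.005),
    filter_config(special_region_overlap = 0.25),
    filter_config(segdup_overlap = 0.25)
  )
  for (cfg in tighter) {
    expect_lte(nrow(filter_cnvs(calls, ann, cfg)$calls), base)
  }
})
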