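# Burden encodings: spans, NDD overlap fractions, carrier rules, gene and
# gene-set indicators.

mk_regions <- function() {
  data.table(label = c("R_DEL", "R_DUP"), chrom = "chr1",
             start = c(40000L, 70000L), end = c(50000L, 80000L),
             type = c("DEL", "DUP"))
}

test_that("genome span sums call lengths by type and NDD partition", {
  subs <- data.table(sample_id = c("S1", "S2"))
  calls <- rbind(
    mk_calls(0, 100000, sample_id = "S1", type = "DEL"),     # 0.1 Mb, non-NDD
    mk_calls(200000, 450000, sample_id = "S1", type = "DUP") # 0.25 Mb, non-NDD
  )
  regions <- data.table(label = "R", chrom = "chr1", start = 600000L,
                        end = 700000L, type = "DEL")
  sp <- genome_span(calls, regions, subs)
  s1 <- sp[sample_id == "S1"]
  expect_equal(s1$span_total_mb, 0.35)
  expect_equal(s1$span_del_mb, 0.10)
  expect_equal(s1$span_dup_mb, 0.25)
  expect_equal(s1$cnv_count, 2)
  expect_equal(s1$mean_cnv_length_mb, 0.175)
  # subject with no calls is retained with zero burden
  s2 <- sp[sample_id == "S2"]
  expect_equal(s2$span_total_mb, 0)
  expect_equal(s2$cnv_count, 0)
  # NDD partition: a call overlapping a matching-type region by >= 1 bp
  calls2 <- rbind(
    mk_calls(599999, 650000, sample_id = "S1", type = "DEL"),  # 1 bp overlap
    mk_calls(600000, 650000, sample_id = "S2", type = "DUP")   # type mismatch
  )
  sp2 <- genome_span(calls2, regions, subs)
  expect_equal(sp2[sample_id == "S1", span_ndd_del_mb], 50001 / 1e6)
  expect_equal(sp2[sample_id == "S1", span_nonndd_del_mb], 0)
  expect_equal(sp2[sample_id == "S2", span_ndd_dup_mb], 0)
  expect_equal(sp2[sample_id == "S2", span_nonndd_dup_mb], 0.05)
})

test_that("span partitions sum to per-type totals on random fixtures", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    s <- as.integer(sort(sample(seq(0, 90000, by = 3000), n)))
    e <- pmin(100000L, s + sample(500:2500, n, TRUE))
    calls <- mk_calls(s, e, type = sample(c("DEL", "DUP"), n, TRUE))
    sp <- genome_span(calls, mk_regions(), data.table(sample_id = "S1"))
    expect_equal(sp$span_total_mb, sp$span_del_mb + sp$span_dup_mb)
    expect_equal(sp$span_del_mb, sp$span_ndd_del_mb + sp$span_nonndd_del_mb)
    expect_equal(sp$span_dup_mb, sp$span_ndd_dup_mb + sp$span_nonndd_dup_mb)
    # spans match the per-bp coverage oracle (calls are non-overlapping)
    for (tp in c("DEL", "DUP")) {
      m <- bp_mask(calls[type == tp, start], calls[type == tp, end], 100000L)
      expect_equal(sp[[paste0("span_", tolower(tp), "_mb")]], sum(m) / 1e6)
    }
  }
})

test_that("overlapping same-type calls within a subject are rejected", {
  calls <- rbind(mk_calls(0, 10000), mk_calls(5000, 15000))
  expect_error(genome_span(calls, mk_regions(), data.table(sample_id = "S1")),
               "overlapping")
})

test_that("NDD overlap fraction is the union coverage of the region", {
  region <- list(chrom = "chr1", start = 40000L, end = 50000L, type = "DEL")
  # two fragments covering 80% of the region
  calls <- rbind(mk_calls(40000, 44000), mk_calls(46000, 50000))
  fr <- ndd_overlap_fraction(calls, region)
  expect_equal(fr$fraction, 0.8)
  # no overlapping call
  expect_equal(nrow(ndd_overlap_fraction(mk_calls(0, 1000), region)), 0L)
  # single containing call
  expect_equal(ndd_overlap_fraction(mk_calls(30000, 60000), region)$fraction, 1)
  # required type is respected
  expect_equal(nrow(ndd_overlap_fraction(mk_calls(40000, 50000, type = "DUP"),
                                         region)), 0L)
  # random fixtures match the per-bp oracle
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(1:5, 1)
    s <- as.integer(sort(sample(seq(30000, 58000, by = 2000), n)))
    e <- pmin(100000L, s + sample(500:1900, n, TRUE))
    calls <- mk_calls(s, e)
    fr <- ndd_overlap_fraction(calls, region)
    orc <- oracle_fraction(s, e, 40000L, 50000L, 100000L)
    expect_equal(if (nrow(fr)) fr$fraction else 0, orc)
  }
})

test_that("carrier rules behave at their boundaries and are monotone", {
  expect_equal(carrier_status(0.8, "gt0"), 1L)
  expect_equal(carrier_status(0.8, "ge50"), 1L)
  expect_equal(carrier_status(0.8, "eq100"), 0L)
  expect_equal(carrier_status(0.5, "ge50"), 1L)   # "at least 50%"
  expect_equal(carrier_status(0.499, "ge50"), 0L)
  expect_equal(carrier_status(0, "gt0"), 0L)
  expect_equal(carrier_status(1, "eq100"), 1L)
  # 1 bp tolerance on a 10 kb region
  expect_equal(carrier_status(0.99995, "eq100", tol = 1e-4), 1L)
  for (f in runif(50)) {
    g <- carrier_status(f, "gt0")
    m <- carrier_status(f, "ge50")
    e <- carrier_status(f, "eq100")
    expect_true(e <= m && m <= g)
  }
})

test_that("ndd_carriers emits monotone flags for all subjects and regions", {
  subs <- data.table(sample_id = c("S1", "S2", "S3"))
  calls <- rbind(
    mk_calls(40000, 50000, sample_id = "S1"),            # full carrier
    mk_calls(40000, 45000, sample_id = "S2"),            # 50% carrier
    mk_calls(49999, 60000, sample_id = "S3")             # 1 bp: gt0 only
  )
  cr <- ndd_carriers(calls, mk_regions(), subs)
  expect_equal(cr[sample_id == "S1", carrier_R_DEL_eq100], 1L)
  expect_equal(cr[sample_id == "S2",
                  .(carrier_R_DEL_gt0, carrier_R_DEL_ge50, carrier_R_DEL_eq100)],
               data.table(carrier_R_DEL_gt0 = 1L, carrier_R_DEL_ge50 = 1L,
                          carrier_R_DEL_eq100 = 0L))
  expect_equal(cr[sample_id == "S3", carrier_R_DEL_gt0], 1L)
  expect_equal(cr[sample_id == "S3", carrier_R_DEL_ge50], 0L)
  expect_equal(cr$carrier_R_DUP_gt0, rep(0L, 3))
  rules <- c("gt0", "ge50", "eq100")
  for (lab in mk_regions()$label) {
    flags <- as.matrix(cr[, paste0("carrier_", lab, "_", rules), with = FALSE])
    expect_true(all(flags[, 3] <= flags[, 2] & flags[, 2] <= flags[, 1]))
  }
})

test_that("gene indicators use >= 1 bp overlap on collapsed spans", {
  genes <- data.table(symbol = c("G1", "G2"), chrom = "chr1",
                      start = c(500L, 5000L), end = c(1000L, 6000L),
                      protein_coding = c(TRUE, TRUE))
  # 1 bp overlap counts
  hits <- gene_burden(mk_calls(999, 2000), genes)
  expect_equal(hits[stratum == "all", symbol], "G1")
  # half-open abutting does not
  expect_equal(nrow(gene_burden(mk_calls(1000, 2000), genes)), 0L)
  # strata are type-specific
  calls <- rbind(mk_calls(400, 1100, type = "DEL"),
                 mk_calls(4000, 7000, type = "DUP"))
  hits <- gene_burden(calls, genes)
  expect_equal(sort(hits[stratum == "all", symbol]), c("G1", "G2"))
  expect_equal(hits[stratum == "DEL", symbol], "G1")
  expect_equal(hits[stratum == "DUP", symbol], "G2")
  # non-coding genes never enter
  genes2 <- copy(genes)[symbol == "G1", protein_coding := FALSE]
  expect_equal(gene_burden(mk_calls(400, 1100), genes2)[stratum == "all", symbol],
               character(0))
})

test_that("gene indicators match the exhaustive scan and are extension-monotone", {
  set.seed(13)
  genes <- data.table(symbol = sprintf("G%02d", 1:15), chrom = "chr1",
                      start = as.integer(seq(2000, 86000, by = 6000)),
                      end = as.integer(seq(2000, 86000, by = 6000) +
                                         sample(500:4000, 15, TRUE)),
                      protein_coding = TRUE)
  for (rep in 1:30) {
    n <- sample(1:6, 1)
    s <- as.integer(sample(seq(0, 95000, by = 500), n))
    e <- pmin(100000L, s + sample(200:9000, n, TRUE))
    o <- order(s)
    s <- s[o]; e <- e[o]
    keep <- c(TRUE, s[-1] > cummax(e)[-n])
    calls <- mk_calls(s[keep], e[keep])
    hits <- gene_burden(calls, genes)[stratum == "all", symbol]
    orc <- genes$symbol[oracle_gene_hits(calls, genes)]
    expect_equal(sort(hits), sort(orc))
    # enlarging a call never un-hits a gene (extend the rightmost call)
    calls2 <- copy(calls)
    calls2[nrow(calls2), end := pmin(100000L, end + 3000L)]
    hits2 <- gene_burden(calls2, genes)[stratum == "all", symbol]
    expect_true(all(hits %in% hits2))
  }
})

test_that("gene-set counts sum member indicators", {
  subs <- data.table(sample_id = c("S1", "S2"))
  hits <- data.table(sample_id = c("S1", "S1", "S1"),
                     symbol = c("g1", "g3", "g9"), stratum = "all")
  sets <- data.table(set_name = c("A", "A", "A", "B"),
                     gene = c("g1", "g2", "g3", "g7"), category = "neuro")
  gs <- geneset_burden(hits, sets, subs, stratum = "all")
  expect_equal(gs[sample_id == "S1", geneset_A_all], 2L)
  expect_equal(gs[sample_id == "S1", geneset_B_all], 0L)
  expect_equal(gs[sample_id == "S2", geneset_A_all], 0L)
  # singleton sets sum to the total genes hit
  singles <- data.table(set_name = c("s1", "s3", "s9"),
                        gene = c("g1", "g3", "g9"), category = "x")
  gs1 <- geneset_burden(hits, singles, subs, stratum = "all")
  tot <- rowSums(as.matrix(gs1[, -1]))
  expect_equal(tot[1], 3)
  # counts never exceed set size
  expect_lte(max(gs$geneset_A_all), 3L)
})
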