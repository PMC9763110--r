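# Sample-level outlier exclusion and CNV-level filtering of the consensus
# callset. Outlier cutoffs are Q3 + 3*IQR computed within cohort with
# type-7 (linear interpolation) quantiles; CNV filters are independent,
# OR-combined exclusions.

#' CNV filter configuration
#'
#' @param iqr_multiplier Multiplier `m` in the `Q3 + m*IQR` sample-outlier
#'   rule.
#' @param aneuploidy_fraction A sample fails if more than this fraction of
#'   any chromosome is copy-number variant.
#' @param special_region_overlap A CNV is removed when at least this fraction
#'   of it is covered by centromere/telomere/Ig/TCR loci (`>=`).
#' @param segdup_overlap A CNV is removed when more than this fraction of it
#'   is covered by segmental duplications (strict `>`).
#' @param max_frequency A CNV is removed when its within-data frequency
#'   exceeds this (strict `>`).
#' @param min_length_bp Minimum CNV length in bp.
#' @param min_probes Minimum probe count.
#' @param freq_reciprocal Reciprocal-overlap fraction used to cluster calls
#'   for the frequency computation (`>=`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(iqr_multiplier = 3,
                          aneuploidy_fraction = 0.20,
                          special_region_overlap = 0.50,
                          segdup_overlap = 0.50,
                          max_frequency = 0.01,
                          min_length_bp = 10000L,
                          min_probes = 10L,
                          freq_reciprocal = 0.50) {
  cfg <- list(iqr_multiplier = iqr_multiplier,
              aneuploidy_fraction = aneuploidy_fraction,
              special_region_overlap = special_region_overlap,
              segdup_overlap = segdup_overlap,
              max_frequency = max_frequency,
              min_length_bp = as.integer(min_length_bp),
              min_probes = as.integer(min_probes),
              freq_reciprocal = freq_reciprocal)
  stopifnot(cfg$iqr_multiplier > 0, cfg$min_length_bp > 0, cfg$min_probes > 0)
  fr <- c(cfg$aneuploidy_fraction, cfg$special_region_overlap,
          cfg$segdup_overlap, cfg$max_frequency, cfg$freq_reciprocal)
  if (any(fr <= 0 | fr > 1)) stop("filter fractions must lie in (0, 1]")
  class(cfg) <- "filter_config"
  cfg
}

#' Assemble per-sample QC metrics from consensus calls and array metrics
#'
#' Adds CNV count, kb burden, and the per-chromosome fraction of sequence
#' covered by CNV (maximum over chromosomes retained as `max_chrom_frac`) to
#' the caller-derived array-quality metrics.
#'
#' @param calls Consensus call table.
#' @param array_metrics Table with `sample_id`, `cohort_id`, `lrr_sd`,
#'   `baf_sd`, `waviness` and logical genotype-QC flags `miss_ok`, `het_ok`,
#'   `sex_ok`, `rel_ok`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return `data.table`, one row per sample in `array_metrics`.
#' @export
sample_qc_metrics <- function(calls, array_metrics, chrom_lengths) {
  calls <- check_calls(calls)
  m <- copy(as.data.table(array_metrics))
  per_sample <- calls[, .(cnv_count = .N,
                          kb_burden = sum(as.numeric(end - start)) / 1e3),
                      by = sample_id]
  cov <- reduce_intervals(calls[, .(sample_id, chrom, start, end)],
                          by = c("sample_id", "chrom"))
  chrom_frac <- cov[, .(frac = sum(as.numeric(end - start)) /
                          as.numeric(chrom_lengths[chrom[1L]])),
                    by = .(sample_id, chrom)]
  max_frac <- chrom_frac[, .(max_chrom_frac = max(frac)), by = sample_id]
  m <- per_sample[m, on = "sample_id"]
  m <- max_frac[m, on = "sample_id"]
  m[is.na(cnv_count), cnv_count := 0L]
  m[is.na(kb_burden), kb_burden := 0]
  m[is.na(max_chrom_frac), max_chrom_frac := 0]
  attr(m, "chrom_frac") <- chrom_frac
  m[]
}

q3_iqr_cutoff <- function(x, multiplier) {
  qs <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  qs[2L] + multiplier * (qs[2L] - qs[1L])
}

#' Flag sample-level outliers
#'
#' For each of `lrr_sd`, `baf_sd`, `waviness`, `cnv_count` and `kb_burden`, a
#' sample is failed when its value is `>= Q3 + 3*IQR`, computed within its
#' cohort (type-7 quantiles). Samples with more than `aneuploidy_fraction` of
#' any chromosome covered by CNV fail the aneuploidy rule, and samples with
#' any genotype-QC flag `FALSE` fail genotype QC. With a degenerate
#' within-cohort distribution (IQR = 0) the cutoff collapses to Q3 and every
#' sample at Q3 fails under `>=`.
#'
#' @param metrics Output of [sample_qc_metrics()].
#' @param config A [filter_config()].
#' @return `data.table` with `sample_id`, `cohort_id`, `pass` and a
#'   semicolon-separated `reason` string for failing samples.
#' @export
flag_sample_outliers <- function(metrics, config = filter_config()) {
  m <- as.data.table(metrics)
  need <- c("sample_id", "cohort_id", "lrr_sd", "baf_sd", "waviness",
            "cnv_count", "kb_burden", "max_chrom_frac")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("metrics table missing columns: ", paste(miss, collapse = ", "))
  small <- m[, .N, by = cohort_id][N < 4L]
  if (nrow(small)) {
    stop("quartile outlier rules need >= 4 samples per cohort; offending cohort(s): ",
         paste(small$cohort_id, collapse = ", "))
  }
  outlier_metrics <- c("lrr_sd", "baf_sd", "waviness", "cnv_count", "kb_burden")
  reasons <- vector("list", nrow(m))
  for (met in outlier_metrics) {
    cut <- m[, .(cutoff = q3_iqr_cutoff(.SD[[met]], config$iqr_multiplier)),
             by = cohort_id, .SDcols = met]
    cutv <- cut$cutoff[match(m$cohort_id, cut$cohort_id)]
    fail <- m[[met]] >= cutv
    for (i in which(fail)) reasons[[i]] <- c(reasons[[i]], paste0(met, "_outlier"))
  }
  fail_aneu <- m$max_chrom_frac > config$aneuploidy_fraction
  for (i in which(fail_aneu)) reasons[[i]] <- c(reasons[[i]], "aneuploidy")
  flags <- intersect(c("miss_ok", "het_ok", "sex_ok", "rel_ok"), names(m))
  if (length(flags)) {
    geno_fail <- rowSums(!as.matrix(m[, flags, with = FALSE])) > 0L
    for (i in which(geno_fail)) reasons[[i]] <- c(reasons[[i]], "genotype_qc")
  }
  data.table(
    sample_id = m$sample_id,
    cohort_id = m$cohort_id,
    pass = vapply(reasons, is.null, logical(1)),
    reason = vapply(reasons, function(r) paste(r, collapse = ";"), character(1))
  )
}

#' Within-data CNV frequency by reciprocal-overlap clustering
#'
#' Calls are clustered by same type and at least `freq_reciprocal` (default
#' 50 percent) reciprocal overlap, taking connected components of the
#' pairwise overlap graph across all samples; the frequency of a call is the
#' number of distinct samples represented in its cluster divided by the total
#' sample count.
#'
#' @param calls Consensus call table over all samples.
#' @param n_samples Total number of samples in the analysis set.
#' @param config A [filter_config()].
#' @return `data.table` of `calls` with added `cluster` and `freq` columns.
#' @export
cnv_frequency <- function(calls, n_samples, config = filter_config()) {
  calls <- check_calls(calls)
  if (n_samples <= 0L) stop("n_samples must be positive")
  out <- copy(calls)
  if (nrow(out) == 0L) {
    out[, `:=`(cluster = integer(), freq = numeric())]
    return(out[])
  }
  ov <- overlap_pairs(out, out, on = "chrom")
  ov <- ov[xid < yid & out$type[xid] == out$type[yid]]
  if (nrow(ov)) {
    len_x <- (out$end - out$start)[ov$xid]
    len_y <- (out$end - out$start)[ov$yid]
    ov <- ov[ov_bp / len_x >= config$freq_reciprocal &
               ov_bp / len_y >= config$freq_reciprocal]
  }
  comp <- union_find(nrow(out), ov$xid, ov$yid)
  out[, cluster := comp]
  cl_freq <- out[, .(freq = uniqueN(sample_id) / n_samples), by = cluster]
  out[cl_freq, freq := i.freq, on = "cluster"]
  out[]
}

#' Apply CNV-level filters
#'
#' A CNV is removed if any of the following independent criteria holds:
#' at least 50 percent of it is covered by centromere/telomere/Ig/TCR loci;
#' more than 50 percent is covered by segmental duplications; its within-data
#' frequency exceeds 1 percent; it is shorter than 10 kb; or it intersects
#' fewer than 10 probes (all thresholds configurable).
#'
#' @param calls Call table with `freq` and `n_probes` columns (see
#'   [cnv_frequency()]).
#' @param annotation Annotation bundle with `special`, `segdups` and
#'   `chrom_lengths`.
#' @param config A [filter_config()].
#' @return List with surviving `calls` and a `report` carrying one row per
#'   input CNV (`pass`, first-listed `reason`, all `reasons`).
#' @export
filter_cnvs <- function(calls, annotation, config = filter_config()) {
  calls <- check_calls(calls, need = c("sample_id", "chrom", "start", "end",
                                       "type", "n_probes", "freq"))
  unknown <- setdiff(unique(calls$chrom), names(annotation$chrom_lengths))
  if (length(unknown)) {
    stop("CNV on chromosome absent from annotation: ",
         paste(unknown, collapse = ", "))
  }
  n <- nrow(calls)
  spec_frac <- coverage_fraction(calls, annotation$special)
  segdup_frac <- coverage_fraction(calls, annotation$segdups)
  crit <- list(
    special_region = spec_frac >= config$special_region_overlap,
    segdup = segdup_frac > config$segdup_overlap,
    frequency = calls$freq > config$max_frequency,
    min_length = (calls$end - calls$start) < config$min_length_bp,
    min_probes = calls$n_probes < config$min_probes
  )
  reason_mat <- do.call(cbind, crit)
  all_reasons <- apply(reason_mat, 1L, function(r) {
    paste(names(crit)[r], collapse = ";")
  })
  primary <- apply(reason_mat, 1L, function(r) {
    if (any(r)) names(crit)[which(r)[1L]] else ""
  })
  pass <- !apply(reason_mat, 1L, any)
  report <- copy(calls)
  report[, `:=`(pass = pass, reason = primary, reasons = all_reasons,
                special_frac = spec_frac, segdup_frac = segdup_frac)]
  list(calls = calls[pass], report = report[])
}

#' Run the full QC stage
#'
#' Chains [sample_qc_metrics()], [flag_sample_outliers()], [cnv_frequency()]
#' (computed on the post-consensus, pre-filter callset of samples passing
#' sample QC) and [filter_cnvs()].
#'
#' @param calls Consensus call table.
#' @param array_metrics See [sample_qc_metrics()].
#' @param annotation Annotation bundle.
#' @param config A [filter_config()].
#' @return List with `calls` (post-QC), `sample_flags`, `cnv_report`,
#'   `metrics` and a `counts` summary.
#' @export
qc_pipeline <- function(calls, array_metrics, annotation,
                        config = filter_config()) {
  metrics <- sample_qc_metrics(calls, array_metrics, annotation$chrom_lengths)
  sample_flags <- flag_sample_outliers(metrics, config)
  keep <- sample_flags[pass == TRUE, sample_id]
  calls_kept <- calls[sample_id %in% keep]
  calls_freq <- cnv_frequency(calls_kept, n_samples = length(keep), config)
  filt <- filter_cnvs(calls_freq, annotation, config)
  list(
    calls = filt$calls,
    sample_flags = sample_flags,
    cnv_report = filt$report,
    metrics = metrics,
    counts = c(
      input_cnvs = nrow(calls),
      input_samples = nrow(sample_flags),
      samples_pass = length(keep),
      cnvs_after_sample_qc = nrow(calls_kept),
      cnvs_pass = nrow(filt$calls)
    )
  )
}
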