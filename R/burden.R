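# Per-subject CNV burden encodings at the four analysed scales:
# genome-wide span (Mb), NDD-region span and carrier status, gene-level
# indicators, and gene-set counts. All subjects in the analysis set are
# retained, zero-burden subjects included.

#' Genome-wide CNV span burden
#'
#' Sums post-QC call lengths per subject into total, per-type, and NDD /
#' non-NDD partitioned spans (megabases), plus CNV count and mean CNV length.
#' A call counts toward the NDD partition when it overlaps any NDD region of
#' matching type by at least 1 bp; a call is never split between partitions.
#' Overlapping same-type calls within a subject violate the annealing
#' postcondition and are rejected.
#'
#' @param calls Post-QC call table.
#' @param ndd_regions `data.table(label, chrom, start, end, type)`.
#' @param subjects Subject frame (`sample_id`); zero-burden subjects get all
#'   zero spans.
#' @return `data.table`, one row per subject: `span_total_mb`, `span_del_mb`,
#'   `span_dup_mb`, `span_ndd_del_mb`, `span_ndd_dup_mb`,
#'   `span_nonndd_del_mb`, `span_nonndd_dup_mb`, `cnv_count`,
#'   `mean_cnv_length_mb`.
#' @export
genome_span <- function(calls, ndd_regions, subjects) {
  calls <- check_calls(calls)
  subjects <- as.data.table(subjects)
  if (nrow(calls)) {
    chk <- copy(calls)
    setorder(chk, sample_id, chrom, type, start)
    bad <- chk[, .(V1 = if (.N < 2L) FALSE else
                     any(start[-1L] < cummax(end)[-.N])),
               by = .(sample_id, chrom, type)][V1 == TRUE]
    if (nrow(bad)) {
      stop("overlapping same-type calls within subject(s): ",
           paste(unique(bad$sample_id), collapse = ", "))
    }
  }
  out <- copy(calls)
  out[, is_ndd := FALSE]
  nr <- as.data.table(ndd_regions)
  if (nrow(out) && nrow(nr)) {
    ov <- overlap_pairs(out, nr, on = "chrom")
    ov <- ov[out$type[xid] == nr$type[yid]]
    if (nrow(ov)) out[unique(ov$xid), is_ndd := TRUE]
  }
  out[, len_mb := as.numeric(end - start) / 1e6]
  agg <- out[, .(
    span_total_mb = sum(len_mb),
    span_del_mb = sum(len_mb[type == "DEL"]),
    span_dup_mb = sum(len_mb[type == "DUP"]),
    span_ndd_del_mb = sum(len_mb[type == "DEL" & is_ndd]),
    span_ndd_dup_mb = sum(len_mb[type == "DUP" & is_ndd]),
    span_nonndd_del_mb = sum(len_mb[type == "DEL" & !is_ndd]),
    span_nonndd_dup_mb = sum(len_mb[type == "DUP" & !is_ndd]),
    cnv_count = .N,
    mean_cnv_length_mb = mean(len_mb)
  ), by = sample_id]
  res <- agg[subjects[, .(sample_id)], on = "sample_id"]
  for (j in setdiff(names(res), "sample_id")) {
    set(res, which(is.na(res[[j]])), j, 0)
  }
  res[]
}

#' Fraction of an NDD region covered by a subject's CNVs
#'
#' The covered fraction is computed from the union of each subject's calls of
#' the region's required type, so a fragmented carrier is still recognised.
#'
#' @param calls Post-QC call table.
#' @param region One-row `data.table` (or list) with `chrom`, `start`, `end`,
#'   `type`.
#' @return `data.table(sample_id, fraction)` for every subject with at least
#'   one call (subjects without calls of the required type get fraction 0 via
#'   [ndd_carriers()]).
#' @export
ndd_overlap_fraction <- function(calls, region) {
  calls <- check_calls(calls)
  region <- as.data.table(as.list(region)[c("chrom", "start", "end", "type")])
  rel <- calls[chrom == region$chrom & type == region$type &
                 start < region$end & end > region$start]
  if (nrow(rel) == 0L) {
    return(data.table(sample_id = character(), fraction = numeric()))
  }
  rel[, `:=`(start = pmax(start, region$start), end = pmin(end, region$end))]
  u <- reduce_intervals(rel[, .(sample_id, chrom, start, end)],
                        by = c("sample_id", "chrom"))
  u[, .(fraction = sum(as.numeric(end - start)) /
          as.numeric(region$end - region$start)), by = sample_id]
}

#' Carrier status from an overlap fraction
#'
#' Three overlap rules are supported: `gt0` (any overlap), `ge50` (at least
#' half the region covered) and `eq100` (complete coverage, judged with a
#' 1 bp tolerance via `tol`).
#'
#' @param fraction Numeric overlap fraction(s) in [0, 1].
#' @param rule One of `"gt0"`, `"ge50"`, `"eq100"`.
#' @param tol Fractional tolerance for the `eq100` rule (pass
#'   `1 / region_length_bp` for a 1 bp tolerance).
#' @return Integer 0/1 vector.
#' @export
carrier_status <- function(fraction, rule = c("gt0", "ge50", "eq100"), tol = 0) {
  rule <- match.arg(rule)
  stopifnot(all(fraction >= 0 & fraction <= 1 + 1e-12))
  as.integer(switch(rule,
    gt0 = fraction > 0,
    ge50 = fraction >= 0.5,
    eq100 = fraction >= 1 - tol
  ))
}

#' NDD carrier flags for all subjects, regions and overlap rules
#'
#' @param calls Post-QC call table.
#' @param ndd_regions Region table (`label`, `chrom`, `start`, `end`, `type`).
#' @param subjects Subject frame.
#' @param rules Overlap rules to evaluate.
#' @return Wide `data.table`: one row per subject, columns
#'   `carrier_<label>_<rule>` plus `frac_<label>`.
#' @export
ndd_carriers <- function(calls, ndd_regions, subjects,
                         rules = c("gt0", "ge50", "eq100")) {
  nr <- as.data.table(ndd_regions)
  subjects <- as.data.table(subjects)
  out <- subjects[, .(sample_id)]
  for (i in seq_len(nrow(nr))) {
    fr <- ndd_overlap_fraction(calls, nr[i])
    v <- fr$fraction[match(out$sample_id, fr$sample_id)]
    v[is.na(v)] <- 0
    out[, paste0("frac_", nr$label[i]) := v]
    tol <- 1 / as.numeric(nr$end[i] - nr$start[i])
    for (r in rules) {
      out[, paste0("carrier_", nr$label[i], "_", r) :=
            carrier_status(v, r, tol = tol)]
    }
  }
  out[]
}

#' Gene-level CNV indicators
#'
#' A gene is hit when any call overlaps its collapsed span by at least 1 bp.
#' Indicators are computed for three strata: all CNVs, deletions only,
#' duplications only. Only protein-coding genes enter the burden.
#'
#' @param calls Post-QC call table.
#' @param genes Gene table from [collapse_isoforms()] (needs `symbol`,
#'   `chrom`, `start`, `end`, `protein_coding`).
#' @return Long `data.table(sample_id, symbol, stratum)`; one row per
#'   (subject, gene, stratum) hit.
#' @export
gene_burden <- function(calls, genes) {
  calls <- check_calls(calls)
  g <- as.data.table(genes)
  if ("protein_coding" %in% names(g)) g <- g[protein_coding == TRUE]
  empty <- data.table(sample_id = character(), symbol = character(),
                      stratum = character())
  if (nrow(calls) == 0L || nrow(g) == 0L) return(empty)
  ov <- overlap_pairs(calls, g, on = "chrom")
  if (nrow(ov) == 0L) return(empty)
  hits <- data.table(
    sample_id = calls$sample_id[ov$xid],
    symbol = g$symbol[ov$yid],
    type = calls$type[ov$xid]
  )
  all_h <- unique(hits[, .(sample_id, symbol)])[, stratum := "all"]
  del_h <- unique(hits[type == "DEL", .(sample_id, symbol)])[, stratum := "DEL"]
  dup_h <- unique(hits[type == "DUP", .(sample_id, symbol)])[, stratum := "DUP"]
  rbindlist(list(all_h, del_h, dup_h))
}

#' Gene-set burden counts
#'
#' For each subject and gene-set, the number of set member genes overlapped
#' by the subject's CNVs (within a stratum). Set members that do not resolve
#' to a known gene are ignored.
#'
#' @param gene_hits Output of [gene_burden()].
#' @param genesets `data.table(set_name, gene, category)`.
#' @param subjects Subject frame.
#' @param stratum One of `"all"`, `"DEL"`, `"DUP"`.
#' @return Wide `data.table`: one row per subject, one count column
#'   `geneset_<set>_<stratum>` per set.
#' @export
geneset_burden <- function(gene_hits, genesets, subjects, stratum = "all") {
  gs <- as.data.table(genesets)
  subjects <- as.data.table(subjects)
  target <- stratum
  hits <- as.data.table(gene_hits)
  hits <- hits[hits[["stratum"]] == target]
  out <- subjects[, .(sample_id)]
  for (s in unique(gs$set_name)) {
    members <- gs[set_name == s, gene]
    cnt <- hits[symbol %in% members, .N, by = sample_id]
    v <- cnt$N[match(out$sample_id, cnt$sample_id)]
    v[is.na(v)] <- 0L
    out[, paste0("geneset_", s, "_", stratum) := as.integer(v)]
  }
  out[]
}

#' Full per-subject burden profile
#'
#' Combines genome-wide spans, NDD carrier flags, gene indicators and
#' gene-set counts into one wide subject-by-feature table (genes are returned
#' separately in long form, since the gene family can be large).
#'
#' @param calls Post-QC call table.
#' @param annotation Annotation bundle (`ndd_regions`, `genes`, `genesets`).
#' @param subjects Subject frame.
#' @param geneset_strata Strata for which gene-set counts are computed.
#' @return List with `profile` (wide table) and `gene_hits` (long table).
#' @export
burden_profile <- function(calls, annotation, subjects,
                           geneset_strata = c("all", "DEL", "DUP")) {
  spans <- genome_span(calls, annotation$ndd_regions, subjects)
  carriers <- ndd_carriers(calls, annotation$ndd_regions, subjects)
  gene_hits <- gene_burden(calls, annotation$genes)
  prof <- carriers[spans, on = "sample_id"]
  for (st in geneset_strata) {
    gsb <- geneset_burden(gene_hits, annotation$genesets, subjects, stratum = st)
    prof <- gsb[prof, on = "sample_id"]
  }
  list(profile = prof[], gene_hits = gene_hits)
}
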