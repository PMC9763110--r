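# Dual-caller consensus: gain/loss conflict exclusion, interval
# intersection of same-type calls, and annealing of fragmented calls.
# All operations are batched across samples; calls are only ever paired
# within (sample_id, chrom).

#' Remove cross-caller gain/loss conflicts
#'
#' A call from one caller and a call from the other with *opposite* type and
#' more than 50 percent reciprocal overlap are judged to describe the same
#' locus with contradictory dosage; both members are removed before
#' intersection.
#'
#' @param a,b Call tables from the two callers (one caller each).
#' @param reciprocal Reciprocal-overlap fraction that must be *exceeded* by
#'   both members for a pair to count as a conflict (default 0.5).
#' @return List with cleaned `a`, `b` and a `conflicts` table of removed
#'   pairs.
#' @export
resolve_type_conflicts <- function(a, b, reciprocal = 0.5) {
  a <- check_calls(a)
  b <- check_calls(b)
  check_two_callsets(a, b)
  empty_report <- data.table(
    sample_id = character(), chrom = character(),
    a_start = integer(), a_end = integer(), a_type = character(),
    b_start = integer(), b_end = integer(), b_type = character(),
    ov_bp = integer()
  )
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(list(a = a, b = b, conflicts = empty_report))
  }
  ov <- overlap_pairs(a, b, on = "chrom")
  if (nrow(ov) == 0L) return(list(a = a, b = b, conflicts = empty_report))
  ov[, `:=`(
    same_sample = a$sample_id[xid] == b$sample_id[yid],
    opposite = a$type[xid] != b$type[yid],
    frac_a = ov_bp / (a$end[xid] - a$start[xid]),
    frac_b = ov_bp / (b$end[yid] - b$start[yid])
  )]
  confl <- ov[same_sample & opposite & frac_a > reciprocal & frac_b > reciprocal]
  if (nrow(confl) == 0L) return(list(a = a, b = b, conflicts = empty_report))
  report <- data.table(
    sample_id = a$sample_id[confl$xid], chrom = a$chrom[confl$xid],
    a_start = a$start[confl$xid], a_end = a$end[confl$xid],
    a_type = a$type[confl$xid],
    b_start = b$start[confl$yid], b_end = b$end[confl$yid],
    b_type = b$type[confl$yid],
    ov_bp = confl$ov_bp
  )
  keep_a <- setdiff(seq_len(nrow(a)), confl$xid)
  keep_b <- setdiff(seq_len(nrow(b)), confl$yid)
  list(a = a[keep_a], b = b[keep_b], conflicts = report)
}

#' Intersect two callers' callsets into consensus calls
#'
#' For every same-sample, same-chromosome, same-type pair of calls with at
#' least 1 bp of overlap, the intersection interval is emitted; overlapping
#' or abutting intersections are merged, so the result equals the maximal
#' runs of bases covered by both callers with agreeing type. Probe counts
#' are recomputed over the consensus intervals from the probe map. Calls
#' without a same-type partner in the other callset contribute nothing.
#'
#' @param a,b Call tables from the two callers (one caller each).
#' @param probes Probe map `data.table(chrom, pos)`.
#' @return Consensus call table with `callers` naming both callers.
#' @export
consensus_intersect <- function(a, b, probes) {
  a <- check_calls(a)
  b <- check_calls(b)
  check_two_callsets(a, b)
  empty <- data.table(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(), type = character(),
                      n_probes = integer(), callers = character())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  caller_a <- if ("caller" %in% names(a)) a$caller[1L] else "a"
  caller_b <- if ("caller" %in% names(b)) b$caller[1L] else "b"
  callers <- paste(sort(c(caller_a, caller_b)), collapse = ",")
  ov <- overlap_pairs(a, b, on = "chrom")
  if (nrow(ov) == 0L) return(empty)
  ov <- ov[a$sample_id[xid] == b$sample_id[yid] & a$type[xid] == b$type[yid]]
  if (nrow(ov) == 0L) return(empty)
  pieces <- data.table(
    sample_id = a$sample_id[ov$xid],
    chrom = a$chrom[ov$xid],
    start = pmax(a$start[ov$xid], b$start[ov$yid]),
    end = pmin(a$end[ov$xid], b$end[ov$yid]),
    type = a$type[ov$xid]
  )
  cons <- reduce_intervals(pieces, by = c("sample_id", "chrom", "type"))
  cons[, `:=`(n_probes = count_probes(cons, probes), callers = callers)]
  setorder(cons, sample_id, chrom, start)
  setcolorder(cons, c("sample_id", "chrom", "start", "end", "type",
                      "n_probes", "callers"))
  cons[]
}

check_two_callsets <- function(a, b) {
  if ("caller" %in% names(a) && nrow(a) && length(unique(a$caller)) > 1L) {
    stop("callset 'a' mixes calls from more than one caller")
  }
  if ("caller" %in% names(b) && nrow(b) && length(unique(b$caller)) > 1L) {
    stop("callset 'b' mixes calls from more than one caller")
  }
  invisible(NULL)
}

# Greedy left-to-right merge of sorted intervals: adjacent calls merge when
# gap / merged span < max_gap_frac; repeated until a fixed point.
anneal_group <- function(s, e, max_gap_frac) {
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(s)) {
      gap <- s[i + 1L] - e[i]
      span <- e[i + 1L] - s[i]
      if (gap / span < max_gap_frac) {
        e[i] <- max(e[i], e[i + 1L])
        s <- s[-(i + 1L)]
        e <- e[-(i + 1L)]
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  list(s, e)
}

#' Anneal fragmented CNV calls
#'
#' Within each sample/chromosome/type, adjacent calls are merged when the gap
#' between them is less than `max_gap_frac` (default 30 percent) of the
#' overall length of the annealed CNV; merging proceeds left-to-right and is
#' repeated until no further pair qualifies. Output calls are non-overlapping
#' within sample/chromosome/type and probe counts are recounted over the
#' merged spans.
#'
#' @param calls Call table (typically the consensus set).
#' @param probes Probe map `data.table(chrom, pos)`; if `NULL`, probe counts
#'   are dropped.
#' @param max_gap_frac Gap fraction threshold (strict `<`).
#' @return Annealed call table.
#' @export
anneal_fragments <- function(calls, probes = NULL, max_gap_frac = 0.30) {
  calls <- check_calls(calls)
  if (nrow(calls) == 0L) return(calls)
  extra <- setdiff(names(calls), c("sample_id", "chrom", "start", "end", "type"))
  keep_callers <- "callers" %in% names(calls)
  callers_val <- if (keep_callers) calls$callers[1L] else NULL
  setorder(calls, sample_id, chrom, type, start)
  out <- calls[, {
    if (.N == 1L) {
      list(start = start, end = end)
    } else {
      r <- anneal_group(start, end, max_gap_frac)
      list(start = r[[1L]], end = r[[2L]])
    }
  }, by = .(sample_id, chrom, type)]
  if (!is.null(probes)) out[, n_probes := count_probes(out, probes)]
  if (keep_callers) out[, callers := callers_val]
  setorder(out, sample_id, chrom, start)
  setcolorder(out, intersect(c("sample_id", "chrom", "start", "end", "type",
                               "n_probes", "callers"), names(out)))
  out[]
}

#' Run the full consensus stage
#'
#' Applies gain/loss conflict exclusion, intersects the two callsets, and
#' anneals fragmented consensus calls.
#'
#' @inheritParams consensus_intersect
#' @param reciprocal Conflict reciprocal-overlap threshold.
#' @param max_gap_frac Annealing gap-fraction threshold.
#' @return List with `calls` (final consensus), `conflicts`, and a `counts`
#'   record of input/removed/emitted call numbers.
#' @export
consensus_pipeline <- function(a, b, probes, reciprocal = 0.5,
                               max_gap_frac = 0.30) {
  res <- resolve_type_conflicts(a, b, reciprocal = reciprocal)
  cons <- consensus_intersect(res$a, res$b, probes)
  ann <- anneal_fragments(cons, probes = probes, max_gap_frac = max_gap_frac)
  list(
    calls = ann,
    conflicts = res$conflicts,
    counts = c(
      input_a = nrow(as.data.table(a)), input_b = nrow(as.data.table(b)),
      conflict_pairs = nrow(res$conflicts),
      consensus = nrow(cons), annealed = nrow(ann)
    )
  )
}
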