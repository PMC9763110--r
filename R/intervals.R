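# Low-level interval arithmetic on 0-based half-open [start, end) integer
# coordinates. All user-facing coordinate conversion happens in io.R; every
# function in the package assumes half-open internally.

#' @import data.table
#' @importFrom stats lm glm binomial coef vcov pnorm pt quantile rnorm rbinom
#'   rpois runif setNames var sd complete.cases anova as.formula hatvalues
#'   p.adjust predict qnorm
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".I", ".N", ".SD", ".grp", ".y", "start", "end", "chrom", "type",
  "sample_id", "caller", "n_probes", "conf", "truth_id", "is_false", "qid",
  "ov_bp", "xid", "yid", "xs", "xe", "ys", "ye", "cs", "ce", "i.cs", "i.ce",
  "cluster", "freq", "i.freq", "len", "pos", "reason", "reasons", "pass",
  "cohort_id", "term", "beta", "se", "p", "q", "z", "k", "family",
  "estimable", "label", "fraction", "gene", "symbol", "protein_coding",
  "set_name", "category", "cutoff", "assessment_min", "assessment_max",
  "phenotype_raw", "cohort_type", "lrr_sd", "prs", "kb_burden", "cnv_count",
  "max_chrom_frac", "cnv_id", "accession", "stratum", "mean_cnv_length_mb",
  "frac", "gene_n", "gene_hit", "is_ndd", "is_ndd_event", "len_mb",
  "same_sample", "opposite", "frac_a", "frac_b", "violation", "state",
  "true_ndd_del_mb", "special_frac", "segdup_frac", "N", "V1", "too_close"
))

# Merge overlapping or abutting intervals within groups (coverage-mask union).
reduce_intervals <- function(dt, by = c("sample_id", "chrom", "type")) {
  dt <- as.data.table(dt)
  if (nrow(dt) == 0L) return(dt[, c(by, "start", "end"), with = FALSE])
  out <- copy(dt)
  setorderv(out, c(by, "start", "end"))
  out[, .grp := {
    prev_end <- shift(cummax(as.numeric(end)), fill = NA)
    cumsum(is.na(prev_end) | start > prev_end)
  }, by = by]
  res <- out[, .(start = min(start), end = max(end)), by = c(by, ".grp")]
  res[, .grp := NULL]
  res[]
}

# All >=1 bp overlapping pairs between two interval tables, matched on `on`
# (always including chrom). Returns row indices into x and y plus overlap bp.
overlap_pairs <- function(x, y, on = "chrom") {
  x <- as.data.table(x)
  y <- as.data.table(y)
  if (nrow(x) == 0L || nrow(y) == 0L) {
    return(data.table(xid = integer(), yid = integer(), ov_bp = integer()))
  }
  x2 <- x[, c(on, "start", "end"), with = FALSE]
  x2[, `:=`(xid = .I, cs = start, ce = end - 1L)]
  setnames(x2, c("start", "end"), c("xs", "xe"))
  y2 <- y[, c(on, "start", "end"), with = FALSE]
  y2[, `:=`(yid = .I, cs = start, ce = end - 1L)]
  setnames(y2, c("start", "end"), c("ys", "ye"))
  setkeyv(y2, c(on, "cs", "ce"))
  ov <- foverlaps(x2, y2, by.x = c(on, "cs", "ce"), type = "any", nomatch = NULL)
  ov[, .(xid, yid, ov_bp = as.integer(pmin(xe, ye) - pmax(xs, ys)))]
}

# Fraction of each query interval covered by the union of track intervals.
coverage_fraction <- function(query, track) {
  query <- as.data.table(query)
  if (nrow(query) == 0L) return(numeric(0))
  frac <- numeric(nrow(query))
  track <- as.data.table(track)
  if (nrow(track) == 0L) return(frac)
  tr <- reduce_intervals(track[, .(chrom, start, end)], by = "chrom")
  ov <- overlap_pairs(query, tr)
  if (nrow(ov)) {
    agg <- ov[, .(covered = sum(as.numeric(ov_bp))), by = xid]
    frac[agg$xid] <- agg$covered / (as.numeric(query$end) - query$start)[agg$xid]
  }
  frac
}

# Count probes with position in [start, end); probes: data.table(chrom, pos).
count_probes <- function(dt, probes) {
  dt <- as.data.table(dt)
  if (nrow(dt) == 0L) return(integer(0))
  p <- as.data.table(probes)
  setorder(p, chrom, pos)
  res <- integer(nrow(dt))
  for (ch in unique(dt$chrom)) {
    idx <- which(dt$chrom == ch)
    ppos <- p[chrom == ch, pos]
    if (length(ppos) == 0L) next
    res[idx] <- findInterval(dt$end[idx] - 1L, ppos) -
      findInterval(dt$start[idx] - 1L, ppos)
  }
  res
}

# Union-find over integer node ids 1..n given an edge table; returns component id.
union_find <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(edges_i)) {
    ri <- find(edges_i[e])
    rj <- find(edges_j[e])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

# Validate a call table's minimal column contract.
check_calls <- function(calls, need = c("sample_id", "chrom", "start", "end", "type")) {
  calls <- as.data.table(calls)
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop("call table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(calls) && any(calls$start >= calls$end)) {
    stop("call table contains intervals with start >= end")
  }
  if (nrow(calls) && !all(calls$type %in% c("DEL", "DUP"))) {
    stop("cnv type must be 'DEL' or 'DUP'")
  }
  calls
}
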