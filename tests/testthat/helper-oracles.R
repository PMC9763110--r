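# Shared fixture builders and independent brute-force oracles. The oracles
# deliberately use per-basepair masks or exhaustive scans rather than the
# package's interval arithmetic.

library(data.table)

mk_calls <- function(start, end, type = "DEL", sample_id = "S1",
                     chrom = "chr1", caller = "a", n_probes = NA_integer_) {
  data.table(sample_id = sample_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             type = type, n_probes = as.integer(n_probes), caller = caller,
             conf = NA_real_)
}

toy_probes <- function(genome_len = 100000L, spacing = 1000L,
                       chrom = "chr1") {
  data.table(chrom = chrom, pos = seq.int(0L, genome_len - 1L, by = spacing))
}

# Per-basepair coverage mask of half-open intervals on a toy chromosome.
bp_mask <- function(starts, ends, genome_len) {
  mask <- logical(genome_len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) mask[(starts[i] + 1L):ends[i]] <- TRUE
  }
  mask
}

# Maximal runs of TRUE in a mask, as half-open intervals.
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.table(start = starts[r$values], end = ends[r$values])
}

# Oracle consensus: per-bp AND of same-type coverage, segmented into runs.
oracle_consensus <- function(a, b, genome_len) {
  out <- list()
  for (tp in c("DEL", "DUP")) {
    ma <- bp_mask(a[type == tp, start], a[type == tp, end], genome_len)
    mb <- bp_mask(b[type == tp, start], b[type == tp, end], genome_len)
    runs <- mask_runs(ma & mb)
    if (nrow(runs)) out[[tp]] <- runs[, .(start, end, type = tp)]
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    return(data.table(start = integer(), end = integer(), type = character()))
  }
  setorder(res, start)
  res[]
}

# Oracle annealing: exhaustively re-merge the closest qualifying pair until
# none qualifies (independent of the left-to-right greedy implementation;
# both must reach the same fixed point on sorted non-overlapping input).
oracle_anneal <- function(starts, ends, max_gap_frac = 0.30) {
  repeat {
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    n <- length(starts)
    if (n < 2L) break
    gap <- starts[-1L] - ends[-n]
    span <- ends[-1L] - starts[-n]
    ok <- which(gap / span < max_gap_frac)
    if (!length(ok)) break
    i <- ok[1L]
    ends[i] <- ends[i + 1L]
    starts <- starts[-(i + 1L)]; ends <- ends[-(i + 1L)]
  }
  data.table(start = starts, end = ends)
}

# Oracle coverage fraction of a region by the union of intervals.
oracle_fraction <- function(starts, ends, region_start, region_end, genome_len) {
  m <- bp_mask(starts, ends, genome_len)
  idx <- (region_start + 1L):region_end
  sum(m[idx]) / (region_end - region_start)
}

# Oracle gene indicator: exhaustive O(n*m) scan for >= 1 bp overlap.
oracle_gene_hits <- function(calls, genes) {
  hit <- matrix(FALSE, nrow = nrow(genes), ncol = 1)
  sapply(seq_len(nrow(genes)), function(j) {
    any(calls$chrom == genes$chrom[j] &
          calls$start < genes$end[j] & calls$end > genes$start[j])
  })
}

# Oracle BH step-up q-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Oracle HC3 sandwich from the definitional formula.
oracle_hc3_se <- function(X, y, term_col) {
  XtX_inv <- solve(crossprod(X))
  bhat <- XtX_inv %*% crossprod(X, y)
  e <- as.numeric(y - X %*% bhat)
  h <- diag(X %*% XtX_inv %*% t(X))
  meat <- t(X) %*% diag(e^2 / (1 - h)^2) %*% X
  V <- XtX_inv %*% meat %*% XtX_inv
  sqrt(diag(V))[term_col]
}

# Small single-cohort analysis table for model tests.
mk_cohort_data <- function(n = 200, seed = 1, cohort_type = "score",
                           beta_x = 0, noise_sd = 0.1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.2) * runif(n, 0.1, 2)
  pcs <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("PC", 1:5)))
  lrr <- pmax(0.02, rnorm(n, 0.12, 0.02))
  latent <- pmin(1, pmax(0, 0.4 + beta_x * x + rnorm(n, 0, noise_sd)))
  dat <- data.table(
    sample_id = sprintf("S%04d", seq_len(n)),
    cohort_id = "c1",
    cohort_type = cohort_type,
    assessment_min = if (cohort_type == "score") 17L else NA_integer_,
    assessment_max = if (cohort_type == "score") 85L else NA_integer_,
    phenotype_raw = if (cohort_type == "score") {
      round(17 + latent * 68)
    } else {
      as.numeric(latent >= 0.45)
    },
    x = x, lrr_sd = lrr, prs = rnorm(n)
  )
  for (j in colnames(pcs)) dat[, (j) := pcs[, j]]
  dat
}
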