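# Fixed-effects inverse-variance-weighted meta-analysis across cohorts and
# Benjamini-Hochberg FDR control within test families.

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Combines cohort estimates of one term with weights `w_i = 1/se_i^2`:
#' `beta = sum(w*b)/sum(w)`, `se = 1/sqrt(sum(w))`, `z = beta/se`, two-sided
#' normal p-value.
#'
#' @param beta Cohort effect estimates on a common scale.
#' @param se Cohort standard errors (all positive).
#' @return One-row `data.table(beta, se, z, p, k)`.
#' @export
ivw_meta <- function(beta, se) {
  if (length(beta) == 0L) stop("no estimates to combine")
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  if (any(!is.finite(se)) || any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  data.table(beta = b, se = s, z = z, p = 2 * pnorm(-abs(z)),
             k = length(beta))
}

#' Meta-analyse odds ratios on the log scale
#'
#' IVW combination of per-cohort log odds ratios (from ordinal or logistic
#' fits, not rescaled), reported as an odds ratio with a 95 percent CI.
#'
#' @param log_or Cohort log odds ratios.
#' @param se Their standard errors.
#' @return One-row `data.table(or, ci_lo, ci_hi, log_or, se, z, p, k)`.
#' @export
meta_or <- function(log_or, se) {
  m <- ivw_meta(log_or, se)
  data.table(or = exp(m$beta),
             ci_lo = exp(m$beta - qnorm(0.975) * m$se),
             ci_hi = exp(m$beta + qnorm(0.975) * m$se),
             log_or = m$beta, se = m$se, z = m$z, p = m$p, k = m$k)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment within one family of tests:
#' `q(i) = min_{j: p(j) >= p(i)} m * p(j) / rank(j)`, capped at 1.
#'
#' @param p P-values in (0, 1].
#' @return Q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Meta-analyse a table of cohort results and control FDR within families
#'
#' Groups per-cohort association results by term, drops inestimable rows,
#' IVW-combines the remainder, and computes BH q-values within each test
#' family. Terms with no estimable cohort are reported with `k = 0` and no
#' estimate.
#'
#' @param results Stacked output of [cohort_associations()], optionally with
#'   a `family` column (one q-value family per distinct value); a single
#'   family is assumed otherwise.
#' @return `data.table(term, family, k, beta, se, z, p, q)`.
#' @export
meta_analyze <- function(results) {
  res <- as.data.table(results)
  if (!"family" %in% names(res)) res[, family := "default"]
  out <- res[, {
    est <- .SD[estimable == TRUE]
    if (nrow(est) == 0L) {
      data.table(k = 0L, beta = NA_real_, se = NA_real_, z = NA_real_,
                 p = NA_real_)
    } else {
      m <- ivw_meta(est$beta, est$se)
      data.table(k = m$k, beta = m$beta, se = m$se, z = m$z, p = m$p)
    }
  }, by = .(term, family)]
  out[, q := NA_real_]
  out[!is.na(p), q := bh_fdr(p), by = family]
  out[]
}
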