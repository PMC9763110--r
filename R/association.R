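# Per-cohort regression of the (rescaled) phenotype on burden terms.
# Score cohorts are analysed with linear regression on the 0-1 rescaled
# symptom score; case/control cohorts with logistic regression, whose
# log-odds estimates enter the meta-analysis directly under the
# censored-latent-variable interpretation. Covariates are the five genotype
# principal components plus the log-R-ratio SD array-quality metric.

default_covariates <- function() c(paste0("PC", 1:5), "lrr_sd")

#' Rescale a raw symptom score to the unit interval
#'
#' Maps a raw instrument score to `(raw - min) / (max - min)` using the
#' instrument's *theoretical* range, so 0 means no symptoms and 1 the
#' theoretical maximum.
#'
#' @param raw Numeric raw scores.
#' @param assessment_min,assessment_max Theoretical instrument bounds.
#' @param sample_id Optional ids used in error messages.
#' @return Numeric vector in [0, 1].
#' @export
rescale_phenotype <- function(raw, assessment_min, assessment_max,
                              sample_id = NULL) {
  if (any(assessment_min >= assessment_max)) {
    stop("assessment_min must be below assessment_max")
  }
  bad <- which(raw < assessment_min | raw > assessment_max)
  if (length(bad)) {
    id <- if (!is.null(sample_id)) sample_id[bad[1L]] else bad[1L]
    stop("raw score outside theoretical range for sample ", id)
  }
  (raw - assessment_min) / (assessment_max - assessment_min)
}

make_result <- function(cohort_id, term, model_family, beta = NA_real_,
                        se = NA_real_, p = NA_real_, n = NA_integer_,
                        estimable = FALSE, reason = "") {
  data.table(cohort_id = cohort_id, term = term, model_family = model_family,
             beta = beta, se = se, p = p, n = as.integer(n),
             estimable = estimable, reason = reason)
}

# Resolve the response for a cohort data table.
cohort_response <- function(dat, family = c("auto", "linear", "logistic")) {
  family <- match.arg(family)
  ctype <- dat$cohort_type[1L]
  if (family == "auto") family <- if (ctype == "cc") "logistic" else "linear"
  y <- if (family == "linear") {
    rescale_phenotype(dat$phenotype_raw, dat$assessment_min,
                      dat$assessment_max, dat$sample_id)
  } else if (ctype == "cc") {
    as.integer(dat$phenotype_raw)
  } else {
    # logistic requested on a score cohort: median split fallback is not
    # meaningful here; treat as error
    stop("logistic family requires a case/control cohort")
  }
  list(y = y, family = family)
}

fit_one <- function(dat, term, covariates, family, extra_covariates = NULL) {
  dat <- as.data.table(dat)
  cohort <- dat$cohort_id[1L]
  covs <- c(covariates, extra_covariates)
  need <- c(term, covs)
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop("missing model columns: ", paste(miss, collapse = ", "))
  resp <- cohort_response(dat, family)
  mf <- dat[, need, with = FALSE]
  mf[, .y := resp$y]
  mf <- mf[complete.cases(mf)]
  n <- nrow(mf)
  fam_label <- resp$family
  if (n < length(need) + 2L) {
    return(make_result(cohort, term, fam_label, n = n, reason = "too_few_obs"))
  }
  x <- mf[[term]]
  if (length(unique(x)) < 2L || var(x) == 0) {
    return(make_result(cohort, term, fam_label, n = n, reason = "zero_variance"))
  }
  fml <- as.formula(paste(".y ~", paste(c(term, covs), collapse = " + ")))
  fit <- if (resp$family == "linear") {
    lm(fml, data = mf)
  } else {
    # separation with very rare carriers surfaces as a huge SE, which the
    # IVW weighting already handles; the glm warning adds nothing
    suppressWarnings(glm(fml, data = mf, family = binomial()))
  }
  cf <- coef(fit)
  if (is.na(cf[term]) || any(is.na(cf[covs]))) {
    return(make_result(cohort, term, fam_label, n = n, reason = "collinear"))
  }
  sm <- summary(fit)$coefficients
  make_result(cohort, term, fam_label,
              beta = sm[term, 1L], se = sm[term, 2L], p = sm[term, 4L],
              n = n, estimable = TRUE)
}

#' Fit a per-cohort burden regression
#'
#' Regresses the phenotype (0-1 rescaled score, or case status) on one burden
#' term plus the standard covariate set (five principal components and the
#' log-R-ratio SD). Inestimable results (zero-variance term, collinearity,
#' too few observations) are flagged rather than fitted.
#'
#' @param dat Data for a single cohort: `cohort_id`, `cohort_type`,
#'   `phenotype_raw`, `assessment_min`, `assessment_max`, covariates, and the
#'   burden term.
#' @param term Name of the burden column (per-Mb spans, carrier flags, or
#'   gene-set counts).
#' @param covariates Covariate column names.
#' @param family `"auto"` selects linear for score cohorts, logistic for
#'   case/control.
#' @return One-row `data.table` (`cohort_id`, `term`, `model_family`, `beta`,
#'   `se`, `p`, `n`, `estimable`, `reason`).
#' @export
fit_burden_model <- function(dat, term, covariates = default_covariates(),
                             family = "auto") {
  fit_one(dat, term, covariates, family)
}

#' Fit a gene-set enrichment regression
#'
#' As [fit_burden_model()], with two additional covariates controlling the
#' subject's global CNV load — genome-wide CNV count and mean CNV length —
#' so the set coefficient measures set-specific enrichment beyond overall
#' burden.
#'
#' @inheritParams fit_burden_model
#' @param burden_covariates Names of the global burden covariate columns.
#' @return One-row `data.table` as in [fit_burden_model()].
#' @export
fit_enrichment_model <- function(dat, term,
                                 covariates = default_covariates(),
                                 burden_covariates = c("cnv_count",
                                                       "mean_cnv_length_mb"),
                                 family = "auto") {
  fit_one(dat, term, covariates, family, extra_covariates = burden_covariates)
}

#' Linear fit with HC3 heteroskedasticity-consistent standard errors
#'
#' Refits the linear burden model and replaces the classical standard error
#' with the HC3 sandwich estimate
#' \eqn{(X'X)^{-1} X' \mathrm{diag}(e_i^2/(1-h_{ii})^2) X (X'X)^{-1}};
#' the coefficient is identical to the ordinary fit. Used as a sensitivity
#' analysis for terms driven by few carriers.
#'
#' @inheritParams fit_burden_model
#' @return One-row `data.table` with `model_family = "linear_hc3"`.
#' @export
fit_hc3 <- function(dat, term, covariates = default_covariates()) {
  dat <- as.data.table(dat)
  cohort <- dat$cohort_id[1L]
  resp <- cohort_response(dat, "linear")
  mf <- dat[, c(term, covariates), with = FALSE]
  mf[, .y := resp$y]
  mf <- mf[complete.cases(mf)]
  n <- nrow(mf)
  if (n < length(covariates) + 3L || var(mf[[term]]) == 0) {
    return(make_result(cohort, term, "linear_hc3", n = n,
                       reason = "inestimable"))
  }
  fml <- as.formula(paste(".y ~", paste(c(term, covariates), collapse = " + ")))
  fit <- lm(fml, data = mf)
  if (any(is.na(coef(fit)))) {
    return(make_result(cohort, term, "linear_hc3", n = n, reason = "collinear"))
  }
  h <- hatvalues(fit)
  if (any(h >= 1 - 1e-12)) {
    stop("HC3 undefined: observation with leverage 1")
  }
  v <- sandwich::vcovHC(fit, type = "HC3")
  beta <- coef(fit)[term]
  se <- sqrt(v[term, term])
  p <- 2 * pt(abs(beta / se), df = fit$df.residual, lower.tail = FALSE)
  make_result(cohort, term, "linear_hc3", beta = beta, se = se, p = p,
              n = n, estimable = TRUE)
}

#' Proportional-odds (ordinal logistic) burden fit
#'
#' Analyses a score cohort's raw symptom levels with a proportional-odds
#' model, yielding an odds-ratio effect estimate directly comparable across
#' cohorts without rescaling. Raw integer levels are used as-is; with more
#' than 50 distinct values, decile bins bound the parameter count. Cohorts
#' with fewer than three distinct levels fall back to logistic regression.
#'
#' @inheritParams fit_burden_model
#' @return One-row `data.table` with `model_family = "ordinal"` (or
#'   `"logistic"` on fallback); `beta` is the log odds ratio.
#' @export
fit_ordinal <- function(dat, term, covariates = default_covariates()) {
  dat <- as.data.table(dat)
  cohort <- dat$cohort_id[1L]
  lev <- dat$phenotype_raw
  if (length(unique(lev[!is.na(lev)])) < 3L) {
    return(fit_one(dat, term, covariates, "auto"))
  }
  mf <- dat[, c(term, covariates), with = FALSE]
  y <- lev
  if (length(unique(y)) > 50L) {
    br <- unique(quantile(y, probs = seq(0, 1, 0.1), type = 7))
    y <- cut(y, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  mf[, .y := y]
  mf <- mf[complete.cases(mf)]
  n <- nrow(mf)
  if (var(mf[[term]]) == 0) {
    return(make_result(cohort, term, "ordinal", n = n, reason = "zero_variance"))
  }
  mf[, .y := factor(.y, ordered = TRUE)]
  fml <- as.formula(paste(".y ~", paste(c(term, covariates), collapse = " + ")))
  fit <- tryCatch(
    MASS::polr(fml, data = mf, Hess = TRUE),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(make_result(cohort, term, "ordinal", n = n, reason = "no_convergence"))
  }
  beta <- coef(fit)[term]
  se <- sqrt(vcov(fit)[term, term])
  p <- 2 * pnorm(abs(beta / se), lower.tail = FALSE)
  make_result(cohort, term, "ordinal", beta = beta, se = se, p = p,
              n = n, estimable = TRUE)
}

# Large-sample SE of an R-squared (Cohen's variance formula), applied to
# an R-squared increment.
r2_se <- function(r2, n, k) {
  sqrt(pmax(0, 4 * r2 * (1 - r2)^2 * (n - k - 1)^2 / ((n^2 - 1) * (n + 3))))
}

#' Joint polygenic-score and CNV-burden model with incremental R-squared
#'
#' Standardises the PRS to mean 0 / SD 1 within the cohort, then fits a
#' baseline linear model (covariates only), a +PRS model, and a +PRS+CNV
#' model. Each increment's R-squared gain is reported with a large-sample
#' (Cohen) standard error and an F-test p-value. Subjects without a PRS are
#' dropped (with the count recorded).
#'
#' @param dat Single-cohort data (score cohort) including a `prs` column.
#' @param cnv_term Name of the CNV burden column.
#' @param covariates Baseline covariate names.
#' @return List with `results` (PRS and CNV coefficient rows from the full
#'   model) and `increments` (`term`, `delta_r2`, `se`, `p`, `n`), plus
#'   `n_dropped`.
#' @export
joint_prs_cnv <- function(dat, cnv_term = "span_ndd_del_mb",
                          covariates = default_covariates()) {
  dat <- as.data.table(dat)
  cohort <- dat$cohort_id[1L]
  resp <- cohort_response(dat, "linear")
  mf <- dat[, c(cnv_term, "prs", covariates), with = FALSE]
  mf[, .y := resp$y]
  n_all <- nrow(mf)
  mf <- mf[complete.cases(mf)]
  n_dropped <- n_all - nrow(mf)
  n <- nrow(mf)
  prs_sd <- sd(mf$prs)
  if (!is.finite(prs_sd) || prs_sd == 0) stop("PRS has zero variance")
  mf[, prs := (prs - mean(prs)) / prs_sd]
  f0 <- as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  f1 <- as.formula(paste(".y ~", paste(c(covariates, "prs"), collapse = " + ")))
  f2 <- as.formula(paste(".y ~", paste(c(covariates, "prs", cnv_term),
                                       collapse = " + ")))
  m0 <- lm(f0, data = mf)
  m1 <- lm(f1, data = mf)
  m2 <- lm(f2, data = mf)
  r2 <- vapply(list(m0, m1, m2), function(m) summary(m)$r.squared, numeric(1))
  k2 <- length(coef(m2)) - 1L
  a1 <- anova(m0, m1)
  a2 <- anova(m1, m2)
  increments <- data.table(
    cohort_id = cohort,
    term = c("prs", cnv_term),
    delta_r2 = c(r2[2L] - r2[1L], r2[3L] - r2[2L]),
    se = r2_se(c(r2[2L] - r2[1L], r2[3L] - r2[2L]), n, k2),
    p = c(a1$`Pr(>F)`[2L], a2$`Pr(>F)`[2L]),
    n = n
  )
  sm <- summary(m2)$coefficients
  coef_row <- function(tm) {
    if (tm %in% rownames(sm)) {
      make_result(cohort, tm, "linear", sm[tm, 1L], sm[tm, 2L], sm[tm, 4L],
                  n, TRUE)
    } else {
      make_result(cohort, tm, "linear", n = n, reason = "collinear")
    }
  }
  results <- rbind(coef_row("prs"), coef_row(cnv_term))
  list(results = results, increments = increments, n_dropped = n_dropped)
}

#' Fit one model across all cohorts
#'
#' Convenience wrapper looping a fitter over cohorts and terms.
#'
#' @param dat Multi-cohort analysis table.
#' @param terms Burden term names.
#' @param fitter One of `"burden"`, `"enrichment"`, `"hc3"`, `"ordinal"`.
#' @param ... Passed to the underlying fitter.
#' @return Stacked per-cohort `data.table` of results.
#' @export
cohort_associations <- function(dat, terms, fitter = "burden", ...) {
  dat <- as.data.table(dat)
  f <- switch(fitter,
              burden = fit_burden_model,
              enrichment = fit_enrichment_model,
              hc3 = fit_hc3,
              ordinal = fit_ordinal,
              stop("unknown fitter: ", fitter))
  out <- list()
  for (co in unique(dat$cohort_id)) {
    sub <- dat[cohort_id == co]
    for (tm in terms) out[[length(out) + 1L]] <- f(sub, tm, ...)
  }
  rbindlist(out)
}
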