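# End-to-end runner: consensus -> QC -> burden -> per-cohort association ->
# IVW meta-analysis with FDR within families.

span_terms <- function() {
  c("span_total_mb", "span_del_mb", "span_dup_mb",
    "span_ndd_del_mb", "span_ndd_dup_mb",
    "span_nonndd_del_mb", "span_nonndd_dup_mb")
}

#' Assemble the per-cohort analysis table
#'
#' Merges the subject/covariate table, the sample QC metrics (for the
#' `lrr_sd` covariate) and the wide burden profile, keeping only samples that
#' passed sample QC.
#'
#' @param subjects Subject table.
#' @param metrics Sample metrics (from [sample_qc_metrics()] or the
#'   generator).
#' @param profile Wide burden profile (from [burden_profile()]).
#' @param keep Sample ids passing QC (default: all in `profile`).
#' @return Analysis-ready `data.table`.
#' @export
analysis_table <- function(subjects, metrics, profile, keep = NULL) {
  dat <- as.data.table(subjects)
  m <- as.data.table(metrics)[, .(sample_id, lrr_sd)]
  dat <- m[dat, on = "sample_id"]
  dat <- as.data.table(profile)[dat, on = "sample_id"]
  if (!is.null(keep)) dat <- dat[sample_id %in% keep]
  dat[]
}

#' Run the complete burden-association pipeline on a study bundle
#'
#' Chains dual-caller consensus calling, sample- and CNV-level QC, burden
#' encoding, per-cohort regression for the genome-wide span family and the
#' NDD carrier family, and fixed-effects IVW meta-analysis with BH-FDR
#' within each family. Gene and gene-set families are optional.
#'
#' @param study Bundle from [synth_study()] (or an equivalently shaped list
#'   built from files: `annotation`, `callsets$A/B`, `subjects`, `metrics`).
#' @param config A [filter_config()].
#' @param carrier_rule Overlap rule used for the NDD carrier family.
#' @param families Which test families to fit: subset of
#'   `c("span", "ndd_carrier", "genes", "genesets")`.
#' @param min_gene_freq Minimum carrier frequency for a gene to enter the
#'   gene family.
#' @return List with `consensus`, `qc`, `burden`, `data` (analysis table),
#'   `cohort_results`, `meta` and a `counts` log.
#' @export
run_pipeline <- function(study, config = filter_config(),
                         carrier_rule = "ge50",
                         families = c("span", "ndd_carrier"),
                         min_gene_freq = 1e-4) {
  ann <- study$annotation
  cons <- consensus_pipeline(study$callsets$A, study$callsets$B, ann$probes)
  qc <- qc_pipeline(cons$calls, study$metrics, ann, config)
  keep <- qc$sample_flags[pass == TRUE, sample_id]
  subjects_kept <- as.data.table(study$subjects)[sample_id %in% keep]

  want_sets <- "genesets" %in% families
  bp <- burden_profile(qc$calls, ann, subjects_kept,
                       geneset_strata = if (want_sets) c("all", "DEL", "DUP")
                                        else character(0))
  dat <- analysis_table(subjects_kept, study$metrics, bp$profile)

  results <- list()
  if ("span" %in% families) {
    r <- cohort_associations(dat, span_terms(), fitter = "burden")
    r[, family := "genomewide_burden"]
    results[["span"]] <- r
  }
  if ("ndd_carrier" %in% families && nrow(ann$ndd_regions)) {
    terms <- paste0("carrier_", ann$ndd_regions$label, "_", carrier_rule)
    terms <- intersect(terms, names(dat))
    r <- cohort_associations(dat, terms, fitter = "burden")
    r[, family := paste0("ndd_regions_", carrier_rule)]
    results[["ndd"]] <- r
  }
  if ("genes" %in% families) {
    hits <- bp$gene_hits
    n_sub <- nrow(subjects_kept)
    gene_freq <- hits[stratum == "all", .(gene_n = uniqueN(sample_id)),
                      by = symbol][gene_n / n_sub >= min_gene_freq]
    gdat <- copy(dat)
    gr <- list()
    for (g in gene_freq$symbol) {
      carriers <- hits[stratum == "all" & symbol == g, sample_id]
      gdat[, gene_hit := as.integer(sample_id %in% carriers)]
      rr <- cohort_associations(gdat, "gene_hit", fitter = "burden")
      rr[, term := paste0("gene_", g)]
      gr[[g]] <- rr
    }
    if (length(gr)) {
      r <- rbindlist(gr)
      r[, family := "genes"]
      results[["genes"]] <- r
    }
  }
  if (want_sets) {
    set_terms <- grep("^geneset_.*_DEL$", names(dat), value = TRUE)
    r <- cohort_associations(dat, set_terms, fitter = "enrichment")
    r[, family := "genesets_DEL"]
    results[["genesets"]] <- r
  }
  cohort_results <- rbindlist(results, use.names = TRUE)
  meta <- meta_analyze(cohort_results)

  list(
    consensus = cons,
    qc = qc,
    burden = bp,
    data = dat,
    cohort_results = cohort_results,
    meta = meta,
    counts = c(cons$counts, qc$counts,
               analysis_samples = nrow(subjects_kept))
  )
}

#' Plain-text forest summary of a meta-analysed term
#'
#' @param cohort_results Per-cohort results table.
#' @param meta Meta results table.
#' @param term Term to summarise.
#' @return Character vector of lines, invisibly; also printed.
#' @export
forest_text <- function(cohort_results, meta, term) {
  tt <- term
  cr <- as.data.table(cohort_results)
  cr <- cr[cr$term == tt & cr$estimable == TRUE]
  mr <- as.data.table(meta)
  mr <- mr[mr$term == tt]
  lines <- c(
    sprintf("term: %s", term),
    sprintf("  %-12s beta=% .5f se=%.5f p=%.3g", cr$cohort_id, cr$beta,
            cr$se, cr$p),
    sprintf("  %-12s beta=% .5f se=%.5f p=%.3g q=%.3g [IVW, k=%d]",
            "META", mr$beta, mr$se, mr$p, mr$q, mr$k)
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
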