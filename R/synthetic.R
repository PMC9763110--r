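# Synthetic study generator: emits every input the pipeline consumes
# (annotation tracks, true CNVs, two noisy caller callsets, sample QC
# metrics, covariates, phenotypes) with known ground truth, so that
# consensus recovery, QC behaviour and statistical calibration can be
# tested against planted values.

#' Build a synthetic-study configuration
#'
#' Defines the study conditions for the generator: cohort structure, a small
#' multi-chromosome genome with a regular probe grid, neurodevelopmental-
#' disorder (NDD) CNV regions of both types, caller error structure, and a
#' linear phenotype model on the 0-1 scale with a planted NDD-deletion span
#' effect. Defaults emulate a rare-CNV study at desk scale: NDD carrier
#' frequency 0.5 percent per region (comparable to the most common
#' pathogenic microdeletions), background CNV rate just under one event per
#' subject, and residual noise chosen so latent scores stay inside [0, 1].
#'
#' @param n_cohorts Number of cohorts.
#' @param subjects_per_cohort Subjects per cohort.
#' @param cc_cohorts How many of the cohorts are case/control (the rest carry
#'   continuous symptom scores on instrument-specific theoretical ranges).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param probe_spacing Array probe spacing in bp.
#' @param ndd_regions `data.table(label, chrom, start, end, type)` of NDD CNV
#'   regions; `NULL` uses a built-in set of three deletion and three
#'   duplication regions.
#' @param ndd_carrier_prob Per-subject, per-region probability of carrying a
#'   CNV of the region's type spanning the region.
#' @param gene_count Number of gene models (two are placed inside each NDD
#'   region; one gene gets two isoforms).
#' @param geneset_count,geneset_size Number and size of generated gene-sets.
#' @param segdup_fraction Fraction of the genome covered by the synthetic
#'   segmental-duplication track.
#' @param true_cnv_rate Expected background (non-NDD) CNVs per subject.
#' @param beta_ndd_del Planted effect of NDD deletion span, per Mb on the 0-1
#'   phenotype scale.
#' @param beta_prs Planted effect per SD of the polygenic score.
#' @param beta_pcs Planted effects of the five genotype principal components.
#' @param intercept Latent phenotype intercept on the 0-1 scale.
#' @param noise_sd Residual SD of the latent phenotype.
#' @param caller_error List with `jitter_sd` (boundary jitter SD, bp),
#'   `frag_prob` (probability a true CNV is emitted as two fragments with a
#'   gap under 30 percent of the true span), `false_rate` (expected false
#'   calls per sample per caller) and `flip_prob` (gain/loss type flip
#'   probability per call per caller); alternatively a list with elements
#'   `A` and `B`, each such a record, for caller-specific error.
#' @param case_threshold Latent-scale cutoff that dichotomises case/control
#'   cohorts.
#' @param qc_outlier_frac Fraction of samples given inflated array-quality
#'   metrics (planted QC outliers).
#' @param geno_fail_frac Per-flag probability of failing genotype QC.
#' @param seed Integer seed; all stage streams are derived from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_cohorts = 5L,
                         subjects_per_cohort = 200L,
                         cc_cohorts = 1L,
                         chrom_lengths = c(chr1 = 60e6, chr2 = 45e6, chr3 = 30e6),
                         probe_spacing = 5000L,
                         ndd_regions = NULL,
                         ndd_carrier_prob = 0.005,
                         gene_count = 60L,
                         geneset_count = 8L,
                         geneset_size = 8L,
                         segdup_fraction = 0.02,
                         true_cnv_rate = 0.8,
                         beta_ndd_del = 0.03,
                         beta_prs = 0.01,
                         beta_pcs = rep(0.005, 5),
                         intercept = 0.4,
                         noise_sd = 0.12,
                         caller_error = list(jitter_sd = 5000, frag_prob = 0.05,
                                             false_rate = 0.10, flip_prob = 0.01),
                         case_threshold = 0.55,
                         qc_outlier_frac = 0.01,
                         geno_fail_frac = 0.005,
                         seed = 20260101L) {
  if (is.null(ndd_regions)) {
    # size mix mirrors real neurodevelopmental CNV regions, which range
    # from a few hundred kb to several Mb
    ndd_regions <- data.table(
      label = c("NDD_DEL_A", "NDD_DUP_B", "NDD_DEL_C",
                "NDD_DUP_D", "NDD_DEL_E", "NDD_DUP_F"),
      chrom = c("chr1", "chr1", "chr2", "chr2", "chr3", "chr3"),
      start = as.integer(c(10e6, 40e6, 8e6, 28e6, 5e6, 20e6)),
      end   = as.integer(c(12.5e6, 40.4e6, 9.5e6, 30e6, 5.5e6, 20.6e6)),
      type  = c("DEL", "DUP", "DEL", "DUP", "DEL", "DUP")
    )
    ndd_regions <- ndd_regions[chrom %in% names(chrom_lengths)]
  }
  ndd_regions <- as.data.table(ndd_regions)
  cfg <- list(
    n_cohorts = as.integer(n_cohorts),
    subjects_per_cohort = as.integer(subjects_per_cohort),
    cc_cohorts = as.integer(cc_cohorts),
    chrom_lengths = chrom_lengths,
    probe_spacing = as.integer(probe_spacing),
    ndd_regions = ndd_regions,
    ndd_carrier_prob = ndd_carrier_prob,
    gene_count = as.integer(gene_count),
    geneset_count = as.integer(geneset_count),
    geneset_size = as.integer(geneset_size),
    segdup_fraction = segdup_fraction,
    true_cnv_rate = true_cnv_rate,
    beta_ndd_del = beta_ndd_del,
    beta_prs = beta_prs,
    beta_pcs = beta_pcs,
    intercept = intercept,
    noise_sd = noise_sd,
    caller_error = normalize_caller_error(caller_error),
    case_threshold = case_threshold,
    qc_outlier_frac = qc_outlier_frac,
    geno_fail_frac = geno_fail_frac,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

# Accept one error record for both callers or per-caller records (A, B).
normalize_caller_error <- function(err) {
  need <- c("jitter_sd", "frag_prob", "false_rate", "flip_prob")
  if (all(c("A", "B") %in% names(err))) {
    lapply(err[c("A", "B")], function(e) {
      miss <- setdiff(need, names(e))
      if (length(miss)) stop("caller_error missing: ", paste(miss, collapse = ", "))
      e
    })
  } else {
    miss <- setdiff(need, names(err))
    if (length(miss)) stop("caller_error missing: ", paste(miss, collapse = ", "))
    list(A = err, B = err)
  }
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_cohorts >= 1L, cfg$subjects_per_cohort >= 1L)
  if (cfg$cc_cohorts < 0L || cfg$cc_cohorts > cfg$n_cohorts) {
    stop("cc_cohorts must be between 0 and n_cohorts")
  }
  if (any(cfg$chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (cfg$probe_spacing <= 0) stop("probe_spacing must be positive")
  probs <- c(ndd_carrier_prob = cfg$ndd_carrier_prob,
             segdup_fraction = cfg$segdup_fraction,
             qc_outlier_frac = cfg$qc_outlier_frac,
             geno_fail_frac = cfg$geno_fail_frac)
  for (nm in c("A", "B")) {
    e <- cfg$caller_error[[nm]]
    probs[paste0("frag_prob_", nm)] <- e$frag_prob
    probs[paste0("flip_prob_", nm)] <- e$flip_prob
    if (e$false_rate < 0) stop("event rates must be non-negative")
    if (e$jitter_sd < 0) stop("jitter_sd must be non-negative")
  }
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities outside [0,1]: ", paste(names(probs)[bad], collapse = ", "))
  if (cfg$true_cnv_rate < 0) stop("event rates must be non-negative")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(cfg$beta_pcs) != 5L) stop("beta_pcs must have length 5")
  nr <- cfg$ndd_regions
  if (nrow(nr)) {
    unknown <- setdiff(nr$chrom, names(cfg$chrom_lengths))
    if (length(unknown)) {
      stop("NDD region chromosome(s) not in genome: ", paste(unknown, collapse = ", "))
    }
    over <- nr[end > cfg$chrom_lengths[chrom] | start < 0]
    if (nrow(over)) {
      stop("NDD region '", over$label[1L], "' exceeds its chromosome bounds")
    }
    if (anyDuplicated(nr$label)) stop("NDD region labels must be unique")
  }
  invisible(cfg)
}

# Derive one deterministic RNG seed per generator stage. The base seed is
# multiplied so that stage streams of nearby base seeds can never coincide
# (offsets run 1..5, so colliding would need base seeds 7x apart).
stage_seed <- function(cfg, offset) {
  ((cfg$seed %% 250000000L) * 7L) + offset
}

#' Collapse gene isoforms to one span per gene symbol
#'
#' For genes with multiple isoforms the minimum start and maximum end over
#' isoforms define the gene span, the convention used for gene-level burden.
#'
#' @param isoforms `data.table(symbol, chrom, start, end, accession)`.
#' @return One row per symbol with the collapsed span and a `protein_coding`
#'   flag (accession prefix `NM_`).
#' @export
collapse_isoforms <- function(isoforms) {
  iso <- as.data.table(isoforms)
  genes <- iso[, .(
    chrom = chrom[1L],
    start = min(start),
    end = max(end),
    accession = accession[1L]
  ), by = .(symbol)]
  genes[, protein_coding := startsWith(accession, "NM_")]
  genes[]
}

#' Generate the synthetic annotation bundle
#'
#' Builds chromosomes, a regular probe map, centromere/telomere and
#' immunoglobulin/T-cell-receptor loci, a random segmental-duplication track,
#' gene models (with at least one multi-isoform gene, collapsed via
#' [collapse_isoforms()]) and the NDD CNV regions from the configuration.
#'
#' @param config A [synth_config()].
#' @return List with `chrom_lengths`, `probes`, `special`, `segdups`,
#'   `isoforms`, `genes`, `ndd_regions`, `genesets`.
#' @export
synth_annotation <- function(config) {
  validate_synth_config(config)
  set.seed(stage_seed(config, 1L))
  cl <- config$chrom_lengths
  chroms <- names(cl)

  probes <- rbindlist(lapply(chroms, function(ch) {
    data.table(chrom = ch, pos = seq.int(0L, as.integer(cl[[ch]]) - 1L,
                                         by = config$probe_spacing))
  }))

  special <- rbindlist(lapply(chroms, function(ch) {
    len <- as.integer(cl[[ch]])
    telo <- as.integer(min(500e3, floor(len * 0.05)))
    cen_half <- as.integer(min(500e3, floor(len * 0.05)))
    mid <- as.integer(len %/% 2L)
    data.table(
      chrom = ch,
      start = c(0L, len - telo, mid - cen_half),
      end = c(telo, len, mid + cen_half),
      label = c("telomere", "telomere", "centromere")
    )
  }))
  # one Ig/TCR-style locus on the largest chromosome, away from the middle
  big <- chroms[which.max(cl)]
  big_len <- as.integer(cl[[big]])
  ig_start <- as.integer(floor(big_len * 0.83))
  special <- rbind(special, data.table(
    chrom = big, start = ig_start,
    end = as.integer(min(big_len, ig_start + 300e3)), label = "ig_tcr"
  ))

  genome_bp <- sum(as.numeric(cl))
  n_segdup <- as.integer(round(config$segdup_fraction * genome_bp / 1e5))
  segdups <- if (n_segdup > 0L) {
    ch <- sample(chroms, n_segdup, replace = TRUE, prob = as.numeric(cl))
    len <- as.integer(round(runif(n_segdup, 50e3, 150e3)))
    st <- as.integer(floor(runif(n_segdup, 0, as.numeric(cl[ch]) - len)))
    data.table(chrom = ch, start = st, end = st + len, label = "segdup")
  } else {
    data.table(chrom = character(), start = integer(), end = integer(),
               label = character())
  }

  nr <- config$ndd_regions
  # two genes inside every NDD region, remainder placed at random
  ndd_genes <- if (nrow(nr)) rbindlist(lapply(seq_len(nrow(nr)), function(i) {
    L <- nr$end[i] - nr$start[i]
    data.table(
      chrom = nr$chrom[i],
      start = as.integer(nr$start[i] + round(c(0.05, 0.55) * L)),
      end = as.integer(nr$start[i] + round(c(0.45, 0.90) * L))
    )
  })) else data.table(chrom = character(), start = integer(), end = integer())

  n_rand <- max(0L, config$gene_count - nrow(ndd_genes))
  ch <- sample(chroms, n_rand, replace = TRUE, prob = as.numeric(cl))
  glen <- as.integer(round(runif(n_rand, 20e3, 200e3)))
  gst <- as.integer(floor(runif(n_rand, 0, as.numeric(cl[ch]) - glen)))
  rand_genes <- data.table(chrom = ch, start = gst, end = gst + glen)
  gene_tbl <- rbind(ndd_genes, rand_genes)
  gene_tbl[, symbol := sprintf("GENE%03d", .I)]
  n_nc <- min(2L, nrow(gene_tbl))
  acc_prefix <- rep("NM_", nrow(gene_tbl))
  if (n_nc > 0L) acc_prefix[seq(nrow(gene_tbl) - n_nc + 1L, nrow(gene_tbl))] <- "NR_"
  gene_tbl[, accession := sprintf("%s%06d", acc_prefix, .I)]

  # first random gene carries two isoforms; all others a single isoform
  iso_target <- nrow(ndd_genes) + 1L
  isoforms <- rbindlist(lapply(seq_len(nrow(gene_tbl)), function(i) {
    g <- gene_tbl[i]
    if (i == iso_target && g$end - g$start >= 10L) {
      L <- g$end - g$start
      data.table(symbol = g$symbol, chrom = g$chrom,
                 start = c(g$start, g$start + as.integer(round(0.3 * L))),
                 end = c(g$start + as.integer(round(0.6 * L)), g$end),
                 accession = g$accession)
    } else {
      data.table(symbol = g$symbol, chrom = g$chrom, start = g$start,
                 end = g$end, accession = g$accession)
    }
  }))
  genes <- collapse_isoforms(isoforms)

  pc_genes <- genes[protein_coding == TRUE, symbol]
  ndd_members <- genes[symbol %in% gene_tbl$symbol[seq_len(nrow(ndd_genes))] &
                         protein_coding == TRUE, symbol]
  cats <- c("brain_expression", "control", "scRNA", "lof_intolerant", "neuro")
  genesets <- data.table(set_name = "neuro_ndd", gene = ndd_members,
                         category = "neuro")
  extra <- max(0L, config$geneset_count - 1L)
  if (extra > 0L) {
    genesets <- rbind(genesets, rbindlist(lapply(seq_len(extra), function(i) {
      data.table(
        set_name = sprintf("set_%s_%02d", cats[(i - 1L) %% length(cats) + 1L], i),
        gene = sample(pc_genes, min(config$geneset_size, length(pc_genes))),
        category = cats[(i - 1L) %% length(cats) + 1L]
      )
    })))
  }

  list(chrom_lengths = cl, probes = probes, special = special,
       segdups = segdups, isoforms = isoforms, genes = genes,
       ndd_regions = copy(nr), genesets = genesets)
}

#' Generate ground-truth CNVs and the subject frame
#'
#' Plants NDD-region CNVs (per-region carrier probability, event spanning the
#' region with small random extensions) and background CNVs (Poisson count
#' per subject, log-uniform lengths 50 kb to 1 Mb). Any two true events of
#' one subject on one chromosome are kept at least 2 Mb apart, which
#' guarantees that the 30 percent annealing rule can never merge distinct
#' true events and that opposite-type events can never be mistaken for a
#' caller gain/loss conflict.
#'
#' @param config A [synth_config()].
#' @param annotation Bundle from [synth_annotation()].
#' @return List with `subjects` (sample/cohort frame), `true_cnvs` and
#'   `true_betas`.
#' @export
synth_truth <- function(config, annotation) {
  set.seed(stage_seed(config, 2L))
  cl <- config$chrom_lengths
  chroms <- names(cl)
  n_sub <- config$n_cohorts * config$subjects_per_cohort
  subjects <- data.table(
    sample_id = sprintf("S%05d", seq_len(n_sub)),
    cohort_id = rep(sprintf("cohort%02d", seq_len(config$n_cohorts)),
                    each = config$subjects_per_cohort)
  )
  n_score <- config$n_cohorts - config$cc_cohorts
  subjects[, cohort_type := ifelse(
    as.integer(factor(cohort_id)) <= n_score, "score", "cc")]

  nr <- config$ndd_regions
  ndd_events <- if (nrow(nr)) rbindlist(lapply(seq_len(nrow(nr)), function(i) {
    carriers <- which(runif(n_sub) < config$ndd_carrier_prob)
    if (!length(carriers)) return(NULL)
    ext_l <- as.integer(round(runif(length(carriers), 10e3, 60e3)))
    ext_r <- as.integer(round(runif(length(carriers), 10e3, 60e3)))
    data.table(
      sample_id = subjects$sample_id[carriers],
      chrom = nr$chrom[i],
      start = pmax(0L, nr$start[i] - ext_l),
      end = pmin(as.integer(cl[[nr$chrom[i]]]), nr$end[i] + ext_r),
      type = nr$type[i]
    )
  })) else NULL

  n_bg <- rpois(n_sub, config$true_cnv_rate)
  draw_background <- function(k, samples) {
    ch <- sample(chroms, k, replace = TRUE, prob = as.numeric(cl))
    len <- as.integer(round(exp(runif(k, log(50e3), log(1e6)))))
    st <- as.integer(floor(runif(k, 0, as.numeric(cl[ch]) - len)))
    data.table(sample_id = samples, chrom = ch, start = st, end = st + len,
               type = sample(c("DEL", "DUP"), k, replace = TRUE))
  }
  bg <- if (sum(n_bg) > 0L) {
    draw_background(sum(n_bg), rep(subjects$sample_id, n_bg))
  } else NULL
  if (!is.null(bg)) bg[, is_ndd_event := FALSE]
  if (!is.null(ndd_events)) ndd_events[, is_ndd_event := TRUE]
  cnvs <- rbindlist(list(ndd_events, bg), use.names = TRUE)

  # enforce >= 2 Mb separation between a subject's events on one chromosome:
  # with event lengths bounded by ~2.6 Mb the 30% rule then can never anneal
  # two distinct true events, and opposite-type events can never reach the
  # 50% reciprocal overlap of the conflict rule. Only background events are
  # moved; unresolvable ones are dropped.
  min_gap <- 2e6
  for (iter in 1:25) {
    setorder(cnvs, sample_id, chrom, start)
    cnvs[, violation := {
      prev_end <- shift(cummax(as.numeric(end)))
      too_close <- !is.na(prev_end) & (start - prev_end) < min_gap
      too_close | shift(too_close, type = "lead", fill = FALSE)
    }, by = .(sample_id, chrom)]
    redraw <- which(cnvs$violation & !cnvs$is_ndd_event)
    if (!length(redraw)) break
    cnvs[redraw, c("chrom", "start", "end", "type") := {
      nb <- draw_background(length(redraw), sample_id)
      list(nb$chrom, nb$start, nb$end, nb$type)
    }]
  }
  setorder(cnvs, sample_id, chrom, start)
  cnvs[, violation := {
    prev_end <- shift(cummax(as.numeric(end)))
    too_close <- !is.na(prev_end) & (start - prev_end) < min_gap
    too_close | shift(too_close, type = "lead", fill = FALSE)
  }, by = .(sample_id, chrom)]
  cnvs <- cnvs[!(violation & !is_ndd_event)]
  cnvs[, c("violation") := NULL]
  cnvs[, cnv_id := sprintf("T%06d", .I)]
  setcolorder(cnvs, c("cnv_id", "sample_id", "chrom", "start", "end", "type",
                      "is_ndd_event"))

  list(
    subjects = subjects,
    true_cnvs = cnvs[],
    true_betas = c(span_ndd_del_mb = config$beta_ndd_del, prs = config$beta_prs)
  )
}

#' Generate two noisy caller callsets from the ground truth
#'
#' Each true CNV appears in each caller's output with independent boundary
#' jitter; with the configured fragmentation probability it is emitted as two
#' sub-calls whose gap is below 30 percent of the true span (so annealing can
#' recover the event); types flip gain/loss at the configured rate; false
#' calls are drawn uniformly over the non-centromeric genome with log-uniform
#' lengths 10 kb to 1 Mb. Probe counts are recomputed from the probe map.
#' Every emitted call carries `truth_id` (or `is_false = TRUE`).
#'
#' @param truth From [synth_truth()].
#' @param config A [synth_config()].
#' @param annotation From [synth_annotation()].
#' @return List of two call tables named `A` and `B`.
#' @export
synth_callsets <- function(truth, config, annotation) {
  set.seed(stage_seed(config, 3L))
  cl <- config$chrom_lengths
  cens <- annotation$special[label == "centromere"]
  n_sub <- nrow(truth$subjects)

  one_caller <- function(caller_name, err) {
    base <- copy(truth$true_cnvs)[, .(truth_id = cnv_id, sample_id, chrom,
                                      start, end, type)]
    n <- nrow(base)
    if (n) {
      s <- base$start + as.integer(round(rnorm(n, 0, err$jitter_sd)))
      e <- base$end + as.integer(round(rnorm(n, 0, err$jitter_sd)))
      s <- pmax(0L, s)
      e <- pmin(as.integer(cl[base$chrom]), e)
      degenerate <- e - s < 1000L
      s[degenerate] <- base$start[degenerate]
      e[degenerate] <- base$end[degenerate]
      base[, `:=`(start = s, end = e)]
      flip <- runif(n) < err$flip_prob
      base[flip, type := ifelse(type == "DEL", "DUP", "DEL")]

      frag <- runif(n) < err$frag_prob
      whole <- base[!frag]
      if (any(frag)) {
        fb <- base[frag]
        L <- fb$end - fb$start
        gap <- pmax(1L, as.integer(round(runif(nrow(fb), 0.05, 0.25) * L)))
        a <- as.integer(round(runif(nrow(fb), 0.2, 0.8) * (L - gap)))
        a <- pmax(1L, pmin(a, L - gap - 1L))
        left <- copy(fb)[, end := start + a]
        right <- copy(fb)[, start := start + a + gap]
        base <- rbind(whole, left, right)
      } else {
        base <- whole
      }
      base[, is_false := FALSE]
    } else {
      base <- data.table(truth_id = character(), sample_id = character(),
                         chrom = character(), start = integer(),
                         end = integer(), type = character(),
                         is_false = logical())
    }

    n_false <- rpois(n_sub, err$false_rate)
    if (sum(n_false) > 0L) {
      k <- sum(n_false)
      samples <- rep(truth$subjects$sample_id, n_false)
      ch <- sample(names(cl), k, replace = TRUE, prob = as.numeric(cl))
      len <- as.integer(round(exp(runif(k, log(10e3), log(1e6)))))
      st <- as.integer(floor(runif(k, 0, as.numeric(cl[ch]) - len)))
      fc <- data.table(truth_id = NA_character_, sample_id = samples,
                       chrom = ch, start = st, end = st + len,
                       type = sample(c("DEL", "DUP"), k, replace = TRUE),
                       is_false = TRUE)
      # reject-and-redraw any false call whose midpoint falls in a centromere
      for (i in 1:10) {
        mid <- fc$start + (fc$end - fc$start) %/% 2L
        in_cen <- rep(FALSE, nrow(fc))
        for (j in seq_len(nrow(cens))) {
          hit <- fc$chrom == cens$chrom[j] & mid >= cens$start[j] & mid < cens$end[j]
          in_cen <- in_cen | hit
        }
        if (!any(in_cen)) break
        kk <- sum(in_cen)
        ch2 <- sample(names(cl), kk, replace = TRUE, prob = as.numeric(cl))
        len2 <- as.integer(round(exp(runif(kk, log(10e3), log(1e6)))))
        st2 <- as.integer(floor(runif(kk, 0, as.numeric(cl[ch2]) - len2)))
        fc[in_cen, `:=`(chrom = ch2, start = st2, end = st2 + len2)]
      }
      base <- rbind(base, fc)
    }

    base[, `:=`(
      caller = caller_name,
      n_probes = count_probes(base, annotation$probes),
      conf = round(exp(rnorm(nrow(base), log(15), 0.5)), 3)
    )]
    setorder(base, sample_id, chrom, start)
    setcolorder(base, c("sample_id", "chrom", "start", "end", "type",
                        "n_probes", "caller", "conf", "truth_id", "is_false"))
    base[]
  }

  list(A = one_caller("callerA", config$caller_error$A),
       B = one_caller("callerB", config$caller_error$B))
}

#' Generate phenotypes and covariates under the planted linear model
#'
#' The latent score is
#' `intercept + beta_ndd_del * (true NDD deletion span in Mb) + sum(beta_pc *
#' PC) + beta_prs * PRS + Normal(0, noise_sd)`, truncated to [0, 1]. Score
#' cohorts are assigned an instrument-specific theoretical range and emit
#' integer raw scores on it; case/control cohorts dichotomise the latent
#' score at `case_threshold`.
#'
#' @param truth From [synth_truth()].
#' @param config A [synth_config()].
#' @param annotation From [synth_annotation()] (used to derive the true NDD
#'   deletion span when `ndd_del_mb` is not supplied).
#' @param ndd_del_mb Optional per-subject true NDD deletion span (Mb), in
#'   `truth$subjects` order.
#' @return List with the augmented `subjects` table and the per-subject
#'   `latent` scores.
#' @export
synth_phenotypes <- function(truth, config, annotation, ndd_del_mb = NULL) {
  if (config$noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(stage_seed(config, 4L))
  subjects <- copy(truth$subjects)
  n <- nrow(subjects)

  if (is.null(ndd_del_mb)) {
    prof <- genome_span(truth$true_cnvs, config$ndd_regions, subjects)
    ndd_del_mb <- prof[subjects, on = "sample_id"]$span_ndd_del_mb
  }
  stopifnot(length(ndd_del_mb) == n)

  pcs <- matrix(rnorm(n * 5L), n, 5L, dimnames = list(NULL, paste0("PC", 1:5)))
  prs <- rnorm(n)
  latent <- config$intercept +
    config$beta_ndd_del * ndd_del_mb +
    as.numeric(pcs %*% config$beta_pcs) +
    config$beta_prs * prs +
    rnorm(n, 0, config$noise_sd)
  latent <- pmin(1, pmax(0, latent))

  # instrument palette: theoretical (min, max) score ranges
  palette <- list(c(17L, 85L), c(0L, 136L), c(0L, 88L), c(0L, 51L), c(20L, 80L))
  cohorts <- unique(subjects$cohort_id)
  rng <- palette[((seq_along(cohorts) - 1L) %% length(palette)) + 1L]
  names(rng) <- cohorts

  subjects[, `:=`(
    assessment_min = NA_integer_, assessment_max = NA_integer_,
    phenotype_raw = NA_real_
  )]
  for (co in cohorts) {
    idx <- which(subjects$cohort_id == co)
    if (subjects$cohort_type[idx[1L]] == "score") {
      r <- rng[[co]]
      subjects[idx, `:=`(
        assessment_min = r[1L], assessment_max = r[2L],
        phenotype_raw = round(r[1L] + latent[idx] * (r[2L] - r[1L]))
      )]
    } else {
      subjects[idx, phenotype_raw := as.numeric(latent[idx] >= config$case_threshold)]
    }
  }
  for (j in colnames(pcs)) subjects[, (j) := pcs[, j]]
  subjects[, `:=`(prs = prs, true_ndd_del_mb = ndd_del_mb)]
  list(subjects = subjects[], latent = latent)
}

#' Generate per-sample array-quality metrics and genotype-QC flags
#'
#' Baseline metrics are drawn around typical array values; a configured
#' fraction of samples receives one strongly inflated metric (planted
#' outliers for the Q3+3IQR rule) and genotype-QC flags fail independently at
#' a small rate.
#'
#' @param subjects Subject frame.
#' @param config A [synth_config()].
#' @return `data.table` with `sample_id`, `cohort_id`, `lrr_sd`, `baf_sd`,
#'   `waviness` and logical flags `miss_ok`, `het_ok`, `sex_ok`, `rel_ok`.
#' @export
synth_sample_metrics <- function(subjects, config) {
  set.seed(stage_seed(config, 5L))
  n <- nrow(subjects)
  m <- data.table(
    sample_id = subjects$sample_id,
    cohort_id = subjects$cohort_id,
    lrr_sd = pmax(0.02, rnorm(n, 0.12, 0.02)),
    baf_sd = pmax(0.005, rnorm(n, 0.04, 0.008)),
    waviness = pmax(0.001, rnorm(n, 0.03, 0.01))
  )
  out <- which(runif(n) < config$qc_outlier_frac)
  if (length(out)) {
    which_metric <- sample(c("lrr_sd", "baf_sd", "waviness"), length(out),
                           replace = TRUE)
    for (met in unique(which_metric)) {
      rows <- out[which_metric == met]
      m[rows, (met) := .SD[[met]] * 5, .SDcols = met]
    }
  }
  for (fl in c("miss_ok", "het_ok", "sex_ok", "rel_ok")) {
    m[, (fl) := runif(n) >= config$geno_fail_frac]
  }
  m[]
}

#' Generate a complete synthetic study
#'
#' Runs all generator stages under seeds derived from `config$seed`
#' (annotation, truth, callsets, phenotypes, sample metrics). The same
#' configuration always yields bit-identical output.
#'
#' @param config A [synth_config()].
#' @return List with `config`, `annotation`, `truth` (including `latent`),
#'   `callsets`, `subjects`, `metrics`.
#' @export
synth_study <- function(config = synth_config()) {
  ann <- synth_annotation(config)
  truth <- synth_truth(config, ann)
  callsets <- synth_callsets(truth, config, ann)
  pheno <- synth_phenotypes(truth, config, ann)
  truth$latent <- pheno$latent
  metrics <- synth_sample_metrics(pheno$subjects, config)
  list(config = config, annotation = ann, truth = truth,
       callsets = callsets, subjects = pheno$subjects, metrics = metrics)
}
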