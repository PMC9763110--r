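# Readers/writers for the plain-text formats the pipeline exchanges.
#
# Caller call tables use the PennCNV dialect: tab-separated, 1-based
# *inclusive* coordinates, integer copy-number state (0/1 deletion,
# 3/4 duplication). Internally everything is 0-based half-open, so
# start_internal = start_file - 1 and end_internal = end_file.

#' Read a PennCNV-style CNV call table
#'
#' Expects tab-separated columns `chrom`, `start`, `end` (1-based inclusive),
#' `state` (integer copy number), `n_probes`, `conf`, `sample_id`. Coordinates
#' are converted to the package-internal 0-based half-open convention and the
#' copy-number state collapsed to a `DEL`/`DUP` type.
#'
#' @param path Path to the tab-separated file.
#' @param caller Caller name recorded in the `caller` column.
#' @return A `data.table` of calls (`sample_id`, `chrom`, `start`, `end`,
#'   `type`, `n_probes`, `caller`, `conf`).
#' @export
read_penncnv <- function(path, caller = "caller") {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "start", "end", "state", "n_probes", "conf", "sample_id")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  if (any(dt$state == 2L)) stop("copy-number state 2 is not a CNV")
  dt[, `:=`(
    start = as.integer(start) - 1L,
    end = as.integer(end),
    type = ifelse(state < 2L, "DEL", "DUP"),
    caller = caller
  )]
  dt[, state := NULL]
  setcolorder(dt, c("sample_id", "chrom", "start", "end", "type", "n_probes", "caller", "conf"))
  check_calls(dt)
}

#' Write a CNV call table in PennCNV dialect
#'
#' Inverse of [read_penncnv()]: converts 0-based half-open intervals back to
#' 1-based inclusive coordinates and the type to a copy-number state
#' (`DEL` -> 1, `DUP` -> 3).
#'
#' @param calls Internal call table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_penncnv <- function(calls, path) {
  calls <- check_calls(calls)
  out <- data.table(
    chrom = calls$chrom,
    start = calls$start + 1L,
    end = calls$end,
    state = ifelse(calls$type == "DEL", 1L, 3L),
    n_probes = if ("n_probes" %in% names(calls)) calls$n_probes else NA_integer_,
    conf = if ("conf" %in% names(calls)) calls$conf else NA_real_,
    sample_id = calls$sample_id
  )
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a BED-style annotation track
#'
#' BED uses 0-based half-open coordinates, matching the internal convention,
#' so no shifting is applied. Columns beyond the third are kept under the
#' supplied names.
#'
#' @param path Path to a tab-separated BED-like file without header.
#' @param extra_cols Names for columns after `chrom`, `start`, `end`.
#' @return A `data.table` with `chrom`, `start`, `end` and any extras.
#' @export
read_bed <- function(path, extra_cols = character(0)) {
  dt <- fread(path, sep = "\t", header = FALSE)
  nms <- c("chrom", "start", "end", extra_cols)
  if (ncol(dt) < length(nms)) stop("BED file ", path, " has too few columns")
  setnames(dt, seq_along(nms), nms)
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  dt[]
}

#' Write a BED-style annotation track
#'
#' @param dt Table with `chrom`, `start`, `end` plus optional extra columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(dt, path) {
  fwrite(as.data.table(dt), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read or write the tab-separated subject/covariate table
#'
#' @param path File path.
#' @return `read_subjects()` returns a `data.table`; `write_subjects()`
#'   returns `path` invisibly.
#' @export
read_subjects <- function(path) {
  fread(path, sep = "\t", header = TRUE)
}

#' @param subjects Subject table.
#' @rdname read_subjects
#' @export
write_subjects <- function(subjects, path) {
  fwrite(as.data.table(subjects), path, sep = "\t")
  invisible(path)
}

#' Write a synthetic study bundle to plain-text fixtures
#'
#' Emits the two caller callsets (PennCNV dialect), annotation tracks (BED),
#' the subject table (TSV) and the ground truth (JSON) into a directory.
#'
#' @param study A bundle from [synth_study()].
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_penncnv(study$callsets$A, file.path(dir, "calls_callerA.tsv"))
  write_penncnv(study$callsets$B, file.path(dir, "calls_callerB.tsv"))
  ann <- study$annotation
  write_bed(ann$special, file.path(dir, "special_regions.bed"))
  write_bed(ann$segdups, file.path(dir, "segdups.bed"))
  write_bed(ann$ndd_regions[, .(chrom, start, end, label, type)],
            file.path(dir, "ndd_regions.bed"))
  write_bed(ann$genes[, .(chrom, start, end, symbol, accession)],
            file.path(dir, "genes.bed"))
  fwrite(ann$genesets, file.path(dir, "genesets.tsv"), sep = "\t")
  write_subjects(study$subjects, file.path(dir, "subjects.tsv"))
  fwrite(study$metrics, file.path(dir, "sample_metrics.tsv"), sep = "\t")
  jsonlite::write_json(
    list(
      true_betas = study$truth$true_betas,
      true_cnvs = study$truth$true_cnvs
    ),
    file.path(dir, "ground_truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
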