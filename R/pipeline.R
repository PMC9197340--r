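# End-to-end orchestration: per-sample architecture -> cohort indicators ->
# association suite, with a YAML-config front end and parameter echo.

.default_params <- list(index_threshold = 0.05, min_d_fraction = 0.5,
                        require_same_n2 = TRUE,
                        require_same_n2_evolved = FALSE,
                        min_total_reads = 20000L, strict_qc = FALSE)

#' Run the clonal-architecture pipeline over a set of samples
#'
#' For every AIRR rearrangement file: read and aggregate clonotypes, apply
#' the read-depth QC gate, run the architecture analysis; then join the
#' per-patient indicators to the covariates (when given) and run the
#' association suite. All outputs land in `out_dir`: `indicators.tsv`,
#' `groups.json`, `associations.tsv` (when covariates are given),
#' `qc.tsv` and `params.yaml` (the exact effective parameter set).
#'
#' @param samples Named character vector of AIRR TSV paths (names are patient
#'   ids; basenames up to the first dot are used when unnamed). Ignored when
#'   `config` is given.
#' @param covariates_csv Optional covariate CSV path.
#' @param out_dir Output directory.
#' @param params Named list overriding any of `index_threshold`,
#'   `min_d_fraction`, `require_same_n2`, `require_same_n2_evolved`,
#'   `min_total_reads`, `strict_qc`.
#' @param config Optional YAML file with fields `samples`, `covariates`,
#'   `out_dir`, `params`; values given there take precedence.
#' @return Invisibly, a list with `indicators`, `associations` (or `NULL`),
#'   `qc`, `results` (per-sample architecture results) and `out_dir`.
#' @export
run_pipeline <- function(samples = NULL, covariates_csv = NULL,
                         out_dir = "clonarch_out", params = list(),
                         config = NULL) {
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$samples)) samples <- unlist(cfg$samples)
    if (!is.null(cfg$covariates)) covariates_csv <- cfg$covariates
    if (!is.null(cfg$out_dir)) out_dir <- cfg$out_dir
    if (!is.null(cfg$params)) params <- utils::modifyList(params, cfg$params)
  }
  if (is.null(samples) || length(samples) == 0L) {
    stop("no input samples given")
  }
  if (!is.null(covariates_csv) && !file.exists(covariates_csv)) {
    stop("covariates file not found: ", covariates_csv)
  }
  p <- utils::modifyList(.default_params, params)
  bad <- setdiff(names(params), names(.default_params))
  if (length(bad) > 0L) stop("unknown parameter: ", bad[1L])
  if (is.null(names(samples))) {
    names(samples) <- sub("\\..*$", "", basename(samples))
  }

  results <- list(); qc_rows <- list()
  for (pid in names(samples)) {
    rr <- read_rearrangements(samples[[pid]],
                              min_total_reads = p$min_total_reads)
    qc_rows[[pid]] <- tibble::tibble(
      patient_id = pid, total_reads = rr$qc$total_reads,
      passed = rr$qc$passed, dropped_rows = rr$qc$n_dropped
    )
    if (!rr$qc$passed) {
      msg <- paste0("sample ", pid, ": ", rr$qc$total_reads,
                    " reads < ", p$min_total_reads)
      if (p$strict_qc) stop(msg) else warning(msg)
    }
    results[[pid]] <- run_architecture(
      rr$clonotypes, patient_id = pid,
      index_threshold = p$index_threshold,
      min_d_fraction = p$min_d_fraction,
      require_same_n2 = p$require_same_n2,
      require_same_n2_evolved = p$require_same_n2_evolved
    )
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_architecture_report(results, out_dir)
  qc <- dplyr::bind_rows(qc_rows)
  readr::write_tsv(qc, file.path(out_dir, "qc.tsv"), progress = FALSE)
  yaml::write_yaml(p, file.path(out_dir, "params.yaml"))

  indicators <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::as_tibble(r$indicators)
  }))
  associations <- NULL
  if (!is.null(covariates_csv)) {
    cohort <- build_cohort_table(indicators, read_covariates(covariates_csv))
    associations <- run_association_suite(cohort)
    readr::write_tsv(associations, file.path(out_dir, "associations.tsv"),
                     progress = FALSE)
  }
  invisible(list(indicators = indicators, associations = associations,
                 qc = qc, results = results, out_dir = out_dir))
}

#' Annotate raw reads into an AIRR rearrangement table
#'
#' Thin wrapper chaining [annotate_junction()] over a read table or FASTA
#' file and emitting AIRR-style rows (unassignable reads are dropped with a
#' message).
#'
#' @param reads A tibble with `read_id`, `sequence`, `duplicate_count`, or a
#'   FASTA path (then every read has `duplicate_count` 1 unless the header
#'   carries `;count=N`).
#' @param ref Germline reference.
#' @param out Optional output TSV path.
#' @param ... Passed to [annotate_junction()].
#' @return The AIRR tibble (invisibly when `out` is given).
#' @export
annotate_reads <- function(reads, ref, out = NULL, ...) {
  if (is.character(reads) && length(reads) == 1L) {
    set <- Biostrings::readDNAStringSet(reads)
    counts <- suppressWarnings(
      as.integer(sub("^.*;count=", "", names(set)))
    )
    counts[is.na(counts)] <- 1L
    reads <- tibble::tibble(read_id = sub(";.*$", "", names(set)),
                            sequence = toupper(as.character(set)),
                            duplicate_count = counts)
  }
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    dec <- tryCatch(suppressWarnings(
      annotate_junction(reads$sequence[i], ref, ...)
    ), error = function(e) NULL)
    if (is.null(dec)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sequence_id = reads$read_id[i],
      sequence = reads$sequence[i],
      v_call = dec$v_call %||% "",
      d_call = dec$d_call %||% "",
      j_call = dec$j_call,
      junction = dec$junction,
      np1 = dec$n1, np2 = dec$n2,
      duplicate_count = reads$duplicate_count[i]
    )
  }
  if (length(rows) == 0L) stop("no reads could be annotated")
  airr <- dplyr::bind_rows(rows)
  if (nrow(airr) < nrow(reads)) {
    message(nrow(reads) - nrow(airr), " read(s) unassigned and dropped")
  }
  if (!is.null(out)) {
    readr::write_tsv(airr, out, progress = FALSE)
    return(invisible(airr))
  }
  airr
}
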