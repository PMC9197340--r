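# On-disk artifacts: AIRR rearrangement tables, germline FASTA references,
# covariate CSVs and architecture reports.

#' Read an AIRR rearrangement table into a clonotype table
#'
#' Reads a tab-separated AIRR Rearrangement file, collapses rows to unique
#' clonotypes keyed by the gene-level `(v_call, d_call, j_call, junction)`
#' quadruple (allele suffixes such as `*01` are stripped for identity),
#' computes read-fraction frequencies and applies the minimum-read-depth
#' quality gate.
#'
#' Rows with an empty junction, or with ambiguity codes (non-ACGT characters)
#' in the junction, are dropped; their number is recorded in the QC record.
#'
#' @param path Path to a tab-separated file with at least the columns
#'   `sequence_id`, `junction` (or `sequence`) and `duplicate_count`;
#'   `v_call`, `d_call`, `j_call`, `np1`, `np2` are used when present.
#' @param min_total_reads Minimum summed read count for the sample to pass QC
#'   (default 20000, the usual inclusion threshold for diagnostic IgH
#'   repertoire sequencing).
#' @return A list with `clonotypes`, a tibble with one row per clonotype
#'   (columns `clonotype_id`, `v_call`, `d_call`, `j_call`, `junction`, `n1`,
#'   `d_seq`, `n2`, `reads`, `frequency`, ordered by decreasing frequency),
#'   and `qc`, a [sample_qc()] record.
#' @seealso [decomposition_from_airr()] for how `n1`/`d_seq`/`n2` are
#'   recovered from the AIRR fields.
#' @export
read_rearrangements <- function(path, min_total_reads = 20000L) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(tab) == 0L) stop("empty rearrangement file: ", path)
  if (!"junction" %in% names(tab) && "sequence" %in% names(tab)) {
    tab$junction <- tab$sequence
  }
  for (col in c("sequence_id", "junction", "duplicate_count")) {
    if (!col %in% names(tab)) {
      stop("rearrangement file lacks mandatory column '", col, "': ", path)
    }
  }
  dc <- suppressWarnings(as.numeric(tab$duplicate_count))
  bad <- which(is.na(dc) | dc != round(dc) | dc < 1)
  if (length(bad) > 0L) {
    stop("non-integer duplicate_count at row ", bad[1L],
         " (value '", tab$duplicate_count[bad[1L]], "')")
  }
  tab$duplicate_count <- as.integer(round(dc))
  # empty np cells in a present column mean empty flank, not unknown
  has_np <- c(np1 = "np1" %in% names(tab), np2 = "np2" %in% names(tab))
  for (col in c("v_call", "d_call", "j_call", "np1", "np2")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab$junction <- toupper(ifelse(is.na(tab$junction), "", tab$junction))

  keep <- nzchar(tab$junction) & is_dna(tab$junction)
  n_dropped <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no usable rearrangement rows in ", path)

  clean_call <- function(x) {
    x <- ifelse(is.na(x), "", strip_allele(x))
    x
  }
  agg <- tab |>
    dplyr::mutate(
      v_call = clean_call(.data$v_call),
      d_call = clean_call(.data$d_call),
      j_call = clean_call(.data$j_call),
      np1 = if (has_np[["np1"]]) toupper(dplyr::coalesce(.data$np1, "")) else .data$np1,
      np2 = if (has_np[["np2"]]) toupper(dplyr::coalesce(.data$np2, "")) else .data$np2
    ) |>
    dplyr::group_by(.data$v_call, .data$d_call, .data$j_call, .data$junction) |>
    dplyr::summarise(
      reads = sum(.data$duplicate_count),
      np1 = .data$np1[1L],
      np2 = .data$np2[1L],
      .groups = "drop"
    )

  total <- sum(agg$reads)
  clon <- agg |>
    dplyr::mutate(frequency = .data$reads / total) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$junction,
                   .data$v_call, .data$j_call) |>
    dplyr::mutate(clonotype_id = sprintf("c%04d", dplyr::row_number()))

  dec <- mapply(function(v, d, j, junc, np1, np2) {
    if (!nzchar(j)) {
      # no segment calls available: the whole junction is an opaque insert
      return(list(n1 = junc, d_seq = "", n2 = ""))
    }
    decomposition_from_airr(v_call = v, d_call = d, j_call = j,
                            junction = junc, np1 = np1, np2 = np2)
  }, clon$v_call, clon$d_call, clon$j_call, clon$junction, clon$np1, clon$np2,
  SIMPLIFY = FALSE)
  clon$n1 <- vapply(dec, `[[`, "", "n1")
  clon$d_seq <- vapply(dec, `[[`, "", "d_seq")
  clon$n2 <- vapply(dec, `[[`, "", "n2")

  clonotypes <- clon[, c("clonotype_id", "v_call", "d_call", "j_call",
                         "junction", "n1", "d_seq", "n2", "reads", "frequency")]
  list(
    clonotypes = tibble::as_tibble(clonotypes),
    qc = sample_qc(total, min_total_reads, n_dropped = n_dropped)
  )
}

#' Sample sequencing-depth QC record
#'
#' @param total_reads Summed read count over retained rows.
#' @param min_total_reads Pass threshold.
#' @param n_dropped Rows removed for empty/ambiguous junctions.
#' @return A list with `total_reads`, `min_total_reads`, `passed`, `n_dropped`.
#' @export
sample_qc <- function(total_reads, min_total_reads = 20000L, n_dropped = 0L) {
  list(total_reads = as.integer(total_reads),
       min_total_reads = as.integer(min_total_reads),
       passed = total_reads >= min_total_reads,
       n_dropped = as.integer(n_dropped))
}

#' Read germline V/D/J references from FASTA files
#'
#' @param v_path,d_path,j_path FASTA files, one per segment class. Record
#'   headers are used as segment names; sequences are uppercased and must be
#'   plain ACGT.
#' @return A tibble with columns `name`, `segment_class` (`"V"`, `"D"` or
#'   `"J"`) and `sequence`.
#' @export
read_germline_fasta <- function(v_path, d_path, j_path) {
  read_one <- function(path, class) {
    # read as raw strings: reading as DNA would silently drop invalid
    # letters instead of letting us reject them
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty FASTA: ", path)
    seqs <- toupper(as.character(set))
    names(seqs) <- sub("\\s.*$", "", names(set))
    bad <- which(!is_dna(seqs) | !nzchar(seqs))
    if (length(bad) > 0L) {
      stop("non-ACGT or empty sequence in record '", names(seqs)[bad[1L]],
           "' of ", path)
    }
    if (anyDuplicated(names(seqs))) {
      stop("duplicate segment name '",
           names(seqs)[duplicated(names(seqs))][1L], "' in ", path)
    }
    tibble::tibble(name = names(seqs), segment_class = class,
                   sequence = unname(seqs))
  }
  ref <- dplyr::bind_rows(read_one(v_path, "V"), read_one(d_path, "D"),
                          read_one(j_path, "J"))
  if (anyDuplicated(ref$name)) {
    stop("segment names must be unique across classes; duplicated: ",
         ref$name[duplicated(ref$name)][1L])
  }
  ref
}

.covariate_levels <- list(
  sex = c("male", "female"),
  cns = c("CNS-1", "CNS-2/TLP+"),
  nci_risk = c("standard", "high"),
  eortc_risk = c("VLR", "AR1", "AR2", "VHR"),
  genetic_type = c("ETV6_RUNX1", "hyperdiploidy", "other")
)

#' Read a patient-covariate CSV
#'
#' Expected header: `patient_id,sex,age_years,wbc,cns,nci_risk,eortc_risk,
#' genetic_type`. Levels are validated; blank cells are allowed (and read as
#' missing) for `cns` and `genetic_type` only. The ordinal EORTC risk group is
#' returned both as the label and as its fixed integer coding
#' (VLR=1, AR1=2, AR2=3, VHR=4) in `eortc_risk_ord`.
#'
#' @param path CSV file path.
#' @return A tibble with one validated row per patient.
#' @export
read_covariates <- function(path) {
  cov <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    sex = readr::col_character(),
    age_years = readr::col_double(),
    wbc = readr::col_double(),
    cns = readr::col_character(),
    nci_risk = readr::col_character(),
    eortc_risk = readr::col_character(),
    genetic_type = readr::col_character()
  ), progress = FALSE)
  if (nrow(cov) == 0L) stop("empty covariate file: ", path)
  if (anyDuplicated(cov$patient_id)) {
    stop("duplicate patient_id: ", cov$patient_id[duplicated(cov$patient_id)][1L])
  }
  check_levels <- function(col, allow_missing) {
    vals <- cov[[col]]
    missing <- is.na(vals) | !nzchar(trimws(ifelse(is.na(vals), "", vals)))
    if (any(missing) && !allow_missing) {
      stop("missing value not allowed for '", col, "' (row ",
           which(missing)[1L], ")")
    }
    bad <- which(!missing & !vals %in% .covariate_levels[[col]])
    if (length(bad) > 0L) {
      stop("unknown level '", vals[bad[1L]], "' for '", col, "' at row ",
           bad[1L])
    }
    ifelse(missing, NA_character_, vals)
  }
  cov$sex <- check_levels("sex", allow_missing = FALSE)
  cov$cns <- check_levels("cns", allow_missing = TRUE)
  cov$nci_risk <- check_levels("nci_risk", allow_missing = FALSE)
  cov$eortc_risk <- check_levels("eortc_risk", allow_missing = FALSE)
  cov$genetic_type <- check_levels("genetic_type", allow_missing = TRUE)
  if (any(is.na(cov$age_years) | cov$age_years < 0)) stop("invalid age_years")
  if (any(is.na(cov$wbc) | cov$wbc < 0)) stop("invalid wbc")
  cov$eortc_risk_ord <- match(cov$eortc_risk, .covariate_levels$eortc_risk)
  cov
}

#' Write (and re-read) an architecture report
#'
#' Emits a per-patient TSV of the complexity indicators and a JSON detail
#' file listing each foster group's stem, member clonotypes and evolved-clone
#' count. [read_architecture_report()] restores both losslessly.
#'
#' @param results A named list, one element per patient, each as returned by
#'   [run_architecture()] (fields `indicators` and `groups`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`indicators`, `detail`).
#' @export
write_architecture_report <- function(results, dir) {
  if (length(results) == 0L) stop("empty results: nothing to report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ind <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::as_tibble(r$indicators)
  }))
  ind_path <- file.path(dir, "indicators.tsv")
  readr::write_tsv(ind, ind_path, progress = FALSE)

  detail <- lapply(results, function(r) {
    lapply(r$groups, function(g) {
      list(group_id = g$group_id,
           stem = list(d_call = g$stem$d_call, stem_seq = g$stem$stem_seq,
                       n2 = g$stem$n2, j_gene = g$stem$j_gene),
           index_members = as.list(g$index_members),
           evolved_members = as.list(g$evolved_members),
           n_evolved = g$n_evolved)
    })
  })
  detail_path <- file.path(dir, "groups.json")
  jsonlite::write_json(detail, detail_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(indicators = ind_path, detail = detail_path))
}

#' @rdname write_architecture_report
#' @export
read_architecture_report <- function(dir) {
  ind <- readr::read_tsv(file.path(dir, "indicators.tsv"),
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           .default = readr::col_integer()
                         ), progress = FALSE)
  detail <- jsonlite::read_json(file.path(dir, "groups.json"))
  groups <- lapply(detail, function(pat) {
    lapply(pat, function(g) {
      list(group_id = g$group_id,
           stem = list(d_call = g$stem$d_call, stem_seq = g$stem$stem_seq,
                       n2 = g$stem$n2, j_gene = g$stem$j_gene),
           index_members = unlist(g$index_members, use.names = FALSE),
           evolved_members = unlist(g$evolved_members, use.names = FALSE),
           n_evolved = as.integer(g$n_evolved))
    })
  })
  list(indicators = ind, groups = groups)
}

#' Write a clonotype table as an AIRR rearrangement TSV
#'
#' Inverse of [read_rearrangements()] for simulator output and intermediate
#' artifacts: one row per clonotype, `duplicate_count` carrying the read
#' count, `np1`/`np2` carrying the junction decomposition.
#'
#' @param clonotypes Clonotype tibble (needs `v_call`, `d_call`, `j_call`,
#'   `junction`, `n1`, `n2`, `reads`).
#' @param path Output file path.
#' @export
write_rearrangements <- function(clonotypes, path) {
  out <- tibble::tibble(
    sequence_id = clonotypes$clonotype_id,
    v_call = clonotypes$v_call,
    d_call = clonotypes$d_call,
    j_call = clonotypes$j_call,
    junction = clonotypes$junction,
    np1 = clonotypes$n1,
    np2 = clonotypes$n2,
    duplicate_count = clonotypes$reads
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
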