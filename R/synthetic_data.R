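# Ground-truth simulator: leukemic IgH repertoires with 1-4 independent
# foster lineages, VH-replacement-derived evolved clones sharing the
# ancestral D-N2-J stem, a polyclonal background, and read-count sampling;
# plus cohort covariates with the marginal structure of a published
# 105-patient pediatric BCP-ALL cohort.
#
# Segment pools are shortened relative to biological scale (V 60 nt, D 18 nt,
# J 40 nt): what the tests need is behaviour under the stem-matching
# predicate, not biological fidelity.

#' Generate a random germline V/D/J segment pool
#'
#' Segments are uniform random ACGT strings. D segments are drawn by
#' rejection so that no two germline Ds share a common contiguous substring
#' of `min_d_match` or longer; retained D regions from different germline Ds
#' can then never satisfy the stem predicate, which makes lineage membership
#' unambiguous in simulated data.
#'
#' @param n_v,n_d,n_j Pool sizes (defaults 20/10/6).
#' @param v_len,d_len,j_len Segment lengths in nt (defaults 60/18/40).
#' @param min_d_match The annotation D-match floor the pool must stay under
#'   (default 5).
#' @param seed Optional integer seed for reproducibility.
#' @param max_tries Rejection-sampling bound per D segment.
#' @return A germline reference tibble (`name`, `segment_class`, `sequence`).
#' @export
generate_germline_pool <- function(n_v = 20L, n_d = 10L, n_j = 6L,
                                   v_len = 60L, d_len = 18L, j_len = 40L,
                                   min_d_match = 5L, seed = NULL,
                                   max_tries = 1000L) {
  if (n_v < 1L || n_d < 1L || n_j < 1L) stop("pool sizes must be >= 1")
  if (d_len < 2L * min_d_match) {
    stop("d_len must be at least 2 * min_d_match for usable stems")
  }
  if (!is.null(seed)) set.seed(seed)
  vs <- vapply(seq_len(n_v), function(i) random_dna(v_len), "")
  js <- vapply(seq_len(n_j), function(i) random_dna(j_len), "")
  ds <- character(0)
  for (i in seq_len(n_d)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- random_dna(d_len)
      if (all(vapply(ds, function(d) lcs_length(cand, d), 0L) < min_d_match)) {
        ds <- c(ds, cand); ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("could not draw ", n_d, " D segments of length ", d_len,
           " with pairwise shared substrings < ", min_d_match,
           "; enlarge d_len or reduce n_d")
    }
  }
  tibble::tibble(
    name = c(sprintf("V%02d", seq_len(n_v)), sprintf("D%02d", seq_len(n_d)),
             sprintf("J%d", seq_len(n_j))),
    segment_class = rep(c("V", "D", "J"), c(n_v, n_d, n_j)),
    sequence = c(vs, ds, js)
  )
}

# One simulated clonotype: a V part, N1, retained D (suffix of the lineage's
# retained D after extra 5' trimming), N2 and J part.
.make_member <- function(ref_v, lineage, extra_trim, n1_len, n2,
                         j_trim, v_idx, v_trim) {
  v_seq <- ref_v$sequence[v_idx]
  v_part <- substr(v_seq, 1L, nchar(v_seq) - v_trim)
  d_seq <- substr(lineage$d_retained, extra_trim + 1L,
                  nchar(lineage$d_retained))
  n1 <- random_dna(n1_len)
  j_part <- substr(lineage$j_seq, 1L, nchar(lineage$j_seq) - j_trim)
  list(v_call = ref_v$name[v_idx], d_call = lineage$d_call,
       j_call = lineage$j_call, n1 = n1, d_seq = d_seq, n2 = n2,
       junction = paste0(n1, d_seq, n2),
       sequence = paste0(v_part, n1, d_seq, n2, j_part))
}

#' Simulate one leukemic IgH repertoire with known architecture
#'
#' Each lineage gets a distinct germline D and a J, trimmed at both D ends
#' (at most `n_trim_max` nt per end) plus a random N2 — the lineage stem. The
#' founder joins a random trimmed V through a random N1. Evolved members are
#' generated by VH replacement: a new V and N1, the founder's retained D with
#' additional 5' trimming never exceeding half its length (so every member
#' honours the half-of-D rule against the founder), N2 kept identical for
#' index-level members and perturbed with probability `p_perturb_n2` for
#' sub-threshold members ("partly the same stem"). Polyclonal background
#' clonotypes are drawn by rejection so that none matches any lineage stem
#' under the relaxed predicate. Frequencies give every founder at least 7% of
#' reads, evolved members well under the 5% index threshold, and the
#' background `background_mass` in total; read counts are apportioned
#' deterministically (largest remainder) or by multinomial sampling.
#'
#' @param ref Germline pool from [generate_germline_pool()].
#' @param n_foster_lineages Number of independent foster lineages (1-4).
#' @param evolved_per_lineage Integer vector, one entry per lineage: the
#'   lineage's total evolved-clone count including the founder itself.
#' @param extra_index_per_lineage How many evolved members per lineage are
#'   promoted to index-level frequency (default 0; these keep the exact N2).
#' @param background_clonotypes,background_mass Size and total read fraction
#'   of the polyclonal background.
#' @param total_reads Total reads to apportion (default 20000).
#' @param n_trim_max,n_add_max Maximum exonuclease trimming per end and
#'   maximum N-nucleotides per junction.
#' @param p_perturb_n2 Probability a sub-threshold evolved member's N2 is
#'   resampled.
#' @param sample_reads `FALSE` (default) for deterministic largest-remainder
#'   counts; `TRUE` for multinomial sampling (clonotypes drawn 0 times are
#'   dropped).
#' @param emit_reads Also emit per-read FASTA-style records whose annotation
#'   by [annotate_junction()] is guaranteed (by rejection) to reproduce the
#'   generating decomposition.
#' @param patient_id Identifier recorded in the ground truth.
#' @param seed Optional integer seed.
#' @return A list with `clonotypes` (pipeline-ready tibble), `truth`
#'   (lineage stems, member junctions, expected indicators), and `reads`
#'   (tibble or `NULL`).
#' @export
simulate_leukemic_repertoire <- function(ref, n_foster_lineages = 2L,
                                         evolved_per_lineage = c(5L, 3L),
                                         extra_index_per_lineage = 0L,
                                         background_clonotypes = 150L,
                                         background_mass = 0.3,
                                         total_reads = 20000L,
                                         n_trim_max = 4L, n_add_max = 6L,
                                         p_perturb_n2 = 0.3,
                                         sample_reads = FALSE,
                                         emit_reads = FALSE,
                                         patient_id = "sim",
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_foster_lineages < 1L) stop("n_foster_lineages must be >= 1")
  if (length(evolved_per_lineage) != n_foster_lineages) {
    stop("evolved_per_lineage must have one entry per lineage")
  }
  if (any(evolved_per_lineage < 1L)) {
    stop("evolved counts include the founder and must be >= 1")
  }
  if (background_mass < 0 || background_mass >= 0.5) {
    stop("background_mass must be in [0, 0.5)")
  }
  extra_index <- rep_len(as.integer(extra_index_per_lineage),
                         n_foster_lineages)
  if (any(extra_index > evolved_per_lineage - 1L)) {
    stop("extra_index_per_lineage must leave room within evolved_per_lineage")
  }
  ref_v <- ref[ref$segment_class == "V", , drop = FALSE]
  ref_d <- ref[ref$segment_class == "D", , drop = FALSE]
  ref_j <- ref[ref$segment_class == "J", , drop = FALSE]
  if (nrow(ref_d) < n_foster_lineages) {
    stop("need at least one distinct germline D per lineage")
  }

  min_j_keep <- 5L
  d_idx <- sample.int(nrow(ref_d), n_foster_lineages)
  lineages <- lapply(seq_len(n_foster_lineages), function(l) {
    d_full <- ref_d$sequence[d_idx[l]]
    # keep >= 10 nt so members trimmed to half still clear the 5 nt D floor;
    # when a 3' trim leaves germline sequence beyond the retained D, the N2
    # must not begin with that next germline base, or annotation would
    # always extend the D match into N2 and closure could never hold
    repeat {
      t5 <- sample(0:n_trim_max, 1L); t3 <- sample(0:n_trim_max, 1L)
      if (nchar(d_full) - t5 - t3 < 10L) next
      n2 <- random_dna(sample(1:n_add_max, 1L))
      if (t3 == 0L ||
          substr(n2, 1L, 1L) != substr(d_full, nchar(d_full) - t3 + 1L,
                                       nchar(d_full) - t3 + 1L)) break
    }
    j_idx <- sample.int(nrow(ref_j), 1L)
    list(d_call = ref_d$name[d_idx[l]],
         d_retained = substr(d_full, t5 + 1L, nchar(d_full) - t3),
         j_call = ref_j$name[j_idx],
         j_seq = ref_j$sequence[j_idx],
         n2 = n2)
  })

  draw_member <- function(lineage, index_level) {
    n2 <- if (index_level || stats::runif(1) > p_perturb_n2) lineage$n2
          else random_dna(sample(1:n_add_max, 1L))
    .make_member(ref_v, lineage,
                 extra_trim = sample(0:(nchar(lineage$d_retained) %/% 2L), 1L),
                 n1_len = sample(0:n_add_max, 1L), n2 = n2,
                 j_trim = sample(0:min(n_trim_max,
                                       nchar(lineage$j_seq) - min_j_keep), 1L),
                 v_idx = sample.int(nrow(ref_v), 1L),
                 v_trim = sample(0:n_trim_max, 1L))
  }

  # With emit_reads the raw read must annotate back to exactly the
  # generating decomposition (no accidental anchor overextension), enforced
  # by rejection here so downstream closure holds with probability 1.
  annotates_cleanly <- function(m) {
    if (!emit_reads) return(TRUE)
    dec <- tryCatch(suppressWarnings(annotate_junction(m$sequence, ref)),
                    error = function(e) NULL)
    if (is.null(dec)) return(FALSE)
    has_d <- !is.na(m$d_call %||% NA_character_)
    identical(dec$v_call, m$v_call) &&
      identical(dec$j_call, m$j_call) &&
      identical(dec$d_call %||% NA_character_,
                if (has_d) m$d_call else NA_character_) &&
      identical(dec$n1, if (has_d) m$n1 else m$junction) &&
      identical(dec$d_seq, if (has_d) m$d_seq else "") &&
      identical(dec$n2, if (has_d) m$n2 else "")
  }

  members <- list(); member_key <- character(0)
  roles <- character(0); lineage_of <- integer(0); freq_raw <- numeric(0)
  add_member <- function(m, role, l, fr) {
    key <- paste(m$v_call, m$d_call, m$j_call, m$junction, sep = "|")
    if (key %in% member_key || !annotates_cleanly(m)) return(FALSE)
    members[[length(members) + 1L]] <<- m
    member_key <<- c(member_key, key)
    roles <<- c(roles, role); lineage_of <<- c(lineage_of, l)
    freq_raw <<- c(freq_raw, fr)
    TRUE
  }

  for (l in seq_len(n_foster_lineages)) {
    lineage <- lineages[[l]]
    f_tries <- 0L
    repeat {
      f_tries <- f_tries + 1L
      if (f_tries > 1000L) stop("cannot construct a clean founder")
      founder <- .make_member(ref_v, lineage, extra_trim = 0L,
                              n1_len = sample(0:n_add_max, 1L),
                              n2 = lineage$n2,
                              j_trim = sample(0:min(n_trim_max,
                                                    nchar(lineage$j_seq) - min_j_keep), 1L),
                              v_idx = sample.int(nrow(ref_v), 1L),
                              v_trim = sample(0:n_trim_max, 1L))
      if (add_member(founder, "founder", l, stats::runif(1, 0.07, 0.10))) break
    }
    n_index_extra <- extra_index[l]
    n_sub <- evolved_per_lineage[l] - 1L - n_index_extra
    made <- 0L; tries <- 0L
    while (made < n_index_extra) {
      if (add_member(draw_member(lineage, TRUE), "index_evolved", l,
                     stats::runif(1, 0.055, 0.07))) made <- made + 1L
      tries <- tries + 1L
      if (tries > 1000L * n_index_extra) stop("cannot draw distinct members")
    }
    made <- 0L; tries <- 0L
    while (made < n_sub) {
      if (add_member(draw_member(lineage, FALSE), "evolved", l,
                     stats::runif(1, 2, 20) / total_reads)) made <- made + 1L
      tries <- tries + 1L
      if (tries > 1000L * n_sub) stop("cannot draw distinct members")
    }
  }

  # background: rejected against every lineage stem under the relaxed
  # predicate so none can ever be counted as evolved
  stems_fields <- lapply(lineages, function(l) {
    .stem_fields(list(j_call = l$j_call, n1 = "", d_seq = l$d_retained,
                      n2 = l$n2))
  })
  n_bg <- 0L
  while (n_bg < background_clonotypes) {
    ok <- FALSE
    for (try in 1:100) {
      use_d <- stats::runif(1) > 0.2
      l_bg <- list(d_call = if (use_d) ref_d$name[sample.int(nrow(ref_d), 1L)]
                            else NA_character_,
                   d_retained = "", j_call = "", j_seq = "", n2 = "")
      j_idx <- sample.int(nrow(ref_j), 1L)
      l_bg$j_call <- ref_j$name[j_idx]; l_bg$j_seq <- ref_j$sequence[j_idx]
      if (use_d) {
        d_full <- ref_d$sequence[match(l_bg$d_call, ref_d$name)]
        t5 <- sample(0:n_trim_max, 1L); t3 <- sample(0:n_trim_max, 1L)
        l_bg$d_retained <- substr(d_full, t5 + 1L,
                                  max(t5 + 5L, nchar(d_full) - t3))
        l_bg$n2 <- random_dna(sample(0:n_add_max, 1L))
      }
      m <- .make_member(ref_v, l_bg,
                        extra_trim = 0L,
                        n1_len = sample(1:(2L * n_add_max), 1L),
                        n2 = l_bg$n2,
                        j_trim = sample(0:min(n_trim_max,
                                              nchar(l_bg$j_seq) - min_j_keep), 1L),
                        v_idx = sample.int(nrow(ref_v), 1L),
                        v_trim = sample(0:n_trim_max, 1L))
      if (!use_d) m$d_call <- NA_character_
      fc <- .stem_fields(m)
      clash <- any(vapply(stems_fields, function(sf) {
        fc$j_gene == sf$j_gene && .stem_overlap(fc, sf, 0.5)$ok
      }, TRUE))
      if (!clash && add_member(m, "background", 0L, NA_real_)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not draw a non-matching background clonotype")
    n_bg <- n_bg + 1L
  }

  # frequency budget: leukemic clones rescaled to 1 - background_mass
  leuk <- which(roles != "background")
  s <- sum(freq_raw[leuk])
  r <- (1 - background_mass) / s
  freq <- freq_raw
  freq[leuk] <- freq_raw[leuk] * r
  if (any(roles == "founder" & freq < 0.07 - 1e-12) ||
      any(roles == "index_evolved" & freq < 0.05 - 1e-12)) {
    stop("frequency budget infeasible: founder mass + background_mass ",
         "leave index-level clones below their frequency floor")
  }
  if (any(roles %in% c("evolved") & freq >= 0.05)) {
    stop("frequency budget infeasible: evolved members reach the index ",
         "threshold")
  }
  if (background_clonotypes > 0L) {
    # moderate-variance weights so no background clone can reach the index
    # threshold; the worst-case share is 1.5 / (1.5 + 0.5 (n - 1))
    max_share <- 1.5 / (1.5 + 0.5 * (background_clonotypes - 1L))
    if (max_share * background_mass >= 0.045) {
      stop("frequency budget infeasible: background_mass spread over only ",
           background_clonotypes, " clonotypes could create index-level ",
           "background clones; increase background_clonotypes or reduce ",
           "background_mass")
    }
    w <- stats::runif(background_clonotypes, 0.5, 1.5)
    freq[roles == "background"] <- w / sum(w) * background_mass
  }

  counts <- if (sample_reads) {
    as.integer(stats::rmultinom(1L, total_reads, freq))
  } else {
    largest_remainder_round(freq, total_reads)
  }
  emitted <- which(counts > 0L)

  clon <- tibble::tibble(
    clonotype_id = sprintf("s%04d", seq_along(emitted)),
    sequence = vapply(members[emitted], `[[`, "", "sequence"),
    v_call = vapply(members[emitted], `[[`, "", "v_call"),
    d_call = vapply(members[emitted], function(m) m$d_call %||% "", ""),
    j_call = vapply(members[emitted], `[[`, "", "j_call"),
    junction = vapply(members[emitted], `[[`, "", "junction"),
    n1 = vapply(members[emitted], `[[`, "", "n1"),
    d_seq = vapply(members[emitted], function(m) {
      if (is.na(m$d_call %||% NA_character_)) "" else m$d_seq
    }, ""),
    n2 = vapply(members[emitted], function(m) {
      if (is.na(m$d_call %||% NA_character_)) "" else m$n2
    }, ""),
    reads = counts[emitted],
    frequency = counts[emitted] / sum(counts[emitted]),
    role = roles[emitted],
    lineage = lineage_of[emitted]
  )
  clon <- clon[order(-clon$frequency, clon$junction), , drop = FALSE]
  clon$clonotype_id <- sprintf("s%04d", seq_len(nrow(clon)))

  n_index_true <- n_foster_lineages + sum(extra_index)
  truth <- list(
    patient_id = patient_id,
    seed = seed,
    lineages = lapply(seq_len(n_foster_lineages), function(l) {
      list(d_call = lineages[[l]]$d_call,
           d_retained = lineages[[l]]$d_retained,
           n2 = lineages[[l]]$n2, j_call = lineages[[l]]$j_call,
           member_junctions = clon$junction[clon$lineage == l])
    }),
    expected = list(
      n_index = n_index_true,
      n_foster = n_foster_lineages,
      max_evolved = max(evolved_per_lineage),
      total_evolved = sum(evolved_per_lineage)
    )
  )

  reads_tab <- NULL
  if (emit_reads) {
    reads_tab <- tibble::tibble(
      read_id = clon$clonotype_id,
      sequence = clon$sequence,
      duplicate_count = clon$reads
    )
  }
  clon$sequence <- NULL

  list(clonotypes = clon, truth = truth, reads = reads_tab)
}

# Marginal covariate structure of the reference 105-patient pediatric
# BCP-ALL cohort (counts per level; NA = missing).
.default_cohort_margins <- list(
  sex = c(male = 60, female = 45),
  age_years = c("1to5" = 63, "5to10" = 25, "10plus" = 17),
  wbc = c("lt10" = 55, "10to50" = 35, "ge50" = 15),
  cns = c("CNS-1" = 92, "CNS-2/TLP+" = 11, missing = 2),
  nci_risk = c(standard = 75, high = 30),
  eortc_risk = c(VLR = 23, AR1 = 63, AR2 = 9, VHR = 10),
  genetic_type = c(ETV6_RUNX1 = 27, hyperdiploidy = 39, other = 35,
                   missing = 4)
)

# Expand margin counts (possibly stated for another cohort size) to exactly
# n patients and shuffle.
.expand_margin <- function(counts, n) {
  k <- largest_remainder_round(counts, n)
  sample(rep(names(counts), k))
}

#' Simulate cohort covariates and ground-truth indicators
#'
#' Draws per-patient clinical covariates with the marginal structure of the
#' reference cohort (each covariate independently permuted, so covariates are
#' mutually independent), and per-patient complexity indicators. Under the
#' null (default) the indicators are independent of every covariate:
#' `n_foster` is drawn from the reference marginal distribution
#' (29/58/17/1 of 105 for 1-4 foster clones) and `max_evolved` from a
#' discretised log-normal with median 9, matching the reference cohort's
#' scale (range capped at 1500). Effects are injected on top:
#' `evolved_multiplier` scales `max_evolved` for patients of a given genetic
#' type; `foster_delta` shifts `n_foster` (clamped to at least 1) for given
#' EORTC risk levels.
#'
#' In `mode = "repertoires"` a full AIRR rearrangement file is additionally
#' simulated per patient (with `n_foster` lineages and small evolved counts)
#' and written under `out_dir` together with the covariate CSV and a truth
#' JSON, giving an end-to-end testbed.
#'
#' @param n_patients Cohort size (default 105).
#' @param margins Named list of covariate margin counts; defaults to the
#'   reference cohort structure.
#' @param evolved_multiplier Named numeric vector by genetic type, e.g.
#'   `c(ETV6_RUNX1 = 10)`; empty for the null.
#' @param foster_delta Named integer vector by EORTC risk level; empty for
#'   the null.
#' @param mode `"indicators"` (fast, indicator-level) or `"repertoires"`
#'   (writes per-patient AIRR files).
#' @param out_dir Output directory, required for `mode = "repertoires"`.
#' @param ref Germline pool for repertoire mode (generated if `NULL`).
#' @param total_reads,sample_reads Passed to the repertoire simulator.
#' @param seed Optional integer seed.
#' @return A list with `covariates` (tibble, includes `eortc_risk_ord`),
#'   `indicators` (tibble of true per-patient indicators), and in repertoire
#'   mode `files` (per-patient AIRR paths), `covariates_csv`, `truth_json`.
#' @export
simulate_cohort <- function(n_patients = 105L,
                            margins = .default_cohort_margins,
                            evolved_multiplier = c(),
                            foster_delta = c(),
                            mode = c("indicators", "repertoires"),
                            out_dir = NULL, ref = NULL,
                            total_reads = 20000L, sample_reads = FALSE,
                            seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (length(evolved_multiplier) > 0 &&
      !all(names(evolved_multiplier) %in%
           names(margins$genetic_type))) {
    stop("evolved_multiplier names must be genetic-type levels")
  }
  if (length(foster_delta) > 0 &&
      !all(names(foster_delta) %in% names(margins$eortc_risk))) {
    stop("foster_delta names must be EORTC risk levels")
  }

  age_bin <- .expand_margin(margins$age_years, n_patients)
  wbc_bin <- .expand_margin(margins$wbc, n_patients)
  cns <- .expand_margin(margins$cns, n_patients)
  gen <- .expand_margin(margins$genetic_type, n_patients)
  cov <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    sex = .expand_margin(margins$sex, n_patients),
    age_years = ifelse(age_bin == "1to5", stats::runif(n_patients, 1, 5),
                ifelse(age_bin == "5to10", stats::runif(n_patients, 5, 10),
                       stats::runif(n_patients, 10, 18))),
    wbc = ifelse(wbc_bin == "lt10", stats::runif(n_patients, 0.5, 10),
          ifelse(wbc_bin == "10to50", stats::runif(n_patients, 10, 50),
                 stats::runif(n_patients, 50, 400))),
    cns = ifelse(cns == "missing", NA_character_, cns),
    nci_risk = .expand_margin(margins$nci_risk, n_patients),
    eortc_risk = .expand_margin(margins$eortc_risk, n_patients),
    genetic_type = ifelse(gen == "missing", NA_character_, gen)
  )
  cov$eortc_risk_ord <- match(cov$eortc_risk, names(margins$eortc_risk))

  # null indicator draws: foster count from the reference marginal,
  # evolved count log-normal around the reference median
  foster_probs <- c(29, 58, 17, 1) / 105
  n_foster <- sample(1:4, n_patients, replace = TRUE, prob = foster_probs)
  max_evolved <- pmin(pmax(round(stats::rlnorm(n_patients, log(9), 1.4)), 1L),
                      1500L)
  for (lev in names(evolved_multiplier)) {
    hit <- !is.na(cov$genetic_type) & cov$genetic_type == lev
    max_evolved[hit] <- pmax(round(max_evolved[hit] *
                                     evolved_multiplier[[lev]]), 1L)
  }
  for (lev in names(foster_delta)) {
    hit <- cov$eortc_risk == lev
    n_foster[hit] <- pmax(n_foster[hit] + foster_delta[[lev]], 1L)
  }
  ind <- tibble::tibble(patient_id = cov$patient_id,
                        n_foster = as.integer(n_foster),
                        max_evolved = as.integer(max_evolved))

  if (mode == "indicators") {
    return(list(covariates = cov, indicators = ind))
  }

  if (is.null(out_dir)) stop("out_dir is required for repertoire mode")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(ref)) ref <- generate_germline_pool()
  files <- character(n_patients)
  truth <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    nf <- min(ind$n_foster[i], 4L)
    epl <- pmin(1L + stats::rpois(nf, 3), 30L)
    epl[sample.int(nf, 1L)] <- min(ind$max_evolved[i], 30L)
    sim <- simulate_leukemic_repertoire(
      ref, n_foster_lineages = nf, evolved_per_lineage = epl,
      background_clonotypes = 50L, total_reads = total_reads,
      sample_reads = sample_reads, patient_id = cov$patient_id[i]
    )
    files[i] <- file.path(out_dir,
                          paste0(cov$patient_id[i], ".airr.tsv"))
    write_rearrangements(sim$clonotypes, files[i])
    truth[[i]] <- sim$truth
    ind$n_foster[i] <- sim$truth$expected$n_foster
    ind$max_evolved[i] <- sim$truth$expected$max_evolved
  }
  cov_csv <- file.path(out_dir, "covariates.csv")
  readr::write_csv(cov[, c("patient_id", "sex", "age_years", "wbc", "cns",
                           "nci_risk", "eortc_risk", "genetic_type")],
                   cov_csv, na = "", progress = FALSE)
  truth_json <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(indicators = ind, lineages = truth), truth_json,
                       auto_unbox = TRUE, pretty = TRUE)
  list(covariates = cov, indicators = ind, files = files,
       covariates_csv = cov_csv, truth_json = truth_json)
}
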