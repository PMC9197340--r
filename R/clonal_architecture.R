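# Core computation: index-clone calling, foster-clone grouping by the D-N2-J
# stem, evolved-clone counting, and the two per-patient complexity indicators.
#
# Terminology (VH replacement model): a secondary rearrangement can replace
# the V segment of an existing VDJ join while retaining its D-J core. Index
# clones sharing a D-N2-J stem but differing in V and N1 are therefore read
# as descendants of one ancestral ("foster") rearrangement; any clonotype
# sharing all or part of the D-J stem, regardless of frequency, counts as an
# evolved clone of that lineage.

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L || is.na(x)) y else x

#' Call index clones at a read-fraction threshold
#'
#' An index clone is a clonotype whose read fraction is at least `threshold`
#' (inclusive) of the sample's reads; the conventional threshold is 5%.
#'
#' @param clonotypes Clonotype tibble with `frequency` computed (see
#'   [read_rearrangements()]).
#' @param threshold Read-fraction cutoff in `(0, 1]`, default `0.05`.
#' @return The index-clone rows, ordered by decreasing frequency (ties by
#'   `clonotype_id`).
#' @export
call_index_clones <- function(clonotypes, threshold = 0.05) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single number in (0, 1]")
  }
  idx <- clonotypes[clonotypes$frequency >= threshold, , drop = FALSE]
  idx[order(-idx$frequency, idx$clonotype_id), , drop = FALSE]
}

# Uniform view of a clonotype row / decomposition for the stem predicates.
.stem_fields <- function(x) {
  d_seq <- x$d_seq %||% ""
  n1 <- x$n1 %||% ""
  n2 <- x$n2 %||% ""
  list(j_gene = strip_allele(x$j_call %||% ""),
       n2 = n2, d_seq = d_seq,
       has_d = nzchar(d_seq),
       insert = paste0(n1, d_seq, n2))
}

#' Test whether two rearrangements share a D-N2-J stem
#'
#' The foster-clone relation: both rearrangements use the same J gene, carry
#' an identical N2 insertion (when `require_same_n2`), and show D-region
#' evidence of common origin: the longest common contiguous substring of
#' their retained D regions covers at least `min_d_fraction` of the shorter
#' one. When either rearrangement has no identifiable D, the fallback
#' compares the full V-J insert strings instead, requiring a J-side-anchored
#' (common suffix) overlap of at least `min_d_fraction` of the shorter
#' insert. The predicate is symmetric and reflexive.
#'
#' @param a,b `junction_decomposition` objects, clonotype-table rows, or any
#'   lists carrying `j_call`, `n1`, `d_seq`, `n2`.
#' @param min_d_fraction Minimum shared fraction of the shorter D (or, in the
#'   no-D fallback, of the shorter N insert); default `0.5`.
#' @param require_same_n2 Require identical N2 (default `TRUE`, the strict
#'   foster relation; relaxed for evolved-clone matching).
#' @return `TRUE` or `FALSE`.
#' @export
stem_match_foster <- function(a, b, min_d_fraction = 0.5,
                              require_same_n2 = TRUE) {
  fa <- .stem_fields(a); fb <- .stem_fields(b)
  if (!nzchar(fa$j_gene) || !nzchar(fb$j_gene)) return(FALSE)
  if (fa$j_gene != fb$j_gene) return(FALSE)
  if (require_same_n2 && !identical(fa$n2, fb$n2)) return(FALSE)
  .stem_overlap(fa, fb, min_d_fraction)$ok
}

# Shared overlap computation: D branch when both sides carry a D, J-anchored
# insert-suffix branch otherwise. Returns the overlap length and whether it
# clears the fractional threshold.
.stem_overlap <- function(fa, fb, min_d_fraction = 0.5) {
  if (fa$has_d && fb$has_d) {
    need <- ceiling(min_d_fraction * min(nchar(fa$d_seq), nchar(fb$d_seq)))
    got <- lcs_length(fa$d_seq, fb$d_seq)
  } else {
    need <- ceiling(min_d_fraction * min(nchar(fa$insert), nchar(fb$insert)))
    got <- common_suffix_length(fa$insert, fb$insert)
  }
  list(ok = got >= need, overlap = got)
}

.row_as_list <- function(clonotypes, i) {
  list(clonotype_id = clonotypes$clonotype_id[i],
       v_call = clonotypes$v_call[i], d_call = clonotypes$d_call[i],
       j_call = clonotypes$j_call[i], junction = clonotypes$junction[i],
       n1 = clonotypes$n1[i], d_seq = clonotypes$d_seq[i],
       n2 = clonotypes$n2[i], frequency = clonotypes$frequency[i])
}

#' Group index clones into foster-clone families
#'
#' Partitions the index clones into connected components of the
#' [stem_match_foster()] relation (transitive closure over the pairwise match
#' graph). Each family's representative stem is taken from its
#' highest-frequency member; families are numbered in order of decreasing
#' top-member frequency, so grouping is deterministic and invariant to input
#' order.
#'
#' @param index_clones Output of [call_index_clones()].
#' @param min_d_fraction,require_same_n2 Passed to [stem_match_foster()].
#' @return A list of foster groups; each group is a list with `group_id`,
#'   `stem` (`d_call`, `stem_seq`, `n2`, `j_gene`, `has_d`, `top_frequency`),
#'   `index_members`, `evolved_members` (initialised to the index members)
#'   and `n_evolved`.
#' @export
group_foster_clones <- function(index_clones, min_d_fraction = 0.5,
                                require_same_n2 = TRUE) {
  n <- nrow(index_clones)
  if (is.null(n) || n == 0L) return(list())
  rows <- lapply(seq_len(n), function(i) .row_as_list(index_clones, i))
  adj <- diag(1L, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (stem_match_foster(rows[[i]], rows[[j]], min_d_fraction,
                              require_same_n2)) {
          adj[i, j] <- adj[j, i] <- 1L
        }
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  groups <- lapply(seq_len(max(comp)), function(k) {
    members <- which(comp == k)
    members <- members[order(-index_clones$frequency[members],
                             index_clones$clonotype_id[members])]
    top <- rows[[members[1L]]]
    tf <- .stem_fields(top)
    list(
      stem = list(d_call = if (tf$has_d) top$d_call else NA_character_,
                  stem_seq = if (tf$has_d) tf$d_seq else tf$insert,
                  n2 = tf$n2, j_gene = tf$j_gene, has_d = tf$has_d,
                  top_frequency = top$frequency,
                  top_clonotype = top$clonotype_id),
      index_members = index_clones$clonotype_id[members],
      evolved_members = index_clones$clonotype_id[members],
      n_evolved = length(members)
    )
  })
  ord <- order(-vapply(groups, function(g) g$stem$top_frequency, 0),
               vapply(groups, function(g) g$stem$top_clonotype, ""))
  groups <- groups[ord]
  for (i in seq_along(groups)) groups[[i]]$group_id <- sprintf("fg%d", i)
  groups
}

# View of a group stem as a pseudo-decomposition for the relaxed predicate.
.stem_as_fields <- function(stem) {
  if (isTRUE(stem$has_d)) {
    list(j_gene = stem$j_gene, n2 = stem$n2, d_seq = stem$stem_seq,
         has_d = TRUE, insert = paste0(stem$stem_seq, stem$n2))
  } else {
    list(j_gene = stem$j_gene, n2 = stem$n2, d_seq = "", has_d = FALSE,
         insert = stem$stem_seq)
  }
}

#' Attach evolved clones to foster groups
#'
#' Tests every clonotype, regardless of frequency, against every group stem
#' with the relaxed stem predicate (same J gene; D overlap of at least
#' `min_d_fraction` of the shorter retained D, or the no-D insert fallback;
#' N2 identity not required unless `require_same_n2 = TRUE`). A clonotype
#' matching several stems is assigned to the group with the largest overlap;
#' ties go to the group whose top index clone has the higher frequency. The
#' evolved count of a group includes its index members (the foster clone
#' itself counts).
#'
#' @param groups Output of [group_foster_clones()].
#' @param clonotypes The full clonotype table, including sub-threshold rows.
#' @param min_d_fraction Minimum shared fraction of the shorter D/insert.
#' @param require_same_n2 Keep `FALSE` (default) for the evolved relation;
#'   `TRUE` recovers the strict foster predicate.
#' @return `groups` with `evolved_members` and `n_evolved` updated.
#' @export
assign_evolved_clones <- function(groups, clonotypes, min_d_fraction = 0.5,
                                  require_same_n2 = FALSE) {
  if (length(groups) == 0L) return(groups)
  index_ids <- unlist(lapply(groups, `[[`, "index_members"))
  stem_fields <- lapply(groups, function(g) .stem_as_fields(g$stem))
  top_freq <- vapply(groups, function(g) g$stem$top_frequency, 0)

  for (i in seq_len(nrow(clonotypes))) {
    id <- clonotypes$clonotype_id[i]
    if (id %in% index_ids) next
    fc <- .stem_fields(.row_as_list(clonotypes, i))
    overlap <- rep(-1L, length(groups))
    for (k in seq_along(groups)) {
      sf <- stem_fields[[k]]
      if (fc$j_gene != sf$j_gene) next
      if (require_same_n2 && !identical(fc$n2, sf$n2)) next
      ov <- .stem_overlap(fc, sf, min_d_fraction)
      if (ov$ok) overlap[k] <- ov$overlap
    }
    if (all(overlap < 0L)) next
    best <- which(overlap == max(overlap))
    if (length(best) > 1L) best <- best[which.max(top_freq[best])]
    groups[[best]]$evolved_members <- c(groups[[best]]$evolved_members, id)
    groups[[best]]$n_evolved <- groups[[best]]$n_evolved + 1L
  }
  groups
}

#' Per-patient clonal-complexity indicators
#'
#' Computes `n_index` (index clones), `n_foster` (foster groups),
#' `max_evolved` (the largest evolved-clone count across groups, foster clone
#' included) and `total_evolved` (sum over index clones of one plus the
#' evolved clones attributed to it; each group's non-index evolved members
#' are attributed to the group's highest-frequency index clone, so no clone
#' is double-counted).
#'
#' @param patient_id Sample identifier carried into the result.
#' @param groups Groups populated by [assign_evolved_clones()].
#' @param index_clones Output of [call_index_clones()].
#' @return A one-row list with `patient_id`, `n_index`, `n_foster`,
#'   `max_evolved`, `total_evolved`.
#' @export
compute_indicators <- function(patient_id, groups, index_clones) {
  n_index <- if (is.null(nrow(index_clones))) 0L else nrow(index_clones)
  if (n_index == 0L) {
    warning("no index clones for ", patient_id,
            ": sample lacks a clonal IgH rearrangement")
    return(list(patient_id = patient_id, n_index = 0L, n_foster = 0L,
                max_evolved = 0L, total_evolved = 0L))
  }
  n_nonindex <- vapply(groups, function(g) {
    g$n_evolved - length(g$index_members)
  }, 0)
  list(patient_id = patient_id,
       n_index = as.integer(n_index),
       n_foster = length(groups),
       max_evolved = as.integer(max(vapply(groups, `[[`, 0, "n_evolved"))),
       total_evolved = as.integer(n_index + sum(n_nonindex)))
}

#' Run the full clonal-architecture analysis on one sample
#'
#' Deterministic composition: normalise frequencies, call index clones,
#' group foster clones, attach evolved clones, compute indicators.
#'
#' @param clonotypes Clonotype tibble (needs `reads`; `frequency` is
#'   recomputed from it).
#' @param patient_id Sample identifier.
#' @param index_threshold Read-fraction cutoff for index clones.
#' @param min_d_fraction Stem-overlap threshold for both predicates.
#' @param require_same_n2 N2 identity for the strict foster predicate.
#' @param require_same_n2_evolved N2 identity for the evolved predicate
#'   (default `FALSE`: evolved clones may erode N2).
#' @return A list with `indicators`, `groups` and `index_clones`.
#' @export
run_architecture <- function(clonotypes, patient_id = "sample",
                             index_threshold = 0.05, min_d_fraction = 0.5,
                             require_same_n2 = TRUE,
                             require_same_n2_evolved = FALSE) {
  clonotypes$frequency <- clonotypes$reads / sum(clonotypes$reads)
  idx <- call_index_clones(clonotypes, index_threshold)
  groups <- group_foster_clones(idx, min_d_fraction, require_same_n2)
  groups <- assign_evolved_clones(groups, clonotypes, min_d_fraction,
                                  require_same_n2_evolved)
  list(indicators = compute_indicators(patient_id, groups, idx),
       groups = groups, index_clones = idx)
}
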