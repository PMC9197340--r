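# Decomposition of a rearranged IgH read into V / N1 / D / N2 / J parts.
#
# This is a deliberately simple stand-in for a full germline aligner: V
# matching is prefix-anchored (FR1-primed reads start inside V), J matching is
# suffix-anchored to a germline-J prefix, and the D segment is located by
# longest common contiguous substring within the intervening region. No indel
# alignment is attempted. Pre-annotated AIRR input is the first-class path;
# this annotator exists so that simulated raw reads can be processed
# end-to-end.

#' Construct a junction decomposition
#'
#' A decomposition partitions a rearranged read as
#' `v_part + n1 + d_seq + n2 + j_part`, where `n1`/`n2` are the non-templated
#' insertions flanking the retained germline D (`d_seq`). When no D is
#' assigned, the whole intervening region is stored in `n1` and `n2` is empty.
#'
#' @param v_call,d_call,j_call Gene-level segment names (`NA`/`""` for absent
#'   V or D).
#' @param n1,d_seq,n2 Parts of the V-J intervening region.
#' @param v_part,j_part Retained germline V and J portions (optional; kept so
#'   the read can be reconstructed exactly).
#' @return A list of class `junction_decomposition`.
#' @export
junction_decomposition <- function(v_call = NA_character_, n1 = "",
                                   d_call = NA_character_, d_seq = "",
                                   n2 = "", j_call = NA_character_,
                                   v_part = "", j_part = "") {
  if ((is.na(d_call) || !nzchar(d_call)) && nzchar(d_seq)) {
    stop("d_seq must be empty when d_call is absent")
  }
  structure(list(v_call = v_call, v_part = v_part, n1 = n1,
                 d_call = d_call, d_seq = d_seq, n2 = n2,
                 j_call = j_call, j_part = j_part,
                 junction = paste0(n1, d_seq, n2)),
            class = "junction_decomposition")
}

#' @export
print.junction_decomposition <- function(x, ...) {
  d <- if (is.na(x$d_call) || !nzchar(x$d_call)) "-" else x$d_call
  cat(sprintf("<%s | N1:%s | %s:%s | N2:%s | %s>\n",
              ifelse(is.na(x$v_call), "-", x$v_call), x$n1, d, x$d_seq, x$n2,
              ifelse(is.na(x$j_call), "-", x$j_call)))
  invisible(x)
}

# Best anchored segment match: longest match length, ties broken by
# lexicographically smallest segment name.
.best_match <- function(lengths, names) {
  best <- max(lengths)
  cand <- names[lengths == best]
  list(length = best, name = sort(cand)[1L])
}

#' Annotate a raw read against a germline reference
#'
#' Assigns V by the longest prefix-anchored match to the read start (allowing
#' up to `max_v_mismatches` mismatches), J by the longest read suffix equal to
#' a germline-J prefix, and D by the longest common contiguous substring
#' (length at least `min_d_match`) between the V-J intervening region and any
#' germline D. Ties on match length are broken by segment name, so annotation
#' is deterministic.
#'
#' @param read DNA string (ACGT).
#' @param ref Germline reference tibble from [read_germline_fasta()] or
#'   [generate_germline_pool()].
#' @param max_v_mismatches Mismatches tolerated in the V prefix match
#'   (default 0; raise for noisy reads).
#' @param min_d_match Minimum D substring length to call a D (default 5 nt;
#'   shorter matches are unidentifiable against a random background).
#' @param min_j_match Minimum J match length below which the read is reported
#'   unassigned (default 5).
#' @return A `junction_decomposition`, or `NULL` (with a warning) when no J
#'   match of at least `min_j_match` exists.
#' @export
annotate_junction <- function(read, ref, max_v_mismatches = 0L,
                              min_d_match = 5L, min_j_match = 5L) {
  if (is.na(read) || !nzchar(read)) stop("empty read")
  if (!is_dna(read)) stop("read contains non-ACGT characters")
  read <- toupper(read)
  vs <- ref[ref$segment_class == "V", , drop = FALSE]
  ds <- ref[ref$segment_class == "D", , drop = FALSE]
  js <- ref[ref$segment_class == "J", , drop = FALSE]
  if (nrow(vs) == 0L || nrow(ds) == 0L || nrow(js) == 0L) {
    stop("reference must contain V, D and J segments")
  }

  j_len <- vapply(js$sequence, function(s) suffix_to_prefix_match(read, s), 0L)
  jb <- .best_match(j_len, js$name)
  if (jb$length < min_j_match) {
    warning("no J match of length >= ", min_j_match, "; read unassigned")
    return(NULL)
  }
  j_start <- nchar(read) - jb$length + 1L

  v_len <- vapply(vs$sequence,
                  function(s) anchored_prefix_match(read, s, max_v_mismatches),
                  0L)
  vb <- .best_match(v_len, vs$name)
  v_end <- min(vb$length, j_start - 1L)  # J anchoring wins on overlap
  v_call <- if (v_end >= 1L) vb$name else NA_character_

  middle <- if (j_start - 1L >= v_end + 1L) {
    substr(read, v_end + 1L, j_start - 1L)
  } else ""

  d_call <- NA_character_; d_seq <- ""; n1 <- middle; n2 <- ""
  if (nzchar(middle)) {
    hits <- lapply(ds$sequence, function(s) lcs_substring(middle, s))
    hit_len <- vapply(hits, `[[`, 0L, "length")
    if (max(hit_len) >= min_d_match) {
      db <- .best_match(hit_len, ds$name)
      hit <- hits[[match(db$name, ds$name)]]
      d_call <- db$name
      d_seq <- hit$substring
      n1 <- substr(middle, 1L, hit$start_a - 1L)
      n2 <- substr(middle, hit$start_a + hit$length, nchar(middle))
    }
  }

  junction_decomposition(
    v_call = v_call, n1 = n1, d_call = d_call, d_seq = d_seq, n2 = n2,
    j_call = jb$name,
    v_part = if (v_end >= 1L) substr(read, 1L, v_end) else "",
    j_part = substr(read, j_start, nchar(read))
  )
}

#' Build a decomposition from pre-annotated AIRR fields
#'
#' Trusts the upstream caller's segment assignments. When `np1`/`np2` are
#' present, the retained D is recovered by subtracting the flanks from the
#' junction; otherwise, when a germline reference is supplied, by re-matching
#' the called D's germline sequence inside the junction (longest common
#' substring); with neither, the whole junction is treated as `n1`.
#'
#' @param v_call,d_call,j_call Segment calls (allele suffixes tolerated).
#' @param junction The V-J intervening region (N1-D-N2).
#' @param np1,np2 N-region lengths flanks as strings, if reported upstream.
#' @param ref Optional germline reference for D re-matching.
#' @param min_d_match Minimum substring length for the re-matching fallback.
#' @return A `junction_decomposition`.
#' @export
decomposition_from_airr <- function(v_call = NA_character_,
                                    d_call = NA_character_,
                                    j_call, junction,
                                    np1 = NA_character_, np2 = NA_character_,
                                    ref = NULL, min_d_match = 5L) {
  if (is.na(junction) || !nzchar(junction)) stop("empty junction")
  if (is.na(j_call) || !nzchar(j_call)) stop("missing j_call")
  junction <- toupper(junction)
  v_call <- if (is.na(v_call) || !nzchar(v_call)) NA_character_ else strip_allele(v_call)
  j_call <- strip_allele(j_call)
  d_absent <- is.na(d_call) || !nzchar(d_call)
  d_call <- if (d_absent) NA_character_ else strip_allele(d_call)

  if (d_absent) {
    return(junction_decomposition(v_call = v_call, n1 = junction,
                                  j_call = j_call))
  }
  if (!is.na(np1) && !is.na(np2)) {
    np1 <- toupper(np1); np2 <- toupper(np2)
    if (nchar(np1) + nchar(np2) > nchar(junction)) {
      stop("inconsistent lengths: |np1| + |np2| > |junction|")
    }
    d_seq <- substr(junction, nchar(np1) + 1L, nchar(junction) - nchar(np2))
    return(junction_decomposition(v_call = v_call, n1 = np1, d_call = d_call,
                                  d_seq = d_seq, n2 = np2, j_call = j_call))
  }
  if (!is.null(ref)) {
    germ <- ref$sequence[ref$segment_class == "D" & ref$name == d_call]
    if (length(germ) == 1L) {
      hit <- lcs_substring(junction, germ)
      if (hit$length >= min_d_match) {
        return(junction_decomposition(
          v_call = v_call,
          n1 = substr(junction, 1L, hit$start_a - 1L),
          d_call = d_call, d_seq = hit$substring,
          n2 = substr(junction, hit$start_a + hit$length, nchar(junction)),
          j_call = j_call))
      }
    }
  }
  # called D but no way to locate it: conservative no-D decomposition
  junction_decomposition(v_call = v_call, n1 = junction, j_call = j_call)
}
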