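# Anchored string matching primitives underlying the D-N2-J stem definition.
# All inputs are plain ACGT strings; positions are 1-based and inclusive.

#' Longest common contiguous substring of two DNA strings
#'
#' Classic dynamic programme over the shorter string. Among equally long
#' maximal substrings the one starting leftmost in `a`, then leftmost in `b`,
#' is reported, so results are deterministic.
#'
#' @param a,b Character scalars (possibly empty).
#' @return A list with `length`, `substring`, and the 1-based start positions
#'   `start_a`, `start_b` (0 when `length` is 0).
#' @examples
#' lcs_substring("GGGTTT", "AGGTTC")$substring
#' @export
lcs_substring <- function(a, b) {
  if (is.na(a) || is.na(b) || nchar(a) == 0L || nchar(b) == 0L) {
    return(list(length = 0L, substring = "", start_a = 0L, start_b = 0L))
  }
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(A); nb <- length(B)
  prev <- integer(nb)
  best <- 0L; best_i <- 0L; best_j <- 0L
  for (i in seq_len(na)) {
    shifted <- c(0L, prev[-nb])
    cur <- integer(nb)
    hit <- A[i] == B
    cur[hit] <- shifted[hit] + 1L
    m <- max(cur)
    if (m > best) {   # strict: keeps the leftmost (i, then j) maximal match
      best <- m
      best_j <- which.max(cur)
      best_i <- i
    }
    prev <- cur
  }
  list(length = best,
       substring = if (best > 0L) substr(a, best_i - best + 1L, best_i) else "",
       start_a = if (best > 0L) best_i - best + 1L else 0L,
       start_b = if (best > 0L) best_j - best + 1L else 0L)
}

#' @rdname lcs_substring
#' @export
lcs_length <- function(a, b) lcs_substring(a, b)$length

# Longest L such that hamming(read[1:L], seg[1:L]) <= max_mismatches.
# With max_mismatches = 0 this is the longest common prefix.
anchored_prefix_match <- function(read, seg, max_mismatches = 0L) {
  n <- min(nchar(read), nchar(seg))
  if (n == 0L) return(0L)
  r <- strsplit(substr(read, 1L, n), "", fixed = TRUE)[[1]]
  s <- strsplit(substr(seg, 1L, n), "", fixed = TRUE)[[1]]
  mm <- cumsum(r != s)
  ok <- which(mm <= max_mismatches)
  if (length(ok) == 0L) 0L else max(ok)
}

# Longest L such that the last L characters of `read` equal the first L
# characters of `seg` (read suffix anchored to a germline prefix).
suffix_to_prefix_match <- function(read, seg) {
  n <- min(nchar(read), nchar(seg))
  nr <- nchar(read)
  for (L in rev(seq_len(n))) {
    if (substr(read, nr - L + 1L, nr) == substr(seg, 1L, L)) return(L)
  }
  0L
}

# Length of the longest common suffix of two strings (J-side-anchored overlap
# used by the no-D fallback of the stem predicate).
common_suffix_length <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ra <- rev(strsplit(a, "", fixed = TRUE)[[1]])[seq_len(n)]
  rb <- rev(strsplit(b, "", fixed = TRUE)[[1]])[seq_len(n)]
  neq <- which(ra != rb)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Collapse an IMGT-style call ("IGHV3-23*01, IGHV3-23*04") to its gene-level
# name: first listed call, allele suffix stripped.
strip_allele <- function(call) {
  out <- sub(",.*$", "", call)
  out <- sub("\\*.*$", "", out)
  trimws(out)
}

# Round non-negative targets summing to `total` into non-negative integers
# that sum exactly to `total` (largest-remainder apportionment, deterministic).
largest_remainder_round <- function(targets, total) {
  stopifnot(all(targets >= 0), total >= 0)
  if (sum(targets) == 0) return(integer(length(targets)))
  p <- targets / sum(targets) * total
  counts <- floor(p)
  short <- total - sum(counts)
  if (short > 0L) {
    ord <- order(p - counts, decreasing = TRUE)  # ties: earlier index first
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1L
  }
  as.integer(counts)
}

# Random ACGT string helper shared by the simulator.
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

is_dna <- function(x) grepl("^[ACGT]*$", x)
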