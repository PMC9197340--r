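# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (pure enumeration over substrings/partitions) so that it
# cannot share a defect with the implementation it checks.

rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Longest common contiguous substring by full enumeration of the shorter
# string's substrings, longest first, leftmost-in-a first.
oracle_lcs <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(list(length = 0L, substring = "", start_a = 0L))
  # enumerate substrings of `a`, longest first, leftmost-in-a first
  for (len in seq(n, 1)) {
    for (start in seq_len(nchar(a) - len + 1)) {
      sub <- substr(a, start, start + len - 1)
      if (grepl(sub, b, fixed = TRUE)) {
        return(list(length = len, substring = sub, start_a = start))
      }
    }
  }
  list(length = 0L, substring = "", start_a = 0L)
}

# Longest common suffix by direct enumeration.
oracle_common_suffix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  best <- 0L
  for (len in seq_len(n)) {
    if (substr(a, nchar(a) - len + 1, nchar(a)) ==
        substr(b, nchar(b) - len + 1, nchar(b))) best <- len
  }
  best
}

# Direct re-evaluation of the stem predicate from its definition.
oracle_stem_match <- function(a, b, min_d_fraction = 0.5,
                              require_same_n2 = TRUE) {
  if (a$j_call != b$j_call) return(FALSE)
  if (require_same_n2 && a$n2 != b$n2) return(FALSE)
  if (nzchar(a$d_seq) && nzchar(b$d_seq)) {
    need <- ceiling(min_d_fraction * min(nchar(a$d_seq), nchar(b$d_seq)))
    oracle_lcs(a$d_seq, b$d_seq)$length >= need
  } else {
    ia <- paste0(a$n1, a$d_seq, a$n2)
    ib <- paste0(b$n1, b$d_seq, b$n2)
    need <- ceiling(min_d_fraction * min(nchar(ia), nchar(ib)))
    oracle_common_suffix(ia, ib) >= need
  }
}

# Random decomposition for predicate fuzzing: short regions so threshold
# boundaries are hit often.
rand_decomposition <- function(j_pool = c("J1", "J2"),
                               p_no_d = 0.25) {
  no_d <- runif(1) < p_no_d
  list(j_call = sample(j_pool, 1),
       n1 = rand_dna(sample(0:6, 1)),
       d_seq = if (no_d) "" else rand_dna(sample(4:12, 1)),
       n2 = if (no_d) "" else rand_dna(sample(0:4, 1)))
}

# Exhaustive-partition annotation oracle: enumerates every J suffix length,
# every V prefix length and every D window with plain substring comparisons,
# applying the documented selection order (longest J, then longest V, then
# longest D; name ties lexicographic; leftmost D window).
oracle_annotate <- function(read, ref, max_v_mismatches = 0,
                            min_d_match = 5, min_j_match = 5) {
  vs <- ref[ref$segment_class == "V", ]
  ds <- ref[ref$segment_class == "D", ]
  js <- ref[ref$segment_class == "J", ]
  n <- nchar(read)

  best_j <- list(len = 0L, name = NA_character_)
  for (k in order(js$name)) {
    for (len in seq_len(min(n, nchar(js$sequence[k])))) {
      if (substr(read, n - len + 1, n) == substr(js$sequence[k], 1, len) &&
          len > best_j$len) {
        best_j <- list(len = len, name = js$name[k])
      }
    }
  }
  if (best_j$len < min_j_match) return(NULL)
  j_start <- n - best_j$len + 1

  best_v <- list(len = 0L, name = NA_character_)
  for (k in order(vs$name)) {
    lim <- min(n, nchar(vs$sequence[k]))
    for (len in seq_len(lim)) {
      mm <- sum(strsplit(substr(read, 1, len), "")[[1]] !=
                  strsplit(substr(vs$sequence[k], 1, len), "")[[1]])
      if (mm <= max_v_mismatches && len > best_v$len) {
        best_v <- list(len = len, name = vs$name[k])
      }
    }
  }
  v_end <- min(best_v$len, j_start - 1)
  middle <- if (j_start - 1 >= v_end + 1) substr(read, v_end + 1, j_start - 1) else ""

  d_call <- NA_character_; d_seq <- ""; n1 <- middle; n2 <- ""
  if (nzchar(middle)) {
    best_d <- list(len = 0L, name = NA_character_, start = 0L)
    for (k in order(ds$name)) {
      hit <- oracle_lcs(middle, ds$sequence[k])
      if (hit$length > best_d$len) {
        best_d <- list(len = hit$length, name = ds$name[k],
                       start = hit$start_a, sub = hit$substring)
      }
    }
    if (best_d$len >= min_d_match) {
      d_call <- best_d$name
      d_seq <- best_d$sub
      n1 <- substr(middle, 1, best_d$start - 1)
      n2 <- substr(middle, best_d$start + best_d$len, nchar(middle))
    }
  }
  list(v_call = if (v_end >= 1) best_v$name else NA_character_,
       n1 = n1, d_call = d_call, d_seq = d_seq, n2 = n2,
       j_call = best_j$name)
}

# All permutations of 1..n (n <= 7), for the exact Spearman null.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  out
}

# Exact permutation p-value for Spearman rho (two-sided, untied data).
oracle_spearman_perm_p <- function(x, y) {
  n <- length(x)
  obs <- abs(cor(rank(x), rank(y)))
  perms <- all_perms(n)
  rhos <- apply(perms, 1, function(p) abs(cor(rank(x), rank(y[p]))))
  mean(rhos >= obs - 1e-12)
}

# Squared tie-corrected Wilcoxon rank-sum normal statistic, from first
# principles; asymptotically identical to the two-group Kruskal-Wallis H.
oracle_ranksum_z2 <- function(g1, g2) {
  all <- c(g1, g2)
  r <- rank(all)
  N <- length(all); n1 <- length(g1); n2 <- length(g2)
  W <- sum(r[seq_along(g1)])
  EW <- n1 * (N + 1) / 2
  ties <- table(all)
  varW <- n1 * n2 * (N + 1) / 12 -
    n1 * n2 * sum(ties^3 - ties) / (12 * N * (N - 1))
  ((W - EW)^2) / varW
}

# Tiny hand-buildable germline reference.
toy_reference <- function() {
  tibble::tibble(
    name = c("V1", "V2", "D1", "D2", "J1", "J2"),
    segment_class = c("V", "V", "D", "D", "J", "J"),
    sequence = c("AAAACCCC", "AAAATTTT", "GGGTTT", "CACACA",
                 "CCAAGG", "TTGGCC")
  )
}

# Clonotype-table builder for architecture tests: one row per clone spec.
make_clonotypes <- function(specs) {
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    d_seq <- s$d_seq %||% ""
    n1 <- s$n1 %||% ""
    n2 <- s$n2 %||% ""
    tibble::tibble(
      clonotype_id = s$id %||% sprintf("c%03d", i),
      v_call = s$v_call %||% "V1",
      d_call = s$d_call %||% (if (nzchar(d_seq)) "D1" else ""),
      j_call = s$j_call %||% "J1",
      junction = paste0(n1, d_seq, n2),
      n1 = n1, d_seq = d_seq, n2 = n2,
      reads = as.integer(s$reads)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$frequency <- out$reads / sum(out$reads)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
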