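test_that("index calling is inclusive at the threshold and ordered", {
  clon <- make_clonotypes(list(
    list(id = "a", n1 = "AAAA", reads = 60),
    list(id = "b", n1 = "CCCC", reads = 30),
    list(id = "c", n1 = "GGGG", reads = 6),
    list(id = "d", n1 = "TTTT", reads = 4)
  ))
  idx <- call_index_clones(clon)   # 0.60 / 0.30 / 0.06 / 0.04
  expect_equal(idx$clonotype_id, c("a", "b", "c"))

  at_exact <- make_clonotypes(list(
    list(id = "a", n1 = "AAAA", reads = 95),
    list(id = "b", n1 = "CCCC", reads = 5)
  ))
  expect_equal(nrow(call_index_clones(at_exact)), 2)

  single <- make_clonotypes(list(list(id = "a", n1 = "A", reads = 10)))
  expect_equal(nrow(call_index_clones(single)), 1)

  expect_error(call_index_clones(clon, threshold = 0), "threshold")
  expect_error(call_index_clones(clon, threshold = 1.2), "threshold")
})

test_that("index-clone count is monotone in the threshold", {
  set.seed(520)
  for (rep in 1:20) {
    reads <- sample(1:500, 12)
    clon <- make_clonotypes(lapply(seq_along(reads), function(i) {
      list(id = sprintf("c%02d", i), n1 = rand_dna(6), reads = reads[i])
    }))
    ths <- sort(runif(5, 0.01, 0.5))
    ns <- vapply(ths, function(t) nrow(call_index_clones(clon, t)), 0L)
    expect_true(all(diff(ns) <= 0))
  }
})

test_that("stem predicate follows the half-of-D rule with N2 and J gates", {
  base <- list(j_call = "J1", n1 = "TA", d_seq = "GGGTTT", n2 = "CG")
  # shorter D retaining >= half of the shorter: match
  expect_true(stem_match_foster(base, list(j_call = "J1", n1 = "A",
                                           d_seq = "GTTT", n2 = "CG")))
  # identical decompositions: reflexive
  expect_true(stem_match_foster(base, base))
  # same D and J but different N2: no foster match...
  other_n2 <- list(j_call = "J1", n1 = "TA", d_seq = "GGGTTT", n2 = "AT")
  expect_false(stem_match_foster(base, other_n2))
  # ...unless N2 identity is relaxed (evolved relation)
  expect_true(stem_match_foster(base, other_n2, require_same_n2 = FALSE))
  # different J gene never matches
  expect_false(stem_match_foster(base, modifyList(base, list(j_call = "J2"))))
  # D overlap below half of the shorter D fails
  expect_false(stem_match_foster(base, list(j_call = "J1", n1 = "",
                                            d_seq = "TTAACC", n2 = "CG")))
})

test_that("stem predicate agrees with brute-force enumeration and is symmetric", {
  set.seed(521)
  for (i in 1:2000) {
    a <- rand_decomposition()
    b <- rand_decomposition()
    strict <- runif(1) < 0.5
    got <- stem_match_foster(a, b, require_same_n2 = strict)
    expect_identical(got, oracle_stem_match(a, b, require_same_n2 = strict))
    expect_identical(got, stem_match_foster(b, a, require_same_n2 = strict))
    expect_true(stem_match_foster(a, a, require_same_n2 = strict))
  }
})

test_that("foster grouping takes the transitive closure of pairwise matches", {
  # A-B match (shared TTTT) and B-C match (shared CCCC), but A and C share
  # nothing: one chain-merged group via transitive closure
  clon <- make_clonotypes(list(
    list(id = "A", d_seq = "GGGGTTTT", n2 = "GG", reads = 40),
    list(id = "B", v_call = "V2", n1 = "T", d_seq = "TTTTCCCC", n2 = "GG",
         reads = 35),
    list(id = "C", v_call = "V3", n1 = "GC", d_seq = "CCCCAAAA", n2 = "GG",
         reads = 25)
  ))
  expect_false(stem_match_foster(
    list(j_call = "J1", n1 = "", d_seq = "GGGGTTTT", n2 = "GG"),
    list(j_call = "J1", n1 = "GC", d_seq = "CCCCAAAA", n2 = "GG")
  ))
  groups <- group_foster_clones(call_index_clones(clon))
  expect_equal(length(groups), 1)
  expect_setequal(groups[[1]]$index_members, c("A", "B", "C"))

  # three pairwise-unrelated clones: three singleton groups
  solo <- make_clonotypes(list(
    list(id = "A", d_seq = "AAAACCCC", n2 = "GG", reads = 40),
    list(id = "B", d_seq = "GGGGTTTT", n2 = "GG", reads = 35),
    list(id = "C", j_call = "J2", d_seq = "AAAACCCC", n2 = "GG", reads = 25)
  ))
  expect_equal(length(group_foster_clones(call_index_clones(solo))), 3)

  expect_equal(group_foster_clones(call_index_clones(solo)[0, ]), list())
})

test_that("grouping is invariant to input order and deterministic", {
  set.seed(522)
  clon <- make_clonotypes(list(
    list(id = "A", d_seq = "AACCGGTT", n2 = "GG", reads = 40),
    list(id = "B", v_call = "V2", d_seq = "CCGGTT", n2 = "GG", reads = 30),
    list(id = "C", d_seq = "TTTTAAAA", n2 = "C", reads = 20),
    list(id = "D", v_call = "V3", j_call = "J2", d_seq = "ACGTACGT",
         n2 = "", reads = 10)
  ))
  base <- group_foster_clones(call_index_clones(clon, 0.05))
  for (i in 1:5) {
    shuf <- clon[sample(nrow(clon)), ]
    g <- group_foster_clones(call_index_clones(shuf, 0.05))
    expect_equal(lapply(g, function(x) sort(x$index_members)),
                 lapply(base, function(x) sort(x$index_members)))
    expect_equal(vapply(g, function(x) x$group_id, ""),
                 vapply(base, function(x) x$group_id, ""))
  }
})

test_that("evolved clones join on a partial D-J stem regardless of frequency", {
  clon <- make_clonotypes(list(
    list(id = "idx", d_seq = "GGGTTT", n2 = "CG", reads = 900),
    # sub-threshold, different N2, keeps >= half of the D: evolved
    list(id = "ev1", v_call = "V2", n1 = "A", d_seq = "GGTT", n2 = "AT",
         reads = 5),
    # wrong J gene: never evolved
    list(id = "noJ", j_call = "J2", d_seq = "GGGTTT", n2 = "CG", reads = 5),
    # unrelated stem: stays background
    list(id = "bg", d_seq = "ACACAACC", n2 = "T", reads = 90)
  ))
  res <- run_architecture(clon)
  expect_equal(res$indicators$n_index, 2)   # idx and bg are both >= 5%
  expect_equal(res$indicators$n_foster, 2)
  g_idx <- res$groups[[which(vapply(res$groups, function(g)
    "idx" %in% g$index_members, TRUE))]]
  expect_setequal(g_idx$evolved_members, c("idx", "ev1"))
  expect_equal(g_idx$n_evolved, 2)
})

test_that("a lone index clone yields the minimal indicator vector", {
  clon <- make_clonotypes(list(list(id = "only", d_seq = "GGGTTT", n2 = "C",
                                    reads = 100)))
  res <- run_architecture(clon)
  expect_equal(res$indicators[c("n_index", "n_foster", "max_evolved",
                                "total_evolved")],
               list(n_index = 1L, n_foster = 1L, max_evolved = 1L,
                    total_evolved = 1L))
})

test_that("indicator arithmetic follows the attribution rule", {
  # two groups of 4 evolved each, with 2 and 1 index members:
  # total = (1 + 2) + 1 + (1 + 3) = 8 under top-clone attribution
  clon <- make_clonotypes(list(
    list(id = "a1", d_seq = "AACCGGTT", n2 = "GG", reads = 300),
    list(id = "a2", v_call = "V2", d_seq = "AACCGGTT", n2 = "GG", reads = 200),
    list(id = "a3", v_call = "V3", n1 = "T", d_seq = "CCGGTT", n2 = "AA",
         reads = 10),
    list(id = "a4", v_call = "V4", n1 = "GC", d_seq = "ACCGGT", n2 = "CC",
         reads = 10),
    list(id = "b1", d_seq = "TTTTACAC", n2 = "C", reads = 250),
    list(id = "b2", v_call = "V2", n1 = "A", d_seq = "TTACAC", n2 = "T",
         reads = 10),
    list(id = "b3", v_call = "V3", n1 = "AT", d_seq = "TTTTAC", n2 = "G",
         reads = 10),
    list(id = "b4", v_call = "V4", n1 = "C", d_seq = "TTAC", n2 = "GG",
         reads = 10)
  ))
  res <- run_architecture(clon)
  expect_equal(res$indicators$n_index, 3)
  expect_equal(res$indicators$n_foster, 2)
  expect_equal(vapply(res$groups, `[[`, 0L, "n_evolved"), c(4L, 4L))
  expect_equal(res$indicators$max_evolved, 4)
  expect_equal(res$indicators$total_evolved, 8)
})

test_that("per-sample invariants hold on simulated repertoires", {
  ref <- generate_germline_pool(seed = 524)
  set.seed(525)
  for (i in 1:15) {
    nf <- sample(1:4, 1)
    epl <- sample(1:12, nf, replace = TRUE)
    sim <- simulate_leukemic_repertoire(
      ref, nf, epl,
      extra_index_per_lineage = pmin(sample(0:1, nf, replace = TRUE),
                                     epl - 1L),
      background_clonotypes = 40
    )
    res <- run_architecture(sim$clonotypes)
    ind <- res$indicators
    expect_lte(ind$n_foster, ind$n_index)
    expect_lte(ind$max_evolved, ind$total_evolved)
    expect_gte(ind$max_evolved, 1)
    # partition: every index clone in exactly one group
    idx_ids <- res$index_clones$clonotype_id
    member_of <- unlist(lapply(res$groups, `[[`, "index_members"))
    expect_setequal(member_of, idx_ids)
    expect_equal(anyDuplicated(member_of), 0L)
    # evolved members are disjoint across groups
    ev <- unlist(lapply(res$groups, `[[`, "evolved_members"))
    expect_equal(anyDuplicated(ev), 0L)
  }
})

test_that("zero index clones produce zero indicators with a warning", {
  clon <- make_clonotypes(lapply(1:30, function(i) {
    list(id = sprintf("c%02d", i), n1 = rand_dna(8), reads = 1)
  }))
  expect_warning(res <- run_architecture(clon), "index")
  expect_equal(res$indicators$n_foster, 0L)
  expect_equal(res$indicators$max_evolved, 0L)
})
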