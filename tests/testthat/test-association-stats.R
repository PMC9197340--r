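test_that("Spearman equals Pearson on ranks and handles perfect monotone data", {
  res <- spearman_tie_corrected(1:5, 1:5)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 0)

  set.seed(601)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    res <- spearman_tie_corrected(x, y)
    expect_equal(res$statistic, cor(rank(x), rank(y)))
    # cross-check against the reference asymptotic implementation
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(res$statistic, unname(ref$estimate))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(602)
  x <- rexp(40); y <- x + rnorm(40)
  base <- spearman_tie_corrected(x, y)
  tr <- spearman_tie_corrected(log(x), exp(y / 10))
  expect_equal(tr$statistic, base$statistic)
  expect_equal(tr$p_value, base$p_value)
})

test_that("Spearman degenerate inputs error informatively", {
  expect_error(spearman_tie_corrected(c(1, 2), c(1, 2)), "3 complete pairs")
  expect_error(spearman_tie_corrected(rep(1, 10), 1:10), "variance")
})

test_that("Spearman t-approximation tracks the exact permutation null", {
  # the exact null is discrete at tiny n (steps of 1/60 at n = 5), so the
  # continuous t-approximation can only track it coarsely there and tightens
  # as n grows
  set.seed(603)
  devs <- list()
  for (n in 5:7) {
    devs[[as.character(n)]] <- replicate(10, {
      x <- sample(100, n); y <- sample(100, n)
      abs(spearman_tie_corrected(x, y)$p_value -
            oracle_spearman_perm_p(x, y))
    })
  }
  expect_lt(max(unlist(devs)), 0.1)
  expect_lt(max(devs[["7"]]), 0.04)
  expect_lt(mean(devs[["7"]]), mean(devs[["5"]]))
})

test_that("Kruskal-Wallis H matches the hand formula without ties", {
  # groups {1,2} and {3,4}: H = 12/(N(N+1)) * sum(R^2/n) - 3(N+1) = 2.4
  res <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(res$statistic, 2.4)
  expect_equal(res$n, 4)
})

test_that("two-group Kruskal-Wallis equals the squared tie-corrected rank-sum Z", {
  set.seed(604)
  for (i in 1:300) {
    g1 <- sample(1:8, sample(3:20, 1), replace = TRUE)
    g2 <- sample(1:8, sample(3:20, 1), replace = TRUE)
    if (length(unique(c(g1, g2))) < 2) next
    expect_equal(kruskal_wallis(list(g1, g2))$statistic,
                 oracle_ranksum_z2(g1, g2), tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis degenerate cases", {
  res <- kruskal_wallis(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(kruskal_wallis(list(c(1, 2))), "2 non-empty groups")
})

test_that("rank tests are invariant under monotone transforms of the data", {
  set.seed(605)
  g <- list(rexp(15), rexp(20) * 2, rexp(10))
  a <- kruskal_wallis(g)
  b <- kruskal_wallis(lapply(g, function(v) v^3 + 1))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("contingency expansion reproduces per-patient score pairs", {
  out <- expand_contingency(matrix(c(1, 0, 0, 2), 2, 2, byrow = TRUE),
                            row_scores = c(0, 1), col_scores = c(0, 1))
  expect_equal(out$x, c(0, 1, 1))
  expect_equal(out$y, c(0, 1, 1))

  tabs <- reference_cohort_tables()
  pairs <- expand_contingency(tabs$eortc_risk, 1:4, 1:4)
  expect_length(pairs$x, 105)
  expect_equal(as.vector(table(pairs$x)), c(23, 63, 9, 10))

  expect_error(expand_contingency(matrix(-1), 1, 1), "negative")
  empty <- expand_contingency(matrix(0, 2, 2), 1:2, 1:2)
  expect_length(empty$x, 0)
})

test_that("row percentages match the published worked examples", {
  tabs <- reference_cohort_tables()
  pct <- crosstab_percentages(tabs$genetic_type, axis = "row")
  expect_equal(unname(pct["ETV6_RUNX1", "3"] + pct["ETV6_RUNX1", "4"]), 7.4)
  expect_equal(unname(rowSums(pct)), rep(100, 3), tolerance = 0.2)
  zero_margin <- crosstab_percentages(matrix(c(0, 0, 1, 3), 2, 2,
                                             byrow = TRUE), axis = "row")
  expect_true(all(is.na(zero_margin[1, ])))
})

test_that("five-number summary follows the averaging quartile convention", {
  expect_equal(summarize_distribution(c(1, 2, 3, 4, 5))$median, 3)
  expect_equal(summarize_distribution(c(1, 2, 3, 4))$median, 2.5)
  s <- summarize_distribution(c(1, 1, 9, 9, 9, 54))
  # order statistics by hand: quartile positions fall between observations,
  # so Q1 = 1, median = 9, Q3 = 9 under the averaging convention
  expect_equal(s[c("min", "q1", "median", "q3", "max")],
               list(min = 1, q1 = 1, median = 9, q3 = 9, max = 54))
  expect_error(summarize_distribution(numeric(0)), "empty")
  ordered <- unlist(s[c("min", "q1", "median", "q3", "max")])
  expect_true(all(diff(ordered) >= 0))
})

test_that("the association suite maps covariates to the mandated method", {
  set.seed(606)
  n <- 60
  cohort <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:n),
    n_foster = sample(1:4, n, replace = TRUE),
    max_evolved = pmax(1, round(rlnorm(n, 2, 1))),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_years = runif(n, 1, 18),
    wbc = rlnorm(n, 2, 1),
    cns = sample(c("CNS-1", "CNS-2/TLP+", NA), n, replace = TRUE,
                 prob = c(0.85, 0.1, 0.05)),
    nci_risk = sample(c("standard", "high"), n, replace = TRUE),
    eortc_risk = sample(c("VLR", "AR1", "AR2", "VHR"), n, replace = TRUE),
    genetic_type = sample(c("ETV6_RUNX1", "hyperdiploidy", "other", NA), n,
                          replace = TRUE, prob = c(0.25, 0.35, 0.35, 0.05))
  )
  cohort$eortc_risk_ord <- match(cohort$eortc_risk,
                                 c("VLR", "AR1", "AR2", "VHR"))
  suite <- run_association_suite(cohort)
  expect_setequal(unique(suite$indicator), c("n_foster", "max_evolved"))
  expect_equal(unique(suite$method[suite$covariate == "eortc_risk"]),
               "spearman")
  expect_equal(unique(suite$method[suite$covariate == "sex"]),
               "kruskal_wallis")
  # pairwise deletion: tests on covariates with missing values report their
  # own n
  n_gen <- suite$n[suite$covariate == "genetic_type"][1]
  expect_equal(n_gen, sum(!is.na(cohort$genetic_type)))
  expect_equal(suite$n[suite$covariate == "sex"][1], n)
  expect_true(all(suite$p_value >= 0 & suite$p_value <= 1))
})

test_that("single-level covariates are skipped with a warning", {
  cohort <- tibble::tibble(
    patient_id = c("a", "b", "c"), n_foster = c(1, 2, 3),
    max_evolved = c(1, 5, 9), sex = c("male", "male", "male")
  )
  expect_warning(run_association_suite(cohort, indicators = "n_foster"),
                 "skipped")
  suite <- suppressWarnings(run_association_suite(cohort))
  expect_equal(nrow(suite), 0)
})
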