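# Rank-based association tests between the complexity indicators and
# clinical covariates, plus contingency-table utilities for reproducing
# published cohort summaries.

#' Tie-corrected Spearman correlation test
#'
#' Computes rho as the Pearson correlation of mid-ranks and a two-sided
#' p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom — the convention used by mainstream statistical software for
#' ordinal covariates such as treatment-risk groups.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value are
#'   dropped.
#' @return A list with `method`, `statistic` (rho), `p_value` and `n`.
#' @export
spearman_tie_corrected <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("zero variance: correlation undefined")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(method = "spearman", statistic = rho, p_value = p, n = n)
}

#' Kruskal-Wallis test across groups
#'
#' Standard tie-corrected Kruskal-Wallis H with a chi-square approximation on
#' `k - 1` degrees of freedom (the convention behind the published cohort's
#' p-values). When all observations are identical the statistic is 0 and
#' p is 1.
#'
#' @param groups A list of numeric vectors, one per group; missing values are
#'   dropped within groups, empty groups are dropped.
#' @return A list with `method`, `statistic` (H), `p_value` and `n`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, 0L) > 0L]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  if (n < 2L) stop("need at least 2 observations")
  if (length(unique(values)) == 1L) {
    return(list(method = "kruskal_wallis", statistic = 0, p_value = 1, n = n))
  }
  labels <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  kt <- stats::kruskal.test(values, labels)
  list(method = "kruskal_wallis", statistic = unname(kt$statistic),
       p_value = kt$p.value, n = n)
}

#' Expand a contingency table into paired score vectors
#'
#' Reconstructs per-patient `(row score, column score)` pairs from printed
#' cross-tabulated counts, repeating each cell's pair `counts[i, j]` times.
#' Used to re-run rank tests from published tables without the underlying
#' per-patient data.
#'
#' @param counts Non-negative integer matrix.
#' @param row_scores,col_scores Numeric scores, one per row/column.
#' @return A list with vectors `x` (row scores) and `y` (column scores) of
#'   length `sum(counts)`.
#' @export
expand_contingency <- function(counts, row_scores, col_scores) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative count in contingency table")
  if (length(row_scores) != nrow(counts) ||
      length(col_scores) != ncol(counts)) {
    stop("scores must match table dimensions")
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  reps <- counts[idx]
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]; reps <- reps[ord]
  list(x = rep(row_scores[idx[, 1L]], reps),
       y = rep(col_scores[idx[, 2L]], reps))
}

#' Row or column percentages of a contingency table
#'
#' @param counts Non-negative integer matrix.
#' @param axis `"row"` or `"column"`: the margin percentages sum over.
#' @param digits Decimal places (default 1, the usual `N (row %)` print).
#' @return A matrix of percentages; rows (or columns) with a zero margin are
#'   `NA`.
#' @export
crosstab_percentages <- function(counts, axis = c("row", "column"),
                                 digits = 1) {
  axis <- match.arg(axis)
  counts <- as.matrix(counts)
  margins <- if (axis == "row") rowSums(counts) else colSums(counts)
  pct <- if (axis == "row") counts / margins else t(t(counts) / margins)
  pct[!is.finite(pct)] <- NA_real_
  round(100 * pct, digits)
}

#' Five-number summary of a distribution
#'
#' `min`, `Q1`, `median`, `Q3`, `max` with quartiles by the
#' empirical-distribution averaging convention (`stats::quantile` type 2,
#' the default of major commercial statistics packages).
#'
#' @param values Non-empty numeric vector; missing values dropped.
#' @return A list with `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty vector")
  q <- unname(stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 2))
  list(n = length(values), min = q[1L], q1 = q[2L], median = q[3L],
       q3 = q[4L], max = q[5L])
}

# Which test each covariate gets: Spearman for continuous/ordinal covariates,
# Kruskal-Wallis for binary and nominal ones.
.covariate_methods <- c(age_years = "spearman", wbc = "spearman",
                        eortc_risk = "spearman", sex = "kruskal_wallis",
                        nci_risk = "kruskal_wallis", cns = "kruskal_wallis",
                        genetic_type = "kruskal_wallis")

#' Run the full indicator-by-covariate association suite
#'
#' Tests each clonal-complexity indicator (`n_foster`, `max_evolved`) against
#' each clinical covariate with the method mandated for the covariate's
#' scale: Spearman for age, WBC and the ordinal EORTC risk group (coded
#' VLR=1, AR1=2, AR2=3, VHR=4); Kruskal-Wallis for sex, NCI risk group, CNS
#' status and genetic type. Missing covariate values are deleted pairwise, so
#' each test reports its own `n`. No multiplicity adjustment is applied; the
#' `significant` flag is two-sided at 0.05.
#'
#' @param cohort A tibble joining indicators and covariates per patient
#'   (columns `n_foster`, `max_evolved` plus the covariates above; see
#'   [build_cohort_table()]).
#' @param indicators Indicator columns to test.
#' @param alpha Two-sided significance level for the flag.
#' @return A tibble with one row per (indicator, covariate) test.
#' @export
run_association_suite <- function(cohort,
                                  indicators = c("n_foster", "max_evolved"),
                                  alpha = 0.05) {
  covs <- intersect(names(.covariate_methods), names(cohort))
  out <- list()
  for (ind in indicators) {
    for (cov in covs) {
      method <- .covariate_methods[[cov]]
      y <- cohort[[ind]]
      res <- tryCatch({
        if (method == "spearman") {
          x <- if (cov == "eortc_risk") {
            if ("eortc_risk_ord" %in% names(cohort)) cohort$eortc_risk_ord
            else match(cohort$eortc_risk, c("VLR", "AR1", "AR2", "VHR"))
          } else cohort[[cov]]
          spearman_tie_corrected(x, y)
        } else {
          lev <- cohort[[cov]]
          keep <- !is.na(lev) & !is.na(y)
          if (length(unique(lev[keep])) < 2L) {
            stop("covariate has a single observed level")
          }
          kruskal_wallis(split(y[keep], lev[keep]))
        }
      }, error = function(e) {
        warning("test skipped for ", ind, " ~ ", cov, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        indicator = ind, covariate = cov, method = res$method,
        statistic = res$statistic, p_value = res$p_value, n = res$n,
        significant = res$p_value < alpha
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Join per-patient indicators to covariates
#'
#' @param indicators Tibble with `patient_id` and indicator columns.
#' @param covariates Tibble from [read_covariates()].
#' @return The inner join on `patient_id`.
#' @export
build_cohort_table <- function(indicators, covariates) {
  dplyr::inner_join(indicators, covariates, by = "patient_id")
}
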