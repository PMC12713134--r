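#' @include AllClasses.R
NULL

testResult <- function(testName, statistic, p, n1, n2) {
  list(test_name = testName, statistic = unname(statistic),
       p_value = unname(p), n1 = n1, n2 = n2)
}

#' Two-sample nonparametric group comparisons
#'
#' `mannWhitney()` runs the two-tailed Mann-Whitney U test (exact
#' enumeration when both samples have n <= 8 and no ties, normal
#' approximation with tie and continuity correction otherwise).
#' `ksTwoSample()` runs the two-sample Kolmogorov-Smirnov test and reports
#' the D statistic, the maximal absolute difference between the two
#' empirical CDFs. `fisherExact()` runs Fisher's exact test on a 2x2
#' nonnegative integer table. All tests are two-tailed.
#'
#' @param a,b nonempty numeric samples.
#' @return List with `test_name`, `statistic` (U, D, or odds ratio),
#'   `p_value`, `n1`, `n2`.
#' @export
mannWhitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  exact <- length(a) <= 8L && length(b) <= 8L &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  testResult("mann_whitney_u", wt$statistic, wt$p.value,
             length(a), length(b))
}

#' @rdname mannWhitney
#' @export
ksTwoSample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  kt <- suppressWarnings(
    stats::ks.test(a, b, alternative = "two.sided"))
  testResult("ks_two_sample", kt$statistic, kt$p.value,
             length(a), length(b))
}

#' @rdname mannWhitney
#' @param table2x2 2x2 matrix of nonnegative integer counts.
#' @export
fisherExact <- function(table2x2) {
  table2x2 <- as.matrix(table2x2)
  if (!all(dim(table2x2) == c(2L, 2L)))
    stop("fisherExact requires a 2x2 table")
  if (any(table2x2 < 0)) stop("table cells must be nonnegative")
  ft <- stats::fisher.test(table2x2, alternative = "two.sided")
  testResult("fisher_exact", ft$estimate, ft$p.value,
             sum(table2x2[1, ]), sum(table2x2[2, ]))
}

## plain BH step-up, hand-rolled so the FDR route is independent of
## stats::p.adjust (which serves as the cross-check in the test suite)
stepUpBH <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  thresh <- alpha * seq_len(m) / m
  below <- p[ord] <= thresh
  k <- if (any(below)) max(which(below)) else 0L
  rej <- logical(m)
  if (k > 0L) rej[ord[seq_len(k)]] <- TRUE
  ## BH-adjusted p-values
  adj <- numeric(m)
  adj[ord] <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  list(reject = rej, adjusted = pmin(1, adj))
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' The adaptive two-stage linear step-up: stage 1 applies the step-up at
#' level q' = q/(1+q) to estimate the number of true null hypotheses
#' m0 = m - r1; when 0 < r1 < m, stage 2 re-applies the step-up at level
#' q' * m / m0. Reported q-values follow the convention that a hypothesis
#' is rejected iff its q-value <= q: they are the BH-adjusted p-values
#' scaled by (m0/m) * (1+q).
#'
#' @param pValues numeric vector in [0, 1].
#' @param qLevel target FDR level; default 0.05.
#' @return List with logical `reject`, numeric `q_values`, and integer
#'   `m0` (estimated true nulls).
#' @export
bkyFdr <- function(pValues, qLevel = 0.05) {
  p <- as.numeric(pValues)
  if (length(p) == 0L) stop("no p-values")
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  m <- length(p)
  qPrime <- qLevel / (1 + qLevel)
  s1 <- stepUpBH(p, qPrime)
  r1 <- sum(s1$reject)
  if (r1 == 0L || r1 == m) {
    qv <- pmin(1, s1$adjusted * (1 + qLevel))
    return(list(reject = s1$reject, q_values = qv, m0 = m - r1))
  }
  m0 <- m - r1
  s2 <- stepUpBH(p, qPrime * m / m0)
  qv <- pmin(1, s2$adjusted * (m0 / m) * (1 + qLevel))
  list(reject = s2$reject, q_values = qv, m0 = m - sum(s2$reject))
}

#' Compare a metric between groups with FDR control
#'
#' Convenience wrapper: runs one test per comparison and applies
#' [bkyFdr()] across the resulting p-values.
#'
#' @param samples named list of two-element lists `list(a, b)`.
#' @param test one of "ks", "mw".
#' @param qLevel FDR level.
#' @return data.frame: comparison, statistic, p, q, reject, n1, n2.
#' @export
compareGroups <- function(samples, test = c("ks", "mw"), qLevel = 0.05) {
  test <- match.arg(test)
  fun <- if (test == "ks") ksTwoSample else mannWhitney
  res <- lapply(samples, function(s) fun(s[[1]], s[[2]]))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  fdr <- bkyFdr(p, qLevel)
  data.frame(
    comparison = names(samples),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p = p, q = fdr$q_values, reject = fdr$reject,
    n1 = vapply(res, `[[`, numeric(1), "n1"),
    n2 = vapply(res, `[[`, numeric(1), "n2"),
    row.names = NULL
  )
}
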