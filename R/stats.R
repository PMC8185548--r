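#' Two-sided Fisher exact test on a 2 x 2 table
#'
#' Exact hypergeometric test with the probability-mass two-sided
#' convention: the p-value sums, over all tables with the observed margins,
#' the probabilities of tables whose probability does not exceed that of the
#' observed table (up to a small relative tolerance on the comparison). This
#' is the convention under which the tumour-rejection table
#' \code{rbind(c(4, 16), c(15, 5))} gives p = 0.0012. The doubled-one-tail
#' convention is available behind \code{convention = "doubled-tail"}.
#'
#' @param table 2 x 2 matrix of non-negative integer counts, rows = groups,
#'   columns = outcome / non-outcome.
#' @param convention \code{"probability-mass"} (default) or
#'   \code{"doubled-tail"}.
#' @return a \linkS4class{TestResult}; the statistic slot carries the
#'   conditional odds-ratio estimate. A zero margin leaves only one possible
#'   table, hence p = 1.
#' @examples
#' pValue(fisherExact2x2(rbind(c(4, 16), c(15, 5))))   # 0.00123...
#' @export
fisherExact2x2 <- function(table,
                           convention = c("probability-mass",
                                          "doubled-tail")) {
  convention <- match.arg(convention)
  table <- validate2x2(table)
  if (convention == "probability-mass") {
    ft <- stats::fisher.test(table)
    p <- ft$p.value
    orhat <- unname(ft$estimate)
  } else {
    a <- table[1, 1]
    m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
    lower <- stats::phyper(a, k, m + n - k, m)
    upper <- stats::phyper(a - 1, k, m + n - k, m, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    orhat <- unname(stats::fisher.test(table)$estimate)
  }
  new("TestResult", statistic = orhat, pValue = min(p, 1),
      method = sprintf("Fisher exact test, two-sided (%s)", convention),
      nPerGroup = as.integer(rowSums(table)))
}

validate2x2 <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) stop("'table' must be 2 x 2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (sum(table) == 0) stop("at least one count must be positive")
  table
}

#' Two-sample Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U is computed from midranks. The exact two-sided p-value (enumeration
#' over all arrangements of the pooled sample) is used when the pooled size
#' is at most 16 and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction. Two samples with all
#' values identical carry no ordering information: p = 1.
#'
#' @param x,y numeric samples (both non-empty).
#' @return a \linkS4class{TestResult} with the U statistic.
#' @examples
#' pValue(mannWhitneyU(c(1, 2), c(3, 4)))   # exact: 1/3
#' @export
mannWhitneyU <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  m <- length(x); n <- length(y)
  hasTies <- anyDuplicated(c(x, y)) > 0L
  U <- sum(rank(c(x, y))[seq_len(m)]) - m * (m + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    p <- 1
    path <- "degenerate (all values identical)"
  } else {
    exact <- (m + n) <= 16L && !hasTies
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    p <- wt$p.value
    if (is.na(p)) p <- 1
    path <- if (exact) "exact enumeration"
            else "normal approximation, tie + continuity correction"
  }
  new("TestResult", statistic = U, pValue = min(max(p, .Machine$double.xmin), 1),
      method = paste0("Mann-Whitney U test, two-sided (", path, ")"),
      nPerGroup = c(m, n))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs. The exact
#' permutation p-value is used when the pooled size is at most 16 and the
#' data are tie-free; otherwise the asymptotic Kolmogorov distribution with
#' effective size \eqn{mn/(m+n)}.
#'
#' @param x,y numeric samples (both non-empty).
#' @return a \linkS4class{TestResult} with the D statistic.
#' @examples
#' statistic(ksTwoSample(c(1, 3, 5), c(2, 4, 6)))   # D = 1/3
#' @export
ksTwoSample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  m <- length(x); n <- length(y)
  hasTies <- anyDuplicated(c(x, y)) > 0L
  exact <- (m + n) <= 16L && !hasTies
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  p <- kt$p.value
  if (is.na(p)) p <- 1
  path <- if (exact) "exact enumeration"
          else "asymptotic Kolmogorov distribution, n_eff = mn/(m+n)"
  new("TestResult", statistic = unname(kt$statistic),
      pValue = min(max(p, .Machine$double.xmin), 1),
      method = paste0("Two-sample Kolmogorov-Smirnov test (", path, ")"),
      nPerGroup = c(m, n))
}
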