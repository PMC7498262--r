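#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that two sets
#' of sizes K and n drawn from a universe of N share at least k members.
#' Computed in log-space by `stats::phyper` for numerical stability.
#'
#' @param N universe size.
#' @param K size of the first set (e.g. bound genes).
#' @param n size of the second set (e.g. regulated genes).
#' @param k observed overlap.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' hypergeom_upper_tail(10, 5, 5, 5) # 1/252
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N)
    stop("require 0 <= K, n <= N and k >= 0", call. = FALSE)
  if (k > min(K, n))
    stop("k exceeds min(K, n)", call. = FALSE)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' The table is given row-wise as (a, b) = with/without the property in the
#' observed set and (c, d) = with/without in the background set.  The
#' one-sided "greater" p-value is the hypergeometric upper tail of cell `a`
#' conditional on the margins; the two-sided p-value sums all tables with
#' probability at most that of the observed one (the standard convention,
#' delegated to `stats::fisher.test`).
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @param alternative "greater" (default) or "two_sided".
#' @return list with `p_value`, `odds_ratio` (the sample odds ratio
#'   a*d/(b*c), `Inf` when b*c = 0) and the four counts.
#' @export
#' @examples
#' fisher_exact(3, 0, 0, 3)$p_value # 1/20
fisher_exact <- function(a, b, c, d, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  if (sum(cells) == 0) stop("empty table", call. = FALSE)
  p <- if (alternative == "greater") {
    # X = cell a; margins: first row a+b, first column a+c
    hypergeom_upper_tail(N = a + b + c + d, K = a + c, n = a + b, k = a)
  } else {
    stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                       alternative = "two.sided")$p.value
  }
  or <- if (a * d == 0 && b * c == 0) NaN
        else if (b * c == 0) Inf
        else (a * d) / (b * c)
  list(p_value = min(p, 1), odds_ratio = or, a = a, b = b, c = c, d = d)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the exact supremum distance between the two empirical CDFs,
#' evaluated at every pooled data point so ties are handled correctly.
#' The p-value uses the asymptotic Kolmogorov distribution with the
#' standard effective-sample-size correction
#' lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D, ne = nx*ny/(nx+ny).
#'
#' @param x,y numeric samples.
#' @return list with `D` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  D <- max(abs(Fx - Fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  j <- seq_len(101)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  list(D = D, p_value = min(max(p, 0), 1))
}

#' Chi-square goodness-of-fit test
#'
#' Compares observed label counts to expected counts under given
#' proportions; df = number of labels - 1.
#'
#' @param observed named (or plain) vector of counts.
#' @param expected_proportions proportions summing to 1, same length/order.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_gof <- function(observed, expected_proportions) {
  if (length(observed) != length(expected_proportions))
    stop("observed and expected lengths differ", call. = FALSE)
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    stop("expected proportions must sum to 1", call. = FALSE)
  expected <- sum(observed) * expected_proportions
  if (any(expected == 0 & observed > 0))
    stop("expected count 0 for a label present in the observed set; ",
         "merge labels before testing", call. = FALSE)
  keep <- expected > 0
  stat <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  df <- length(observed) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving
#' with the input (wraps `stats::p.adjust`).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sample t-test
#'
#' Classical pooled-variance Student t by default; Welch with
#' `equal_variance = FALSE`.  A zero-variance comparison (all replicate
#' ratios identical within each group) is reported with `degenerate = TRUE`:
#' t = 0 / p = 1 when the means agree, t = +/-Inf / p = 0 otherwise.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param equal_variance pool the variances (classical Student)?
#' @return list with `t`, `df`, `p_value`, `degenerate`.
#' @export
t_two_sample <- function(x, y, equal_variance = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 values per sample", call. = FALSE)
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  dm <- mean(x) - mean(y)
  if (equal_variance) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- se^4 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (!is.finite(se) || se == 0) {
    if (dm == 0) return(list(t = 0, df = if (is.finite(df)) df else nx + ny - 2,
                             p_value = 1, degenerate = TRUE))
    return(list(t = sign(dm) * Inf, df = nx + ny - 2, p_value = 0,
                degenerate = TRUE))
  }
  t <- dm / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       degenerate = FALSE)
}
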