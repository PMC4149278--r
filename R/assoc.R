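#' Pearson chi-square test on a 2x2 carrier table
#'
#' Computes the uncorrected (no Yates continuity correction) Pearson
#' statistic on the table
#' \preformatted{          positive  negative
#'   cases        a          b
#'   controls     c          d }
#' as `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with `N = a+b+c+d`, and the
#' upper-tail p-value on 1 degree of freedom. The uncorrected statistic is
#' the convention throughout this package's association scans.
#'
#' @param a,b,c,d Non-negative counts (vectorized).
#' @return list with numeric vectors `chi2` and `p`.
#' @examples
#' chi_square_2x2(6, 94, 11, 89)   # chi2 = 1.61, p = 0.20
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  res <- chi2_2x2_raw(a, b, c, d)
  if (anyNA(res$chi2))
    stop("undefined statistic: a table margin is zero")
  res
}

# Vectorized core; zero margins give NA instead of an error.
chi2_2x2_raw <- function(a, b, c, d) {
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den == 0, NA_real_, n * (a * d - b * c)^2 / den)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Case-control association scan over carrier tables
#'
#' Applies [chi_square_2x2()] to every per-locus (or per-cluster) carrier
#' table and flags significance at `alpha` (two-sided, uncorrected for
#' multiple comparisons unless `bonferroni = TRUE`). Monomorphic entries —
#' every individual positive, or every individual negative, in both groups —
#' have a zero margin, so the statistic is undefined; they are reported with
#' `chi2 = NA` and flagged, mirroring how fixed loci are left blank in a
#' prevalence table.
#'
#' @param tables data.frame with columns `case_pos`, `case_n`, `ctrl_pos`,
#'   `ctrl_n`, plus an id column (`locus_id` or `cluster_id`) carried through.
#' @param alpha Significance level.
#' @param bonferroni If `TRUE`, `alpha` is divided by the number of
#'   non-monomorphic tests.
#' @return `tables` with added columns `case_freq`, `ctrl_freq`, `chi2`, `p`,
#'   `monomorphic`, `significant`.
#' @export
association_scan <- function(tables, alpha = 0.05, bonferroni = FALSE) {
  need <- c("case_pos", "case_n", "ctrl_pos", "ctrl_n")
  stopifnot(all(need %in% names(tables)))
  a <- tables$case_pos
  b <- tables$case_n - tables$case_pos
  c <- tables$ctrl_pos
  d <- tables$ctrl_n - tables$ctrl_pos
  if (any(c(a, b, c, d) < 0)) stop("positives exceed group size")
  res <- chi2_2x2_raw(a, b, c, d)
  out <- tables
  out$case_freq <- a / tables$case_n
  out$ctrl_freq <- c / tables$ctrl_n
  out$chi2 <- res$chi2
  out$p <- res$p
  out$monomorphic <- is.na(res$chi2)
  thr <- if (bonferroni) alpha / max(1L, sum(!out$monomorphic)) else alpha
  out$significant <- !is.na(out$p) & out$p < thr
  out
}

#' Sample size for comparing two proportions
#'
#' Classical normal-approximation sample size per group for a two-sided
#' two-proportion comparison (pooled variance under the null, unpooled under
#' the alternative):
#' \deqn{n = \frac{\left(z_{1-\alpha/2}\sqrt{2\bar p(1-\bar p)} +
#'   z_{1-\beta}\sqrt{p_1(1-p_1) + p_2(1-p_2)}\right)^2}{(p_1-p_2)^2}}
#' with \eqn{\bar p = (p_1+p_2)/2}, rounded up per group. Symmetric in
#' `p1`, `p2`.
#'
#' @param p1,p2 The two carrier proportions (must differ).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Integer sample size per group.
#' @examples
#' sample_size_two_proportions(0.04, 0.24, power = 0.80)  # 47 per group
#' sample_size_two_proportions(0.04, 0.24, power = 0.90)  # 62 per group
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.80) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  if (p1 == p2) stop("p1 and p2 must differ: sample size diverges")
  pbar <- (p1 + p2) / 2
  num <- (stats::qnorm(1 - alpha / 2) * sqrt(2 * pbar * (1 - pbar)) +
            stats::qnorm(power) * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2
  as.integer(ceiling(num / (p1 - p2)^2))
}

#' Monte-Carlo size / power of the 2x2 chi-square test
#'
#' Simulates `n_reps` case-control carrier tables with true carrier
#' proportions `p1` (cases) and `p2` (controls) at `n_per_group` per group,
#' and returns the fraction rejected by the uncorrected chi-square test at
#' `alpha`. Tables with a zero margin (statistic undefined) count as
#' non-rejections. With `p1 == p2` this estimates the type-I error rate;
#' otherwise the power.
#'
#' @param p1,p2 True carrier proportions.
#' @param n_per_group Individuals per group.
#' @param alpha Significance level.
#' @param n_reps Number of simulated tables (>= 100).
#' @param seed Integer seed; results are deterministic given it.
#' @return Rejection fraction in \[0, 1\].
#' @export
empirical_power <- function(p1, p2, n_per_group, alpha = 0.05,
                            n_reps = 10000L, seed = 1L) {
  stopifnot(n_reps >= 100L)
  set.seed(seed)
  a <- stats::rbinom(n_reps, n_per_group, p1)
  c <- stats::rbinom(n_reps, n_per_group, p2)
  res <- chi2_2x2_raw(a, n_per_group - a, c, n_per_group - c)
  # critical-value form: reject when the statistic reaches qchisq(1 - alpha, 1)
  crit <- stats::qchisq(1 - alpha, df = 1L)
  mean(!is.na(res$chi2) & res$chi2 >= crit)
}
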