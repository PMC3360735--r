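# Power layer: probability that a SNP with true log OR theta attains
# BFDP <= gamma, via the non-central chi-square distribution of Z^2.

#' Critical Z^2 for attaining a BFDP threshold
#'
#' Returns the smallest z^2 at which the BFDP (computed from the approximate
#' Bayes factor at `sqrt(z2)` with variances `v`, `w` and prior odds `po`)
#' drops to `gamma`. BFDP is strictly decreasing in z^2, so the critical
#' value is found by root bisection (via `uniroot`, tolerance 1e-12) on the
#' defining identity rather than closed-form rearrangement. Returns 0 when
#' the BFDP already sits below `gamma` at Z = 0 (tiny prior odds).
#'
#' @param po prior odds of the null (>= 0).
#' @param w prior variance of the log OR (> 0).
#' @param v sampling variance of the estimate (> 0).
#' @param gamma BFDP threshold in (0, 1).
#' @return critical value of Z^2 (scalar).
#' @export
z2_critical <- function(po, w, v, gamma) {
  stopifnot(po >= 0, w > 0, v > 0, gamma > 0, gamma < 1)
  f <- function(z2) bfdp(approximate_bayes_factor(sqrt(z2), v, w), po) - gamma
  if (f(0) <= 0) return(0)
  hi <- 1
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e8) stop("no attainable critical value (prior odds too large)")
  }
  stats::uniroot(f, lower = 0, upper = hi, tol = 1e-12)$root
}

#' Power to attain a BFDP threshold
#'
#' Probability that a SNP with true log odds ratio `theta` and sampling
#' variance `v` achieves BFDP <= `gamma`. Since Z^2 follows a non-central
#' chi-square with 1 degree of freedom and non-centrality theta^2 / v, the
#' power is the upper tail of that distribution at [z2_critical()]; under the
#' null (theta = 0) this reduces to the central chi-square(1) tail.
#'
#' @param theta true log odds ratio.
#' @param v sampling variance of the log OR estimate; see [var_logor_cc()]
#'   for a case-control parameterization.
#' @param w prior variance of the log OR.
#' @param po prior odds of the null hypothesis.
#' @param gamma BFDP threshold in (0, 1).
#' @return power in `[0, 1]`. Vectorized over `theta`, `v` and `po`.
#' @examples
#' v <- var_logor_cc(791, 7012, maf = 0.3)
#' bfdp_power(log(1.25), v, w_prior(2), po = 224, gamma = 0.8)
#' @export
bfdp_power <- function(theta, v, w, po, gamma = 0.8) {
  n <- max(length(theta), length(v), length(po))
  theta <- rep_len(theta, n); v <- rep_len(v, n); po <- rep_len(po, n)
  vapply(seq_len(n), function(i) {
    z2c <- z2_critical(po[i], w, v[i], gamma)
    stats::pchisq(z2c, df = 1, ncp = theta[i]^2 / v[i], lower.tail = FALSE)
  }, numeric(1))
}

#' Approximate variance of a per-allele log OR in a case-control design
#'
#' Standard approximation V = 1 / (2 n1 f (1 - f)) + 1 / (2 n0 f (1 - f))
#' for the per-allele (trend) log odds ratio with `n1` cases, `n0` controls
#' and minor allele frequency `f`; encodes sample size and allele frequency
#' into the sampling variance used by [bfdp_power()].
#'
#' @param cases,controls numbers of cases and controls.
#' @param maf minor allele frequency in (0, 0.5].
#' @return variance of the log OR estimate. Vectorized.
#' @export
var_logor_cc <- function(cases, controls, maf) {
  stopifnot(all(cases > 0), all(controls > 0), all(maf > 0), all(maf < 1))
  1 / (2 * cases * maf * (1 - maf)) + 1 / (2 * controls * maf * (1 - maf))
}

#' Power curves across categories and a flat-prior comparator
#'
#' Evaluates [bfdp_power()] on a grid of sampling variances for each prior
#' category and for a flat-prior comparator in which all SNPs share a single
#' category (PO = (N - N*) / N*). Lower prior odds buy power, so categories
#' with stronger literature evidence dominate the flat comparator and the
#' no-evidence category falls below it.
#'
#' @param v_grid numeric vector of sampling variances (e.g. from
#'   [var_logor_cc()] over a range of sample sizes).
#' @param po named numeric vector of per-category prior odds.
#' @param po_flat prior odds of the flat comparator; `NULL` to omit.
#' @param theta true log odds ratio (default `log(1.25)`).
#' @param w prior variance of the log OR.
#' @param gamma BFDP threshold.
#' @return data frame with columns `v`, `category`, `po`, `power`.
#' @export
power_curve <- function(v_grid, po, po_flat = NULL, theta = log(1.25),
                        w = w_prior(2), gamma = 0.8) {
  stopifnot(length(v_grid) > 0)
  if (is.null(names(po))) names(po) <- paste0("C", seq_along(po))
  groups <- as.list(po)
  if (!is.null(po_flat)) groups$flat <- po_flat
  rows <- lapply(names(groups), function(nm) {
    data.frame(v = v_grid, category = nm, po = groups[[nm]],
               power = bfdp_power(theta, v_grid, w, groups[[nm]], gamma),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
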