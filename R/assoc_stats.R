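# Frequentist layer: genotype QC, per-allele trend association, stratum
# heterogeneity and inflation diagnostics, all on genotype count tables.

.count_cols <- c("case0", "case1", "case2", "ctrl0", "ctrl1", "ctrl2")

.check_counts <- function(counts) {
  miss <- setdiff(c("rsid", .count_cols), names(counts))
  if (length(miss) > 0L) {
    stop("genotype count table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(as.matrix(counts[, .count_cols]) < 0)) stop("negative counts")
  invisible(counts)
}

#' Per-allele trend logistic regression on genotype counts
#'
#' Fits the per-rare-allele log-additive model by maximum-likelihood logistic
#' regression of case status on the genotype dose (0/1/2 copies of the minor
#' allele), optionally adjusted for categorical strata via indicator
#' covariates. Inference is Wald: the per-allele log OR with its standard
#' error, Z and two-sided p-value, directly consumable by [bfdp_rank()].
#'
#' @param counts data frame with columns `rsid`, `case0`..`case2`,
#'   `ctrl0`..`ctrl2` and optionally `stratum`; several rows per rsid
#'   represent strata.
#' @return data frame with one row per SNP: `rsid`, `theta` (log OR), `se`,
#'   `v`, `z`, `p`, `or`, `ci_lo`, `ci_hi`.
#' @export
trend_logistic <- function(counts) {
  .check_counts(counts)
  out <- lapply(split(counts, counts$rsid), function(tab) {
    rsid <- tab$rsid[1L]
    minor <- sum(tab$case1, tab$case2, tab$ctrl1, tab$ctrl2)
    if (minor == 0) {
      stop("SNP ", rsid, ": minor allele absent, trend model not estimable")
    }
    cells <- data.frame(
      dose = rep(0:2, each = nrow(tab)),
      stratum = rep(if (is.null(tab$stratum)) "all" else tab$stratum, 3L),
      case = c(tab$case0, tab$case1, tab$case2),
      ctrl = c(tab$ctrl0, tab$ctrl1, tab$ctrl2))
    cells <- cells[cells$case + cells$ctrl > 0, , drop = FALSE]
    form <- if (length(unique(cells$stratum)) > 1L) {
      cbind(case, ctrl) ~ dose + factor(stratum)
    } else {
      cbind(case, ctrl) ~ dose
    }
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(form, family = stats::binomial(), data = cells,
                 control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    theta <- stats::coef(fit)[["dose"]]
    se <- sqrt(stats::vcov(fit)["dose", "dose"])
    if (sep || !fit$converged || abs(theta) > 15) {
      stop("SNP ", rsid, ": separation or monotone likelihood, ",
           "trend estimate unstable")
    }
    z <- theta / se
    data.frame(rsid = rsid, theta = theta, se = se, v = se^2, z = z,
               p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
               or = exp(theta),
               ci_lo = exp(theta - stats::qnorm(0.975) * se),
               ci_hi = exp(theta + stats::qnorm(0.975) * se),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[match(unique(counts$rsid), out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bulk per-allele trend fits on genotype count vectors
#'
#' Vectorized Newton-Raphson maximum-likelihood fit of the unstratified
#' two-parameter trend logistic model (intercept + genotype dose) across many
#' SNPs simultaneously. Agrees with the [trend_logistic()] `glm` route; used
#' where tens of thousands of fits are needed (subsampling experiments).
#' SNPs whose table is degenerate (absent minor allele, separation or
#' non-convergence) get `NA` estimates.
#'
#' @param case0,case1,case2,ctrl0,ctrl1,ctrl2 equal-length count vectors.
#' @param max_iter,tol Newton-Raphson controls.
#' @return data frame with `theta`, `se`, `z`, `p` per SNP.
#' @export
trend_fit_counts <- function(case0, case1, case2, ctrl0, ctrl1, ctrl2,
                             max_iter = 50L, tol = 1e-10) {
  a <- cbind(case0, case1, case2)
  b <- cbind(ctrl0, ctrl1, ctrl2)
  stopifnot(all(a >= 0), all(b >= 0))
  n <- a + b
  m <- nrow(a)
  dose <- matrix(rep(0:2, each = m), nrow = m)
  tot_case <- rowSums(a)
  tot <- rowSums(n)
  alpha <- stats::qlogis(pmin(pmax(tot_case / tot, 1e-12), 1 - 1e-12))
  beta <- numeric(m)
  active <- rowSums(a[, 2:3, drop = FALSE] + b[, 2:3, drop = FALSE]) > 0 &
    tot_case > 0 & tot_case < tot
  converged <- !active  # inactive rows are flagged NA later
  se <- rep(NA_real_, m)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    eta <- alpha + beta * dose
    pr <- stats::plogis(eta)
    wgt <- n * pr * (1 - pr)
    resid <- a - n * pr
    u1 <- rowSums(resid)
    u2 <- rowSums(dose * resid)
    h11 <- rowSums(wgt)
    h12 <- rowSums(dose * wgt)
    h22 <- rowSums(dose^2 * wgt)
    det <- h11 * h22 - h12^2
    ok <- active & det > 1e-12
    da <- (h22 * u1 - h12 * u2) / det
    db <- (h11 * u2 - h12 * u1) / det
    alpha[ok] <- alpha[ok] + da[ok]
    beta[ok] <- beta[ok] + db[ok]
    done <- ok & pmax(abs(da), abs(db)) < tol
    if (any(done)) {
      se[done] <- sqrt(h11[done] / det[done])
      converged[done] <- TRUE
      active[done] <- FALSE
    }
    active <- active & ok
  }
  bad <- !converged | is.na(se) | abs(beta) > 15
  theta <- ifelse(bad, NA_real_, beta)
  se[bad] <- NA_real_
  z <- theta / se
  data.frame(theta = theta, se = se, z = z,
             p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the proportions implied by the estimated allele frequency.
#' Monomorphic input yields p = 1 with a warning. Vectorized.
#'
#' @param m0,m1,m2 genotype counts (0/1/2 copies of the minor allele),
#'   typically among controls.
#' @return numeric vector of p-values (the chi-square statistic is
#'   `qchisq(p, 1, lower.tail = FALSE)`).
#' @export
hwe_test <- function(m0, m1, m2) {
  n <- m0 + m1 + m2
  stopifnot(all(n > 0))
  f <- (m1 + 2 * m2) / (2 * n)
  mono <- f == 0 | f == 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s): HWE p set to 1", call. = FALSE)
  }
  e0 <- n * (1 - f)^2
  e1 <- n * 2 * f * (1 - f)
  e2 <- n * f^2
  chisq <- ifelse(mono, 0,
                  (m0 - e0)^2 / e0 + (m1 - e1)^2 / e1 + (m2 - e2)^2 / e2)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Genotype quality-control filter
#'
#' Applies the standard pre-association filters: SNPs with genotype call rate
#' below `call_rate_min`, SNPs whose control genotype distribution deviates
#' from Hardy-Weinberg equilibrium at `p < hwe_p_max`, and (report-only, as
#' the interface is counts-level) samples with genotype completion below
#' `completion_min`.
#'
#' @param counts genotype count table (see [trend_logistic()]).
#' @param snp_call_rate optional data frame `rsid`, `call_rate`.
#' @param sample_completion optional data frame `sample_id`, `completion`.
#' @param call_rate_min,completion_min,hwe_p_max thresholds (defaults 0.95,
#'   0.95 and 1e-7).
#' @return list with `counts` (retained SNPs) and `report` (data frame `id`,
#'   `type`, `reason`, `value`, one row per exclusion). Idempotent: filtering
#'   the retained counts again excludes nothing.
#' @export
qc_filter <- function(counts, snp_call_rate = NULL, sample_completion = NULL,
                      call_rate_min = 0.95, completion_min = 0.95,
                      hwe_p_max = 1e-7) {
  .check_counts(counts)
  report <- data.frame(id = character(0), type = character(0),
                       reason = character(0), value = numeric(0),
                       stringsAsFactors = FALSE)
  drop <- character(0)
  if (!is.null(snp_call_rate)) {
    bad <- snp_call_rate[snp_call_rate$call_rate < call_rate_min, ,
                         drop = FALSE]
    if (nrow(bad) > 0L) {
      report <- rbind(report,
                      data.frame(id = bad$rsid, type = "snp",
                                 reason = "call_rate", value = bad$call_rate,
                                 stringsAsFactors = FALSE))
      drop <- union(drop, bad$rsid)
    }
  }
  ctrl <- stats::aggregate(counts[, c("ctrl0", "ctrl1", "ctrl2")],
                           by = list(rsid = counts$rsid), FUN = sum)
  hwe_p <- suppressWarnings(hwe_test(ctrl$ctrl0, ctrl$ctrl1, ctrl$ctrl2))
  bad_hwe <- ctrl$rsid[hwe_p < hwe_p_max]
  if (length(bad_hwe) > 0L) {
    report <- rbind(report,
                    data.frame(id = bad_hwe, type = "snp", reason = "hwe",
                               value = hwe_p[hwe_p < hwe_p_max],
                               stringsAsFactors = FALSE))
    drop <- union(drop, bad_hwe)
  }
  if (!is.null(sample_completion)) {
    bad <- sample_completion[sample_completion$completion < completion_min, ,
                             drop = FALSE]
    if (nrow(bad) > 0L) {
      report <- rbind(report,
                      data.frame(id = as.character(bad$sample_id),
                                 type = "sample", reason = "completion",
                                 value = bad$completion,
                                 stringsAsFactors = FALSE))
    }
  }
  list(counts = counts[!(counts$rsid %in% drop), , drop = FALSE],
       report = report)
}

#' Cochran's Q heterogeneity test
#'
#' Inverse-variance-weighted heterogeneity of effect estimates across strata
#' or study phases: Q = sum w_i (theta_i - theta_bar)^2 with w_i = 1 / V_i
#' and theta_bar the weighted mean, referred to chi-square with k - 1 degrees
#' of freedom.
#'
#' @param theta numeric vector of (log-scale) effect estimates, length >= 2.
#' @param v numeric vector of their variances.
#' @return list with `Q`, `df` and `p`.
#' @export
cochran_q <- function(theta, v) {
  if (length(theta) < 2L) stop("Cochran's Q needs at least two estimates")
  stopifnot(length(theta) == length(v), all(v > 0))
  w <- 1 / v
  tbar <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - tbar)^2)
  k <- length(theta)
  list(Q = q, df = k - 1L,
       p = stats::pchisq(q, df = k - 1L, lower.tail = FALSE))
}

#' Genomic inflation factor
#'
#' lambda = median of the 1-df association chi-square statistics divided by
#' the median of the central chi-square(1) distribution (0.4549364). Values
#' near 1 indicate no systematic inflation.
#'
#' @param p two-sided p-values (converted to chi-square via the normal
#'   quantile), or
#' @param chisq 1-df chi-square statistics directly.
#' @return lambda (scalar).
#' @export
genomic_inflation <- function(p = NULL, chisq = NULL) {
  if (is.null(chisq)) {
    if (is.null(p) || length(p) == 0L) stop("supply p or chisq")
    chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  if (length(chisq) == 0L) stop("empty input")
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
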