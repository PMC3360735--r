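# Bayesian ranking layer: approximate Bayes factor, BFDP, N* sensitivity,
# ranking and replication selection.

#' Recover an absolute Z statistic from a two-sided p-value
#'
#' @param p two-sided p-value in (0, 1].
#' @return non-negative Z (upper-tail standard normal quantile at p/2).
#' @examples
#' z_from_p(0.05)   # 1.959964
#' @export
z_from_p <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must be in (0, 1]")
  }
  stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Prior variance of the log odds ratio from an OR quantile
#'
#' Returns the variance W of a zero-mean normal prior on the log odds ratio
#' whose 97.5% quantile on the OR scale equals `or_quantile`: W =
#' (ln(or_quantile) / 1.959964)^2. The default `or_quantile = 2` encodes the
#' belief that a true association's OR rarely exceeds 2 (or falls below 1/2).
#'
#' @param or_quantile OR value placed at the 97.5% prior quantile (> 1).
#' @return prior variance W.
#' @export
w_prior <- function(or_quantile = 2) {
  stopifnot(is.numeric(or_quantile), or_quantile > 1)
  (log(or_quantile) / stats::qnorm(0.975))^2
}

#' Sampling variance of a log OR from summary statistics
#'
#' Two conventions, selected by `route`:
#' * `"p"`: V = (ln OR / Z)^2 with Z recovered from the two-sided p-value;
#'   requires OR != 1.
#' * `"ci"`: V = ((ln ci_hi - ln ci_lo) / (2 * 1.959964))^2 from a 95%
#'   confidence interval on the OR scale.
#'
#' `"auto"` uses the p route when `or` and `p` are available and falls back
#' to the CI route otherwise. Published tables usually print OR and p at
#' higher fidelity than the CI bounds, hence the p route default.
#'
#' @param or point odds ratio.
#' @param p two-sided p-value.
#' @param ci_lo,ci_hi 95% confidence bounds on the OR scale.
#' @param route `"auto"`, `"p"` or `"ci"`.
#' @return numeric vector of variances V, with attribute `"route"` recording
#'   the convention used.
#' @export
variance_from_summary <- function(or = NULL, p = NULL, ci_lo = NULL,
                                  ci_hi = NULL, route = c("auto", "p", "ci")) {
  route <- match.arg(route)
  have_p <- !is.null(or) && !is.null(p)
  have_ci <- !is.null(ci_lo) && !is.null(ci_hi)
  if (route == "auto") {
    route <- if (have_p) "p" else if (have_ci) "ci" else
      stop("need either (or, p) or (ci_lo, ci_hi)")
  }
  if (route == "p") {
    if (!have_p) stop("p route requires both or and p")
    if (any(or <= 0)) stop("or must be positive")
    if (any(or == 1)) stop("p route undefined at OR = 1 (Z = 0 division)")
    v <- (log(or) / z_from_p(p))^2
  } else {
    if (!have_ci) stop("ci route requires both ci_lo and ci_hi")
    if (any(ci_lo <= 0) || any(ci_hi <= ci_lo)) {
      stop("confidence bounds must satisfy 0 < ci_lo < ci_hi")
    }
    v <- ((log(ci_hi) - log(ci_lo)) / (2 * stats::qnorm(0.975)))^2
  }
  attr(v, "route") <- route
  v
}

#' Wakefield's approximate Bayes factor
#'
#' ABF = exp(-Z^2 r / 2) / sqrt(1 - r) with r = W / (V + W), for a single
#' association parameter with estimated variance V and a zero-mean normal
#' prior of variance W. Values below 1 favor association; W = 0 gives ABF = 1
#' (vacuous prior).
#'
#' @param z standardized statistic (sign irrelevant).
#' @param v sampling variance of the estimate (> 0).
#' @param w prior variance (>= 0), e.g. from [w_prior()].
#' @return approximate Bayes factor (> 0). Vectorized.
#' @export
approximate_bayes_factor <- function(z, v, w) {
  stopifnot(all(v > 0), all(w >= 0))
  r <- w / (v + w)
  exp(-z^2 * r / 2 - 0.5 * log1p(-r))
}

#' Bayes false discovery probability
#'
#' BFDP = ABF * PO / (ABF * PO + 1): the posterior probability that a
#' reported association is a false discovery, given the approximate Bayes
#' factor and the prior odds PO of the null hypothesis.
#'
#' @param abf approximate Bayes factor (> 0).
#' @param po prior odds of H0 (>= 0).
#' @return probability in `[0, 1)`. Vectorized.
#' @examples
#' bfdp(1, 1)    # 0.5
#' @export
bfdp <- function(abf, po) {
  stopifnot(all(abf > 0), all(po >= 0))
  x <- abf * po
  x / (x + 1)
}

#' BFDP sensitivity range over a set of assumed N*
#'
#' BFDP is monotone decreasing in the assumed number of true SNPs N* (more
#' assumed true SNPs means lower prior odds of the null), so the range over a
#' sensitivity set is attained at its extremes: `lo` at the largest N*, `hi`
#' at the smallest.
#'
#' @param abf approximate Bayes factor(s).
#' @param po_set numeric vector (or list of vectors matching `abf`) of prior
#'   odds, one per N* in the sensitivity set.
#' @return list with numeric elements `lo` and `hi`.
#' @export
bfdp_range <- function(abf, po_set) {
  if (is.list(po_set)) {
    vals <- vapply(po_set, function(po) bfdp(abf, po), numeric(length(abf)))
    vals <- matrix(vals, nrow = length(abf))
    return(list(lo = apply(vals, 1L, min), hi = apply(vals, 1L, max)))
  }
  vals <- bfdp(abf, po_set)
  list(lo = min(vals), hi = max(vals))
}

#' Rank association records and select SNPs for replication
#'
#' Records are ranked ascending by central BFDP with deterministic
#' tie-breaking by (p ascending, rsid lexicographic); `rank_p` ranks by p
#' with the same rsid tie-break. A record is selected for replication when
#' its worst-case BFDP over the N* sensitivity set (`bfdp_hi`) falls below
#' `gamma`, i.e. the threshold must hold for every assumed N*.
#'
#' @param records data frame with columns `rsid`, `bfdp`, `p`, and optionally
#'   `bfdp_hi` (defaults to `bfdp`).
#' @param gamma BFDP selection threshold in (0, 1); default 0.8.
#' @return `records` sorted by `rank_bfdp` with added integer columns
#'   `rank_bfdp`, `rank_p` and logical `selected`.
#' @export
rank_and_select <- function(records, gamma = 0.8) {
  stopifnot(is.data.frame(records), gamma > 0, gamma < 1)
  need <- c("rsid", "bfdp", "p")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(records) == 0L) {
    records$rank_bfdp <- integer(0)
    records$rank_p <- integer(0)
    records$selected <- logical(0)
    return(records)
  }
  if (is.null(records$bfdp_hi)) records$bfdp_hi <- records$bfdp
  n <- nrow(records)
  ord_b <- order(records$bfdp, records$p, records$rsid)
  ord_p <- order(records$p, records$rsid)
  records$rank_bfdp <- integer(n)
  records$rank_p <- integer(n)
  records$rank_bfdp[ord_b] <- seq_len(n)
  records$rank_p[ord_p] <- seq_len(n)
  records$selected <- records$bfdp_hi < gamma
  records <- records[order(records$rank_bfdp), , drop = FALSE]
  rownames(records) <- NULL
  records
}

.theta_z_v <- function(stats, v_route) {
  theta <- if (!is.null(stats$beta)) stats$beta else {
    if (is.null(stats$or)) stop("summary statistics need an 'or' or 'beta' column")
    if (any(stats$or <= 0)) stop("or must be positive")
    log(stats$or)
  }
  if (!is.null(stats$se)) {
    # raw regression output takes precedence over derived variances
    v <- stats$se^2
    route <- "se"
    z <- if (!is.null(stats$p)) z_from_p(stats$p) else abs(theta) / stats$se
  } else {
    have_p <- !is.null(stats$p)
    have_ci <- !is.null(stats$ci_lo) && !is.null(stats$ci_hi)
    use <- if (v_route == "auto") {
      if (have_p && all(theta != 0)) "p" else if (have_ci) "ci" else
        stop("cannot derive V: need se, (or/beta, p) or (ci_lo, ci_hi)")
    } else v_route
    if (use == "p") {
      z <- z_from_p(stats$p)
      if (any(theta == 0)) stop("p route undefined at OR = 1 (Z = 0 division)")
      v <- (theta / z)^2
    } else {
      v <- as.numeric(variance_from_summary(ci_lo = stats$ci_lo,
                                            ci_hi = stats$ci_hi,
                                            route = "ci"))
      z <- if (have_p) z_from_p(stats$p) else abs(theta) / sqrt(v)
    }
    route <- use
  }
  list(theta = theta, z = z, v = v, route = route)
}

#' BFDP analysis of GWAS summary statistics with literature-derived priors
#'
#' End-to-end Bayesian layer: joins summary statistics to per-SNP prior
#' categories, derives per-category prior odds from category counts and an
#' assumed number of true susceptibility SNPs (`n_true`, with a sensitivity
#' set), computes approximate Bayes factors and BFDPs, and ranks/selects SNPs
#' for replication.
#'
#' @param stats data frame of summary statistics with columns `rsid`, `or`
#'   (or `beta`), `p`, and optionally `se`, `ci_lo`, `ci_hi`.
#' @param annot annotation table from [annotate_snps()] (columns `rsid`,
#'   `category`), or any data frame with those columns. Category counts for
#'   the priors are taken over all rows of `annot` (the full scan), not just
#'   the SNPs present in `stats`.
#' @param n_true assumed number of true susceptibility SNPs (central value).
#' @param n_true_sens numeric vector of alternative N* values for the
#'   sensitivity range (default `c(50, 500)`).
#' @param allocation allocation of N* across categories; see
#'   [prior_probabilities()].
#' @param w prior variance of the log OR; default [w_prior()] (97.5% OR
#'   quantile of 2).
#' @param gamma BFDP threshold for replication selection.
#' @param v_route variance derivation convention, see
#'   [variance_from_summary()]; a raw `se` column always takes precedence.
#' @param category_priors optional named numeric vector of per-category prior
#'   probabilities of association, overriding the count-derived priors (e.g.
#'   to inject externally reported values). Sensitivity priors are then
#'   scaled linearly in N*.
#' @return data frame with one row per SNP in `stats`: `rsid`, `category`,
#'   `prior`, `po`, `theta`, `v`, `z`, `p`, `abf`, `bfdp`, `bfdp_lo`,
#'   `bfdp_hi`, `rank_bfdp`, `rank_p`, `selected`; sorted by `rank_bfdp`.
#'   Attribute `"v_route"` records the variance convention.
#' @export
bfdp_rank <- function(stats, annot, n_true = 100, n_true_sens = c(50, 500),
                      allocation = "even", w = w_prior(2), gamma = 0.8,
                      v_route = c("auto", "p", "ci"),
                      category_priors = NULL) {
  v_route <- match.arg(v_route)
  stopifnot(is.data.frame(stats), is.data.frame(annot))
  if (nrow(stats) == 0L) stop("summary statistics table is empty")
  if (is.null(stats$rsid) || is.null(annot$rsid) || is.null(annot$category)) {
    stop("stats needs an rsid column; annot needs rsid and category columns")
  }
  idx <- match(stats$rsid, annot$rsid)
  if (anyNA(idx)) {
    orphans <- stats$rsid[is.na(idx)]
    stop("no annotation for rsid(s): ",
         paste(utils::head(orphans, 10L), collapse = ", "),
         if (length(orphans) > 10L) sprintf(" (and %d more)",
                                            length(orphans) - 10L))
  }
  category <- annot$category[idx]
  cats <- sort(unique(annot$category))

  if (is.null(category_priors)) {
    counts <- table(factor(annot$category, levels = cats))
    counts <- stats::setNames(as.numeric(counts), cats)
    prior_of <- function(nt) {
      prior_probabilities(counts, n_true = nt, allocation = allocation)$pr_h1
    }
  } else {
    miss <- setdiff(cats, names(category_priors))
    if (length(miss) > 0L) {
      stop("category_priors missing categories: ", paste(miss, collapse = ", "))
    }
    base <- category_priors[cats]
    prior_of <- function(nt) {
      pr <- base * nt / n_true
      if (any(pr > 1)) stop("scaled category prior exceeds 1 at N* = ", nt)
      pr
    }
  }

  pr_central <- prior_of(n_true)
  tzv <- .theta_z_v(stats, v_route)
  prior <- pr_central[category]
  po <- prior_to_odds(prior)
  abf <- approximate_bayes_factor(tzv$z, tzv$v, w)
  central <- bfdp(abf, po)

  all_nt <- unique(c(n_true, n_true_sens))
  bf_mat <- vapply(all_nt, function(nt) {
    bfdp(abf, prior_to_odds(prior_of(nt)[category]))
  }, numeric(nrow(stats)))
  bf_mat <- matrix(bf_mat, nrow = nrow(stats))

  out <- data.frame(rsid = stats$rsid, category = category,
                    prior = as.numeric(prior), po = as.numeric(po),
                    theta = tzv$theta, v = tzv$v, z = tzv$z,
                    p = if (is.null(stats$p)) NA_real_ else stats$p,
                    abf = abf, bfdp = central,
                    bfdp_lo = apply(bf_mat, 1L, min),
                    bfdp_hi = apply(bf_mat, 1L, max),
                    stringsAsFactors = FALSE)
  out <- rank_and_select(out, gamma = gamma)
  attr(out, "v_route") <- tzv$route
  attr(out, "w") <- w
  out
}

#' Read GWAS summary statistics from TSV
#'
#' Requires a header with at least `rsid` plus `or` or `beta`; optional
#' columns `p`, `se`, `ci_lo`, `ci_hi` are passed through.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_summary_stats <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(x$rsid) || (is.null(x$or) && is.null(x$beta))) {
    stop("summary statistics TSV needs columns rsid and or (or beta)")
  }
  x
}
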