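# Prior model: turn category counts and an assumed number of true
# susceptibility SNPs (N*) into per-category prior probabilities of
# association and prior odds of the null hypothesis.

#' Per-category prior probabilities of association
#'
#' Given the number of SNPs in each literature-evidence category (`counts`,
#' N_j) and an assumed total number of truly associated SNPs (`n_true`, N*)
#' allocated across categories as N*_j, the prior probability that a SNP of
#' category j is associated is Pr(H1 | C_j) = N*_j / N_j, and the prior odds
#' of the null are PO_j = (N_j - N*_j) / N*_j.
#'
#' The default allocation splits N* evenly across categories (the baseline
#' used for category-informed priors); `"proportional"` allocates N*
#' proportionally to the category sizes, which makes every category's prior
#' equal to the overall N*/N -- the flat-prior comparator. Non-integer
#' allocations are permitted.
#'
#' @param counts positive numeric vector of per-category SNP counts N_j
#'   (names retained; defaults to C1..CJ).
#' @param n_true assumed number of truly associated SNPs N* (positive;
#'   default 100).
#' @param allocation `"even"`, `"proportional"`, or an explicit non-negative
#'   numeric vector summing to `n_true`.
#' @return an object of class `prior_spec`: a list with elements `counts`,
#'   `n_true`, `allocation`, `pr_h1` (Pr(H1|C_j)) and `po` (PO_j; `Inf` where
#'   the allocation is zero).
#' @examples
#' prior_probabilities(c(C1 = 149998, C2 = 137576, C3 = 6637), n_true = 100)
#' @export
prior_probabilities <- function(counts, n_true = 100, allocation = "even") {
  if (!is.numeric(counts) || length(counts) < 1L || any(counts <= 0)) {
    stop("counts must be positive")
  }
  if (!is.numeric(n_true) || length(n_true) != 1L || n_true <= 0) {
    stop("n_true must be a positive scalar")
  }
  J <- length(counts)
  if (is.null(names(counts))) names(counts) <- paste0("C", seq_len(J))
  if (is.character(allocation)) {
    allocation <- match.arg(allocation, c("even", "proportional"))
    alloc <- switch(allocation,
                    even = rep(n_true / J, J),
                    proportional = n_true * counts / sum(counts))
  } else {
    alloc <- as.numeric(allocation)
    if (length(alloc) != J || any(alloc < 0)) {
      stop("explicit allocation must be non-negative and match length(counts)")
    }
    if (abs(sum(alloc) - n_true) > 1e-8 * max(1, n_true)) {
      stop("allocation must sum to n_true (", n_true, "), got ", sum(alloc))
    }
  }
  names(alloc) <- names(counts)
  if (any(alloc > counts)) {
    bad <- names(counts)[alloc > counts]
    stop("allocation exceeds category count for ",
         paste(bad, collapse = ", "),
         " (prior probability above 1 is impossible)")
  }
  pr_h1 <- alloc / counts
  po <- ifelse(alloc > 0, (counts - alloc) / alloc, Inf)
  structure(list(counts = counts, n_true = n_true, allocation = alloc,
                 pr_h1 = pr_h1, po = po),
            class = "prior_spec")
}

#' Prior odds of the null hypothesis per category
#'
#' PO_j = (N_j - N*_j) / N*_j, equivalently (1 - Pr(H1|C_j)) / Pr(H1|C_j).
#' Errors when any category has zero allocated true SNPs, since its prior
#' odds would be infinite (no prior mass on H1).
#'
#' @param spec a `prior_spec` from [prior_probabilities()].
#' @return named numeric vector of prior odds.
#' @examples
#' spec <- prior_probabilities(300000 * c(0.875, 0.10, 0.025), n_true = 100)
#' prior_odds(spec)   # 7874, 899, 224 (to the nearest integer)
#' @export
prior_odds <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  if (any(spec$allocation == 0)) {
    bad <- names(spec$allocation)[spec$allocation == 0]
    stop("infinite prior odds: no true SNPs allocated to ",
         paste(bad, collapse = ", "))
  }
  (spec$counts - spec$allocation) / spec$allocation
}

#' Convert between prior probabilities and prior odds of the null
#'
#' `prior_to_odds()` maps a prior probability of association Pr(H1) to the
#' prior odds of the null PO = (1 - Pr(H1)) / Pr(H1); `odds_to_prior()` is
#' its inverse. Useful for injecting externally reported per-category priors.
#'
#' @param prior prior probability of association, in (0, 1].
#' @param po prior odds of the null, >= 0.
#' @return numeric vector.
#' @export
prior_to_odds <- function(prior) {
  stopifnot(all(prior > 0 & prior <= 1))
  (1 - prior) / prior
}

#' @rdname prior_to_odds
#' @export
odds_to_prior <- function(po) {
  stopifnot(all(po >= 0))
  1 / (1 + po)
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior specification: N =", format(sum(x$counts), big.mark = ","),
      "SNPs, N* =", x$n_true, "\n")
  tab <- data.frame(category = names(x$counts), n = as.numeric(x$counts),
                    n_true = round(x$allocation, 3),
                    pr_h1 = signif(x$pr_h1, 3),
                    po = round(x$po, 1))
  print(tab, row.names = FALSE)
  invisible(x)
}
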