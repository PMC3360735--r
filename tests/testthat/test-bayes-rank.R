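test_that("Z recovery from two-sided p-values matches the normal quantile", {
  expect_equal(z_from_p(1), 0)
  expect_equal(z_from_p(0.05), 1.959964, tolerance = 1e-6)
  expect_equal(z_from_p(2.2e-4), 3.694869, tolerance = 1e-6)
  expect_error(z_from_p(0), "in \\(0, 1\\]")
  expect_error(z_from_p(1.5), "in \\(0, 1\\]")
})

test_that("variance derivation follows both published conventions", {
  # frozen from (ln 0.81 / z(2.2e-4))^2
  vp <- variance_from_summary(or = 0.81, p = 2.2e-4, route = "p")
  expect_equal(as.numeric(vp), 0.0032525, tolerance = 1e-4)
  expect_identical(attr(vp, "route"), "p")
  # frozen from ((ln 0.91 - ln 0.72) / (2 * 1.959964))^2
  vc <- variance_from_summary(ci_lo = 0.72, ci_hi = 0.91, route = "ci")
  expect_equal(as.numeric(vc), 0.0035694, tolerance = 1e-4)
  # consistency limit: CI symmetric on the log scale with matching p
  theta <- log(1.4); se <- 0.1
  p <- 2 * pnorm(abs(theta) / se, lower.tail = FALSE)
  v1 <- variance_from_summary(or = 1.4, p = p, route = "p")
  v2 <- variance_from_summary(ci_lo = exp(theta - qnorm(0.975) * se),
                              ci_hi = exp(theta + qnorm(0.975) * se),
                              route = "ci")
  expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-10)
  expect_equal(as.numeric(v1), se^2, tolerance = 1e-10)
  expect_error(variance_from_summary(or = 1, p = 0.5, route = "p"), "OR = 1")
  expect_error(variance_from_summary(route = "auto"), "need either")
})

test_that("approximate Bayes factor follows the shrinkage form", {
  expect_equal(approximate_bayes_factor(3, 0.01, 0), 1)  # vacuous prior
  r <- 0.125 / (0.01 + 0.125)
  expect_equal(approximate_bayes_factor(0, 0.01, 0.125), 1 / sqrt(1 - r))
  expect_gt(approximate_bayes_factor(0, 0.01, 0.125), 1)
  # frozen hand-arithmetic value at the working-example settings
  expect_equal(approximate_bayes_factor(3.6925, 0.003257, w_prior(2)),
               8.169e-3, tolerance = 1e-4)
})

test_that("bfdp converts Bayes factor and prior odds to a posterior", {
  expect_equal(bfdp(1, 1), 0.5)
  expect_equal(bfdp(0.2, 0), 0)
  # full chain for the 4q23 variant: OR 0.81, p 2.2e-4, prior 5.0e-3
  z <- z_from_p(2.2e-4)
  v <- as.numeric(variance_from_summary(or = 0.81, p = 2.2e-4, route = "p"))
  abf <- approximate_bayes_factor(z, v, w_prior(2))
  expect_equal(round(bfdp(abf, prior_to_odds(5.0e-3)), 2), 0.62)
  # sensitivity bounds: more assumed true SNPs lower the BFDP
  pr <- function(nt) (nt / 3) / 6637
  b <- vapply(c(50, 100, 500),
              function(nt) bfdp(abf, prior_to_odds(pr(nt))), numeric(1))
  expect_true(b[3] <= b[2] && b[2] <= b[1])
  expect_equal(round(b[3], 2), 0.24)
  rng <- bfdp_range(abf, prior_to_odds(pr(c(50, 100, 500))))
  expect_equal(rng$lo, b[3])
  expect_equal(rng$hi, b[1])
  # degenerate sensitivity set collapses to the central value
  expect_equal(bfdp_range(abf, prior_to_odds(pr(100)))$lo, b[2])
})

test_that("BFDP is monotone in prior odds and Bayes factor, ABF in Z^2", {
  abf <- c(0.01, 0.1, 1)
  for (a in abf) expect_true(all(diff(bfdp(a, c(1, 10, 100))) > 0))
  for (po in c(1, 100)) expect_true(all(diff(bfdp(abf, po)) > 0))
  z <- seq(0, 5, by = 0.5)
  expect_true(all(diff(approximate_bayes_factor(z, 0.004, 0.125)) < 0))
})

test_that("ranking sorts by BFDP with deterministic tie-breaks", {
  expect_identical(nrow(rank_and_select(
    data.frame(rsid = character(0), bfdp = numeric(0), p = numeric(0)))), 0L)
  two <- data.frame(rsid = c("b", "a"), bfdp = c(0.3, 0.3),
                    p = c(0.01, 0.001))
  r <- rank_and_select(two)
  expect_identical(r$rsid, c("a", "b"))  # lower p first on BFDP ties
  set.seed(51)
  n <- 1000
  recs <- data.frame(rsid = sprintf("rs%04d", sample(n)),
                     bfdp = round(runif(n), 2), p = runif(n))
  recs$bfdp_hi <- pmin(1 - 1e-9, recs$bfdp + runif(n, 0, 0.2))
  r <- rank_and_select(recs, gamma = 0.8)
  ord <- order(recs$bfdp, recs$p, recs$rsid)  # brute-force sort oracle
  expect_identical(r$rsid, recs$rsid[ord])
  expect_identical(r$rank_bfdp, seq_len(n))
  expect_identical(r$selected, r$bfdp_hi < 0.8)
  expect_identical(r$rank_p[order(r$p, r$rsid)], seq_len(n))
})

test_that("bfdp_rank joins, ranks, and reports orphans", {
  annot <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"),
                      category = c("C1", "C2", "C3", "C1"))
  stats <- data.frame(rsid = c("rs1", "rs3"), or = c(1.2, 0.75),
                      p = c(0.01, 1e-5))
  res <- bfdp_rank(stats, annot, n_true = 2, n_true_sens = c(1, 3))
  expect_identical(res$rsid[1], "rs3")  # strong signal + strong prior first
  expect_true(all(res$bfdp_lo <= res$bfdp & res$bfdp <= res$bfdp_hi))
  # priors derive from the full annotation table: C1 has 2 of 4 SNPs
  expect_equal(res$prior[res$rsid == "rs1"], (2 / 3) / 2)
  expect_error(bfdp_rank(data.frame(rsid = "zz", or = 2, p = 0.1), annot),
               "no annotation for rsid")
  expect_error(bfdp_rank(stats[0, ], annot), "empty")
  # injected category priors override the count-derived ones
  res2 <- bfdp_rank(stats, annot, n_true = 100,
                    category_priors = c(C1 = 1e-4, C2 = 1e-3, C3 = 5e-3))
  expect_equal(res2$prior[res2$rsid == "rs3"], 5e-3)
})

test_that("within a category, BFDP rank order equals p-value rank order", {
  set.seed(52)
  n <- 200
  annot <- data.frame(rsid = sprintf("rs%03d", 1:n),
                      category = sample(c("C1", "C2", "C3"), n, TRUE,
                                        prob = c(0.6, 0.3, 0.1)))
  stats <- data.frame(rsid = annot$rsid, beta = rnorm(n, 0, 0.2),
                      se = 0.1)
  stats$p <- 2 * pnorm(abs(stats$beta) / stats$se, lower.tail = FALSE)
  res <- bfdp_rank(stats, annot, n_true = 10, n_true_sens = c(5, 20))
  for (cc in unique(res$category)) {
    sub <- res[res$category == cc, ]
    expect_identical(order(sub$rank_bfdp), order(sub$rank_p))
  }
})
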