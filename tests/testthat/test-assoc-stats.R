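test_that("trend fit is null on a perfectly balanced table", {
  tab <- data.frame(rsid = "s", case0 = 50, case1 = 40, case2 = 10,
                    ctrl0 = 50, ctrl1 = 40, ctrl2 = 10)
  fit <- trend_logistic(tab)
  expect_equal(fit$theta, 0, tolerance = 1e-8)
  expect_equal(fit$or, 1, tolerance = 1e-8)
})

test_that("trend fit matches an independent Newton-Raphson oracle", {
  tab <- data.frame(rsid = "s", case0 = 50, case1 = 40, case2 = 10,
                    ctrl0 = 40, ctrl1 = 45, ctrl2 = 15)
  fit <- trend_logistic(tab)
  ora <- trend_oracle(tab)
  expect_equal(fit$theta, ora$theta, tolerance = 1e-8)
  expect_equal(fit$se, ora$se, tolerance = 1e-8)
  # stratified fit with indicator adjustment
  tab2 <- data.frame(rsid = "s", stratum = c("fr", "uk"),
                     case0 = c(30, 20), case1 = c(25, 15), case2 = c(5, 5),
                     ctrl0 = c(20, 20), ctrl1 = c(25, 20), ctrl2 = c(10, 5))
  fit2 <- trend_logistic(tab2)
  ora2 <- trend_oracle(tab2)
  expect_equal(fit2$theta, ora2$theta, tolerance = 1e-8)
  expect_equal(fit2$se, ora2$se, tolerance = 1e-8)
})

test_that("dominant 2x2 collapse recovers the closed-form cross-product OR", {
  # no minor homozygotes: the trend model is a 2x2 logistic regression
  tab <- data.frame(rsid = "s", case0 = 60, case1 = 40, case2 = 0,
                    ctrl0 = 80, ctrl1 = 20, ctrl2 = 0)
  fit <- trend_logistic(tab)
  expect_equal(fit$or, (40 * 80) / (60 * 20), tolerance = 1e-7)
  expect_equal(fit$se, sqrt(1 / 40 + 1 / 80 + 1 / 60 + 1 / 20),
               tolerance = 1e-7)
})

test_that("degenerate tables are rejected with the SNP named", {
  mono <- data.frame(rsid = "rsMONO", case0 = 100, case1 = 0, case2 = 0,
                     ctrl0 = 100, ctrl1 = 0, ctrl2 = 0)
  expect_error(trend_logistic(mono), "rsMONO.*minor allele absent")
  sep <- data.frame(rsid = "rsSEP", case0 = 0, case1 = 0, case2 = 100,
                    ctrl0 = 100, ctrl1 = 0, ctrl2 = 0)
  expect_error(trend_logistic(sep), "rsSEP")
})

test_that("bulk Newton-Raphson fits agree with the glm route", {
  set.seed(71)
  tabs <- do.call(rbind, lapply(1:50, function(i) {
    random_count_table(sprintf("s%02d", i))
  }))
  bulk <- trend_fit_counts(tabs$case0, tabs$case1, tabs$case2,
                           tabs$ctrl0, tabs$ctrl1, tabs$ctrl2)
  one_by_one <- trend_logistic(tabs)
  expect_equal(bulk$theta, one_by_one$theta, tolerance = 1e-6)
  expect_equal(bulk$se, one_by_one$se, tolerance = 1e-6)
  expect_equal(bulk$p, one_by_one$p, tolerance = 1e-6)
  # degenerate rows yield NA rather than an error in bulk mode
  bulk2 <- trend_fit_counts(c(10, 0), c(0, 0), c(0, 100),
                            c(10, 100), c(0, 0), c(0, 0))
  expect_true(all(is.na(bulk2$theta)))
})

test_that("HWE chi-square test matches the three-cell formula", {
  expect_equal(hwe_test(25, 50, 25), 1)  # exact HWE proportions
  p <- hwe_test(30, 30, 40)
  expect_equal(qchisq(p, 1, lower.tail = FALSE), 15.5188, tolerance = 1e-4)
  expect_equal(p, 8.17e-5, tolerance = 1e-3)
  set.seed(72)
  for (rep in 1:20) {
    m <- as.vector(rmultinom(1, 500, c(0.4, 0.4, 0.2)))
    f <- (m[2] + 2 * m[3]) / (2 * sum(m))
    e <- sum(m) * c((1 - f)^2, 2 * f * (1 - f), f^2)
    chisq <- sum((m - e)^2 / e)  # brute-force formula oracle
    expect_equal(qchisq(hwe_test(m[1], m[2], m[3]), 1, lower.tail = FALSE),
                 chisq, tolerance = 1e-8)
  }
  expect_warning(p1 <- hwe_test(100, 0, 0), "monomorphic")
  expect_equal(p1, 1)
})

test_that("QC filter excludes by call rate and control HWE, and is idempotent", {
  counts <- data.frame(rsid = c("a", "b", "c"),
                       case0 = c(50, 50, 50), case1 = c(30, 30, 30),
                       case2 = c(20, 20, 20),
                       ctrl0 = c(50, 50, 80), ctrl1 = c(30, 30, 0),
                       ctrl2 = c(20, 20, 20))
  cr <- data.frame(rsid = c("a", "b", "c"), call_rate = c(0.99, 0.94, 0.99))
  res <- qc_filter(counts, snp_call_rate = cr)
  expect_identical(sort(res$counts$rsid), "a")
  expect_identical(res$report$reason[res$report$id == "b"], "call_rate")
  expect_identical(res$report$reason[res$report$id == "c"], "hwe")
  # clean data passes untouched
  clean <- qc_filter(counts[1:2, ],
                     snp_call_rate = data.frame(rsid = c("a", "b"),
                                                call_rate = c(1, 1)))
  expect_identical(nrow(clean$report), 0L)
  # idempotent: refiltering the kept set excludes nothing
  again <- qc_filter(res$counts,
                     snp_call_rate = cr[cr$rsid %in% res$counts$rsid, ])
  expect_identical(again$counts, res$counts)
  expect_identical(nrow(again$report), 0L)
  # sample completion is report-only at the counts level
  sc <- data.frame(sample_id = c("s1", "s2"), completion = c(0.90, 0.99))
  res2 <- qc_filter(counts[1:2, ], sample_completion = sc)
  expect_identical(res2$report$id, "s1")
  expect_identical(res2$report$reason, "completion")
})

test_that("Cochran's Q measures inverse-variance-weighted heterogeneity", {
  expect_error(cochran_q(0.5, 0.1), "at least two")
  same <- cochran_q(c(0.2, 0.2, 0.2), c(0.01, 0.02, 0.03))
  expect_equal(same$Q, 0)
  expect_equal(same$p, 1)
  # two phases of the 4q23 variant from printed ORs and CIs
  theta <- log(c(0.81, 0.84))
  v <- (log(c(0.91, 0.94) / c(0.72, 0.75)) / (2 * qnorm(0.975)))^2
  q <- cochran_q(theta, v)
  expect_equal(q$Q, 0.19, tolerance = 0.02)
  expect_equal(q$p, 0.66, tolerance = 0.01)
  # equal variances: Q = sum of squared deviations / v (brute force)
  set.seed(73)
  th <- rnorm(5); vv <- rep(0.04, 5)
  expect_equal(cochran_q(th, vv)$Q, sum((th - mean(th))^2) / 0.04,
               tolerance = 1e-10)
  # permutation invariance
  idx <- sample(5)
  expect_equal(cochran_q(th[idx], vv[idx])$Q, cochran_q(th, vv)$Q)
})

test_that("genomic inflation is the median chi-square ratio", {
  expect_equal(genomic_inflation(chisq = rep(qchisq(0.5, 1), 7)), 1)
  expect_equal(genomic_inflation(chisq = 2 * rep(qchisq(0.5, 1), 7)), 2)
  set.seed(74)
  p <- runif(1e5)
  expect_equal(genomic_inflation(p = p), 1, tolerance = 0.02)
})
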