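test_that("paired_t matches hand computation and handles ties", {
  r <- paired_t(c(3, 4, 5), c(2, 2, 2))       # differences 1, 2, 3
  expect_equal(r$statistic, 2 / (sd(1:3) / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$statistic, 3.4641016, tolerance = 1e-6)
  expect_equal(r$df, 2)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero variance")
})

test_that("wilcoxon signed-rank is exact for small n and symmetric under the null", {
  allpos <- wilcoxon_signed_rank(7:12, rep(0, 6))
  expect_equal(allpos$p_value, 2 / 64)
  sym <- suppressWarnings(
    wilcoxon_signed_rank(c(-1, 1, -2, 2, -3, 3), rep(0, 6)))
  expect_gt(sym$p_value, 0.9)
  expect_error(wilcoxon_signed_rank(c(1, 1), c(1, 1)), "zero")
})

test_that("wilcoxon exact p equals enumeration over sign patterns (n <= 12)", {
  withr::with_seed(51, {
    for (i in 1:6) {
      n <- sample(6:12, 1)
      d <- round(runif(n, 0.5, 10), 3) * sample(c(-1, 1), n, replace = TRUE)
      d <- d[!duplicated(abs(d))]              # exact path needs no ties
      if (length(d) < 6) next
      p_pkg <- wilcoxon_signed_rank(d, rep(0, length(d)))$p_value
      expect_equal(p_pkg, wilcoxon_enum_p(d), tolerance = 1e-9)
    }
  })
})

test_that("sign test matches binomial enumeration and drops ties", {
  r <- sign_test(c(rep(1, 7), -1, 0), c(rep(0, 9)))
  expect_equal(r$p_value, 0.0703125)
  expect_equal(r$n, 8)                        # the zero difference is dropped
  bal <- sign_test(c(1, 1, -1, -1), rep(0, 4))
  expect_equal(bal$p_value, 1)
  withr::with_seed(52, {
    for (i in 1:8) {
      n <- sample(3:12, 1); k <- sample(0:n, 1)
      x <- c(rep(1, k), rep(-1, n - k))
      expect_equal(sign_test(x, rep(0, n))$p_value, sign_enum_p(k, n),
                   tolerance = 1e-12)
    }
  })
})

test_that("sign and signed-rank tests are invariant to common affine rescaling", {
  withr::with_seed(53, {
    x <- rnorm(14); y <- rnorm(14)
    a <- 3.7; b <- -1.2
    expect_equal(sign_test(a * x + b, a * y + b)$p_value,
                 sign_test(x, y)$p_value)
    expect_equal(wilcoxon_signed_rank(a * x + b, a * y + b)$p_value,
                 wilcoxon_signed_rank(x, y)$p_value)
  })
})

test_that("bootstrap median SE approaches the asymptotic value and is seeded", {
  expect_equal(bootstrap_median_se(rep(5, 30), seed = 1), 0)
  # bootstrap-of-median SEs fluctuate noticeably between samples at n = 100;
  # their average over samples settles near the asymptotic 1.2533/sqrt(n)
  ses <- withr::with_seed(54, vapply(1:10, function(i) {
    bootstrap_median_se(rnorm(100), reps = 1000)
  }, numeric(1)))
  expect_lt(abs(mean(ses) - 1.2533 / sqrt(100)) / (1.2533 / sqrt(100)), 0.2)
  y <- c(2.1, 0.3, -1.4, 5.2, 0.9, -0.7, 3.3)
  expect_identical(bootstrap_median_se(y, reps = 200, seed = 9),
                   bootstrap_median_se(y, reps = 200, seed = 9))
})

test_that("pearson_ancova reports r, p and a condition F test", {
  x <- c(1, 2, 3, 4, 5, 6)
  cond <- rep(c("a", "b"), 3)
  perfect <- pearson_ancova(x, 2 * x + 1, cond)
  expect_equal(perfect$r, 1, tolerance = 1e-9)
  expect_lt(perfect$p_value, 1e-9)
  withr::with_seed(55, {
    xx <- rnorm(40)
    cc <- rep(c("retrocue", "control"), 20)
    yy <- 0.5 * xx + ifelse(cc == "retrocue", 1, 0) + rnorm(40, sd = 0.2)
    res <- pearson_ancova(xx, yy, cc)
    expect_lt(res$ancova_p, 0.001)            # intercept shift detected
    expect_equal(res$ancova_df1, 1)
  })
  expect_error(pearson_ancova(rep(1, 5), 1:5, rep("a", 5)), "zero variance")
})

test_that("a null correlation stays small at n = 36", {
  withr::with_seed(56, {
    rs <- vapply(1:40, function(i) {
      pearson_ancova(rnorm(36), rnorm(36), rep(c("a", "b"), 18))$r
    }, numeric(1))
    expect_gte(mean(abs(rs) < 0.33), 0.9)
  })
})
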