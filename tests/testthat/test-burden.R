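# numeric likelihood-maximization oracle for the two-sample Poisson rate LRT
oracle_lr <- function(c1, n1, c2, n2) {
  ll <- function(lambda, count, n) {
    if (lambda <= 0) return(if (count == 0) 0 else -Inf)
    count * log(lambda) - n * lambda
  }
  upper <- max((c1 + c2) / (n1 + n2), c1 / n1, c2 / n2, 1e-6) * 10 + 1
  opt1 <- stats::optimize(function(l) ll(l, c1, n1), c(1e-9, upper),
                          maximum = TRUE, tol = 1e-12)$objective
  opt2 <- stats::optimize(function(l) ll(l, c2, n2), c(1e-9, upper),
                          maximum = TRUE, tol = 1e-12)$objective
  opt0 <- stats::optimize(function(l) ll(l, c1, n1) + ll(l, c2, n2),
                          c(1e-9, upper), maximum = TRUE, tol = 1e-12)$objective
  if (c1 == 0) opt1 <- 0
  if (c2 == 0) opt2 <- 0
  2 * (opt1 + opt2 - opt0)
}

test_that("size bins follow the <100 / 100-400 / >400 kb table layout", {
  expect_equal(as.character(size_bin(c(99, 100, 400, 401))),
               c("lt100kb", "100to400kb", "100to400kb", "gt400kb"))
})

test_that("stratification reproduces table margins and excludes Y", {
  fx <- make_paper_fixture_cohort()
  rare <- select_rare(cluster_loci(fx$calls), fx$manifest)
  a <- stratify_calls(rare, fx$manifest, "autosomal")
  pick <- function(s, type, bin, col) s[s$cnv_type == type & s$size_bin == bin, col]
  expect_equal(pick(a, "deletion", "total", "case_count"), 439)
  expect_equal(pick(a, "both", "total", "case_count"), 907)
  expect_equal(pick(a, "both", "total", "control_count"), 843)
  x <- stratify_calls(rare, fx$manifest, "x_male")
  expect_equal(pick(x, "both", "total", "case_count"), 65)
  expect_equal(pick(x, "both", "total", "control_count"), 6)
  expect_equal(unique(x$case_n), 299)
  expect_equal(unique(x$control_n), 525)

  withY <- rbind(rare[1, ], rare[1, ])
  withY$chrom[2] <- "Y"
  sY <- stratify_calls(withY, fx$manifest, "autosomal")
  expect_equal(attr(sY, "n_excluded_chrom"), 1)
})

test_that("per-subject rates match the published margins after rounding", {
  expect_equal(round(cnv_rate(907, 335), 2), 2.71)
  expect_equal(round(cnv_rate(843, 1093), 2), 0.77)
  expect_equal(round(cnv_rate(65, 299), 3), 0.217)
  expect_equal(cnv_rate(0, 50), 0)
  expect_error(cnv_rate(1, 0), "positive")
})

test_that("rate LRT is zero at equal rates and scales with counts", {
  eq <- rate_lr_test(10, 100, 10, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(rate_lr_test(0, 50, 0, 50)$statistic, 0)
  one <- rate_lr_test(5, 50, 0, 50)
  two <- rate_lr_test(10, 100, 0, 100)
  expect_equal(two$statistic, 2 * one$statistic)  # closed-form doubling
  expect_gte(one$statistic, 0)
  expect_error(rate_lr_test(-1, 10, 0, 10), "non-negative")
})

test_that("rate LRT agrees with the numeric likelihood-maximization oracle", {
  expect_equal(rate_lr_test(5, 50, 0, 50)$statistic, oracle_lr(5, 50, 0, 50),
               tolerance = 1e-8)
  set.seed(123)
  for (k in 1:25) {
    c1 <- rpois(1, 20); c2 <- rpois(1, 5)
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    expect_equal(rate_lr_test(c1, n1, c2, n2)$statistic,
                 oracle_lr(c1, n1, c2, n2), tolerance = 1e-6)
  }
})

test_that("the contingency G-test variant runs and differs from the rate test", {
  g <- rate_lr_test(50, 335, 30, 1093, method = "contingency")
  expect_gt(g$statistic, 0)
  expect_lt(g$p_value, 1)
})

test_that("Bonferroni flagging uses the strict stated threshold", {
  cells <- data.frame(p_value = c(0.004, 0.005, 0.006))
  out <- apply_bonferroni(cells)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  exact <- apply_bonferroni(cells, alpha = 0.05, m = 12, threshold = NULL)
  expect_equal(exact$significant, c(TRUE, FALSE, FALSE))  # 0.05/12 = 0.00417
})

test_that("burden table is additive and degenerates cleanly with no calls", {
  manifest <- make_manifest(10, 10)
  empty <- make_calls("1", 1e6, 1.1e6)[0, ]
  tbl <- build_burden_table(empty, manifest, "autosomal")
  expect_true(all(tbl$case_count == 0))
  expect_true(all(tbl$lr_chisq == 0))
  expect_false(any(tbl$significant))
  expect_equal(nrow(tbl), 12)
})
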