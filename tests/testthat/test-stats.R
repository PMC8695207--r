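make_group <- function(n, seed, logp_mean = 2.9) {
  generate_library(local({
    s <- herbicide_like_spec(n = n, seed = seed)
    s$continuous["logp", "mean"] <- logp_mean
    s
  }))
}

test_that("identical groups give t = 0, p = 1 on every descriptor row", {
  g <- make_group(10, 31)
  cmp <- compare_descriptors(g, g)
  expect_equal(nrow(cmp), 9L)   # formal charge is excluded (Fisher handles it)
  expect_true(all(abs(cmp$t_stat) < 1e-12))
  expect_true(all(cmp$p_value > 1 - 1e-12))
  expect_false(any(cmp$significant))
})

test_that("well-separated constant-plus-jitter groups reach any alpha", {
  a <- do.call(rbind, lapply(1:4, function(i)
    as.data.frame(c(list(compound_id = paste0("A", i)),
                    at_reference(logp = 0 + i * 1e-6)))))
  b <- do.call(rbind, lapply(1:4, function(i)
    as.data.frame(c(list(compound_id = paste0("B", i)),
                    at_reference(logp = 1 + i * 1e-6)))))
  cmp <- compare_descriptors(a, b)
  expect_lt(cmp$p_value[cmp$descriptor == "logp"], 1e-9)
  expect_true(cmp$significant[cmp$descriptor == "logp"])
})

test_that("swapping the groups negates t and preserves p", {
  a <- make_group(15, 32); b <- make_group(20, 33, logp_mean = 4.2)
  ab <- compare_descriptors(a, b)
  ba <- compare_descriptors(b, a)
  expect_equal(ab$t_stat, -ba$t_stat)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("pooled and Welch variants agree for equal sizes/variances but are distinct tests", {
  a <- make_group(18, 34); b <- make_group(12, 35)
  pooled <- compare_descriptors(a, b, variant = "pooled")
  welch <- compare_descriptors(a, b, variant = "welch")
  expect_identical(attr(pooled, "variant"), "pooled")
  expect_identical(attr(welch, "variant"), "welch")
  # same t statistics pair against stats::t.test run directly
  d <- "logp"
  expect_equal(pooled$p_value[pooled$descriptor == d],
               stats::t.test(a[[d]], b[[d]], var.equal = TRUE)$p.value)
  expect_equal(welch$p_value[welch$descriptor == d],
               stats::t.test(a[[d]], b[[d]])$p.value)
})

test_that("the charge table dichotomises at >= +1 and balanced tables give p = 1", {
  a <- do.call(rbind, lapply(1:2, function(i)
    as.data.frame(c(list(compound_id = paste0("A", i)),
                    at_reference(formal_charge74 = c(1L, 0L)[i])))))
  b <- a; b$compound_id <- c("B1", "B2")
  fz <- fisher_charge_test(a, b)
  expect_equal(unname(fz$table), cbind(c(1, 1), c(1, 1)))
  expect_equal(fz$p_value, 1)
})

test_that("a fully separated 3/3 table gives the enumerated two-sided p of 0.1", {
  # all tables with these margins: p(observed) = 1/C(6,3); doubling by
  # symmetry gives 2/20
  a <- do.call(rbind, lapply(1:3, function(i)
    as.data.frame(c(list(compound_id = paste0("A", i)),
                    at_reference(formal_charge74 = 1L)))))
  b <- do.call(rbind, lapply(1:3, function(i)
    as.data.frame(c(list(compound_id = paste0("B", i)),
                    at_reference(formal_charge74 = 0L)))))
  fz <- fisher_charge_test(a, b)
  expect_equal(fz$p_value, 0.1)
  expect_identical(fz$odds_ratio, Inf)
})

test_that("charge CDFs are non-decreasing, end at 1 and match hand counts", {
  rec <- do.call(rbind, lapply(1:3, function(i)
    as.data.frame(c(list(compound_id = paste0("C", i)),
                    at_reference(formal_charge74 = c(0L, 0L, -1L)[i])))))
  cdf <- charge_cdf(rec)
  expect_equal(cdf$cum_fraction[cdf$charge == -1], 1 / 3)
  expect_equal(cdf$cum_fraction[cdf$charge == 0], 1)
  # all-neutral group: single step at zero
  neutral <- rec; neutral$formal_charge74 <- 0L
  expect_equal(charge_cdf(neutral),
               data.frame(charge = 0L, cum_fraction = 1))
  # property over random draws
  set.seed(41)
  for (i in 1:5) {
    r <- rec[rep(1, 30), ]
    r$formal_charge74 <- sample(-2:2, 30, replace = TRUE)
    cc <- charge_cdf(r)
    expect_true(all(diff(cc$cum_fraction) >= 0))
    expect_equal(cc$cum_fraction[nrow(cc)], 1)
  }
})

test_that("empirical charge CDF stays inside the DKW band of its generator", {
  # DKW: P(sup|F_n - F| > eps) <= 2 exp(-2 n eps^2); at n = 2000 and 99%
  # confidence eps = sqrt(log(2/0.01) / (2n)) ~ 0.036
  n <- 2000
  lib <- generate_library(herbicide_like_spec(n = n, seed = 51))
  probs <- c(0.020, 0.250, 0.722, 0.006, 0.002)
  truth <- cumsum(probs)
  cdf <- charge_cdf(lib)
  eps <- sqrt(log(2 / 0.01) / (2 * n))
  obs <- cdf$cum_fraction[match(-2:2, cdf$charge)]
  obs[is.na(obs)] <- truth[is.na(obs)]   # charges never drawn
  expect_true(all(abs(obs - truth) <= eps))
})

test_that("percentile intervals interpolate order statistics and respect affine maps", {
  grid <- data.frame(x = 0:10)
  expect_equal(unname(percentile_interval(grid, "x", 0.8)), c(1, 9))
  rep1 <- data.frame(x = rep(4.2, 7))
  expect_equal(unname(percentile_interval(rep1, "x", 0.8)), c(4.2, 4.2))
  # affine equivariance
  set.seed(61)
  df <- data.frame(x = rnorm(200))
  pi0 <- percentile_interval(df, "x", 0.8)
  df2 <- data.frame(x = 3 * df$x + 7)
  expect_equal(unname(percentile_interval(df2, "x", 0.8)),
               unname(3 * pi0 + 7))
  # large normal sample approaches mu +/- 1.2816 sigma
  big <- data.frame(x = rnorm(50000, 2, 1.5))
  pib <- percentile_interval(big, "x", 0.8)
  expect_equal(unname(pib), 2 + c(-1, 1) * stats::qnorm(0.9) * 1.5,
               tolerance = 0.03)
})

test_that("score histograms conserve counts on half-point-aligned bins", {
  hg <- score_histogram(c(18, 18), bin_width = 1)
  expect_equal(sum(hg$count), 2)
  expect_equal(hg$count[hg$bin_low == 17], 2)
  expect_equal(min(hg$bin_low), -12)
  expect_equal(max(hg$bin_high), 18)
  set.seed(71)
  for (i in 1:5) {
    sc <- sample(seq(-12, 18, by = 0.5), 40, replace = TRUE)
    hg <- score_histogram(sc, bin_width = 0.5)
    expect_equal(sum(hg$count), 40)
  }
  # a herbicide-like library concentrates mass in the top third of the range
  lib <- generate_library(herbicide_like_spec(n = 400, seed = 72))
  totals <- score_library(lib)$scores$total
  hg <- score_histogram(totals)
  top_third <- hg$bin_low >= 8
  expect_gt(sum(hg$count[top_third]) / sum(hg$count), 0.5)
})
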