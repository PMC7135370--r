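test_that("Fisher enrichment matches hypergeometric enumeration", {
  set_a <- c(rep(TRUE, 100), rep(FALSE, 900))
  set_b <- c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 5), rep(FALSE, 895))
  got <- fisher_enrichment(set_b, set_a)
  ft <- fisher.test(matrix(c(895, 5, 90, 10), 2))
  expect_equal(got$p, ft$p.value, tolerance = 1e-12)
  # brute-force two-sided p by enumerating the hypergeometric support
  m <- 15; n_ <- 985; k <- 100
  probs <- dhyper(0:15, m, n_, k)
  p_brute <- sum(probs[probs <= dhyper(10, m, n_, k) * (1 + 1e-7)])
  expect_equal(got$p, p_brute, tolerance = 1e-9)
  # complete containment reports an infinite odds ratio
  inf <- fisher_enrichment(c(TRUE, TRUE, FALSE, FALSE),
                           c(TRUE, TRUE, TRUE, FALSE))
  expect_true(is.infinite(inf$odds_ratio) || inf$odds_ratio > 1)
})

test_that("independent flags give an odds ratio CI covering 1", {
  set.seed(81)
  cover <- vapply(1:20, function(i) {
    a <- runif(400) < 0.3; b <- runif(400) < 0.2
    ft <- fisher.test(table(a, b))
    ft$conf.int[1] <= 1 && ft$conf.int[2] >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("bootstrap percentage CI is exact in the degenerate case, has the
           binomial width, and is seed-stable", {
  all1 <- bootstrap_percent_ci(rep(1, 50), seed = 1)
  expect_equal(c(all1$percent, all1$lo, all1$hi), c(100, 100, 100))
  set.seed(82)
  flags <- rbinom(1000, 1, 0.3)
  ci <- bootstrap_percent_ci(flags, B = 2000, seed = 3)
  width <- ci$hi - ci$lo
  expected <- 2 * 1.96 * sqrt(mean(flags) * (1 - mean(flags)) / 1000) * 100
  expect_lt(abs(width - expected) / expected, 0.3)
  ci2 <- bootstrap_percent_ci(flags, B = 2000, seed = 3)
  expect_identical(ci, ci2)
})

test_that("permutation fit test: maximal separation, error paths, and null
           calibration", {
  set.seed(83)
  S <- rpois(60, 5) + 1
  lab <- rep(c(TRUE, FALSE), 30)
  stat <- as.numeric(lab) # R^2 = 1 given the label
  pt <- permutation_fit_test(stat + rnorm(60, 0, 1e-6), S, lab,
                             n_perm = 500, seed = 1)
  expect_equal(pt$p, 1 / 501, tolerance = 1e-12)
  expect_error(permutation_fit_test(rep(1, 60), S, lab, 100, 1), "constant")
  expect_error(permutation_fit_test(rnorm(60), S, rep(TRUE, 60), 100, 1),
               "class")
  # exchangeability: null p-values approximately uniform
  ps <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    permutation_fit_test(rnorm(40), rpois(40, 4) + 1,
                         sample(rep(c(TRUE, FALSE), 20)),
                         n_perm = 200, seed = i)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_gt(mean(ps <= 0.05), 0.01)
  expect_lt(mean(ps <= 0.05), 0.10)
})

test_that("diversity model recovers a planted coefficient and matches the
           normal equations", {
  set.seed(84)
  cover <- vapply(1:20, function(i) {
    k <- rnorm(300); lv <- rnorm(300); vr <- rnorm(300)
    theta <- -0.1 * k + rnorm(300, 0, 0.95)
    m <- diversity_connectivity_model(theta, k, lv, vr)
    # beta is on the standardized scale: convert the planted slope
    b_std <- -0.1 * sd(k) / sd(theta)
    m$ci["connectivity", 1] <= b_std && b_std <= m$ci["connectivity", 2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
  # 8-gene toy against an explicit solve
  k <- c(1, 2, 3, 4, 5, 6, 7, 8.5)
  lv <- c(2, 1, 4, 3, 6, 5, 8, 7)
  vr <- c(1, 3, 2, 5, 4, 7, 6, 8)
  th <- c(0.9, 0.8, 0.75, 0.6, 0.55, 0.4, 0.35, 0.2)
  m <- suppressWarnings(diversity_connectivity_model(th, k, lv, vr,
                                                     subset = rep(TRUE, 8)))
  X <- cbind(1, scale(k), scale(lv), scale(vr))
  beta <- solve(crossprod(X), crossprod(X, scale(th)))
  expect_equal(unname(m$beta), as.numeric(beta[2:4]), tolerance = 1e-8)
  # pure-noise response explains almost nothing
  set.seed(85)
  r2s <- vapply(1:10, function(i)
    diversity_connectivity_model(rnorm(400), rnorm(400), rnorm(400),
                                 rnorm(400))$r_squared, numeric(1))
  expect_lt(median(r2s), 0.02)
})

test_that("connectivity-outlier model has R^2 = 1 when the response is the
           flag and covers 0 under random labels", {
  out <- rep(c(TRUE, FALSE), 25)
  m <- connectivity_outlier_model(as.numeric(out) + rnorm(50, 0, 1e-8),
                                  rnorm(50), rnorm(50), out)
  expect_gt(m$r_squared, 0.999)
  set.seed(86)
  cover <- vapply(1:20, function(i) {
    k <- rnorm(200)
    lab <- sample(c(TRUE, FALSE), 200, TRUE)
    mm <- connectivity_outlier_model(k, rnorm(200), rnorm(200), lab)
    mm$ci["outlier", 1] <= 0 && mm$ci["outlier", 2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("logistic enrichment model recovers a planted odds ratio and its
           null CI covers zero", {
  set.seed(87)
  recov <- vapply(1:20, function(i) {
    out <- rbinom(600, 1, 0.3)
    p <- plogis(qlogis(0.15) + log(3) * out)
    is_e <- rbinom(600, 1, p)
    m <- eqtl_outlier_logistic(is_e == 1, rpois(600, 5) + 1, out == 1)
    m$ci[1] <= log(3) && log(3) <= m$ci[2]
  }, logical(1))
  expect_gte(mean(recov), 0.9)
  nullcover <- vapply(1:40, function(i) {
    is_e <- rbinom(400, 1, 0.2)
    out <- rbinom(400, 1, 0.3)
    m <- eqtl_outlier_logistic(is_e == 1, rpois(400, 5) + 1, out == 1)
    m$ci[1] <= 0 && 0 <= m$ci[2]
  }, logical(1))
  expect_gte(mean(nullcover), 0.9)
})

test_that("separation triggers the penalized fallback with finite output", {
  is_e <- c(rep(TRUE, 20), rep(FALSE, 30))
  out <- is_e                       # perfect separation
  m <- suppressWarnings(eqtl_outlier_logistic(is_e, rpois(50, 4) + 1, out))
  expect_true(m$firth)
  expect_true(is.finite(m$beta_outlier))
  expect_true(is.finite(m$se_outlier))
})

test_that("connectivity/p-value trend summary classifies the three
           constructions", {
  set.seed(88)
  k <- runif(300, 0, 10)
  dn <- connectivity_pvalue_trend(k, exp(-0.5 * k) + rnorm(300, 0, 0.02))
  expect_equal(dn$trend, -1L)
  expect_false(dn$interior_mode)
  fl <- connectivity_pvalue_trend(k, runif(300))
  expect_equal(fl$trend, 0L)
  dip <- connectivity_pvalue_trend(k, (k - 5)^2 / 10 + rnorm(300, 0, 0.05))
  expect_true(dip$interior_mode)
})
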