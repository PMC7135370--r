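test_that("expression PC correction removes rank-1 structure and is the
           identity at n_pcs = 0", {
  set.seed(61)
  f <- rnorm(40)
  load <- runif(100, 0.5, 1.5)
  em <- load %o% f + matrix(rnorm(4000, 0, 0.05), 100)
  emc <- correct_expression(em, 1)
  expect_lt(sum(emc^2) / sum(scale(t(em), scale = FALSE)^2), 0.01)
  expect_identical(correct_expression(em, 0), em)
  expect_error(correct_expression(em, 40), "smaller")
})

test_that("correction removes the planted north-south expression gradient", {
  cfg <- small_cfg(seed = 62)
  sim <- suppressWarnings(simulate_genotypes(cfg))
  ex <- simulate_expression(cfg, sim$gm, sim$truth)
  lat <- sim$gm$sample_meta$lat
  pc1_before <- prcomp(t(ex$em))$x[, 1]
  expect_gt(abs(cor(pc1_before, lat)), 0.8)
  emc <- correct_expression(ex$em, 2)
  pc1_after <- prcomp(t(emc))$x[, 1]
  expect_lt(abs(cor(pc1_after, lat)), 0.2)
})

test_that("association t and p are invariant to adding covariate
           combinations to the expression", {
  cfg <- small_cfg(seed = 63)
  sim <- suppressWarnings(simulate_genotypes(cfg))
  gmf <- suppressWarnings(apply_filters(sim$gm, filter_spec()))$gm
  ex <- simulate_expression(cfg, gmf, sim$truth)
  qcols <- grep("^q[0-9]+$", names(gmf$sample_meta), value = TRUE)
  covs <- as.matrix(gmf$sample_meta[, qcols])
  em <- ex$em[1:40, ]
  r1 <- map_eqtl(gmf, em, covariates = covs, alpha_q = 0.2)
  em2 <- em + matrix(rep(2.5 * covs[, 1] - covs[, 2], each = nrow(em)),
                     nrow(em))
  r2 <- map_eqtl(gmf, em2, covariates = covs, alpha_q = 0.2)
  key <- function(r) r$associations[order(r$associations$site_id,
                                          r$associations$target), ]
  expect_equal(key(r1)$t, key(r2)$t, tolerance = 1e-8)
  expect_equal(key(r1)$p, key(r2)$p, tolerance = 1e-8)
})

test_that("planted pairs are recovered with high power and nulls are
           calibrated", {
  hits <- vapply(1:5, function(s) {
    set.seed(700 + s)
    n <- 74
    dose <- rbinom(n, 2, 0.4)
    y <- 1.5 * dose + rnorm(n, 0, 0.5)
    # embed in a small null background
    gm <- make_gm(cbind(dose, matrix(rbinom(n * 30, 2, 0.3), n)))
    em <- rbind(y, matrix(rnorm(20 * n), 20))
    rownames(em) <- c("t1", paste0("n", 1:20))
    r <- map_eqtl(gm, em)
    any(r$associations$site_id == gm$site_meta$site_id[1] &
          r$associations$target == "t1")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # all-null: fraction of p < 0.05 within [0.03, 0.07]
  set.seed(71)
  gm0 <- make_gm(matrix(rbinom(74 * 40, 2, 0.35), 74))
  em0 <- matrix(rnorm(50 * 74), 50)
  rownames(em0) <- paste0("x", 1:50)
  r0 <- map_eqtl(gm0, em0, alpha_q = 0.05)
  # the candidate cap retains every pair with p below it, so counting
  # p < 0.05 among retained pairs is exact
  p_below <- sum(r0$candidates$p < 0.05) / r0$n_tests
  expect_gt(p_below, 0.03)
  expect_lt(p_below, 0.07)
})

test_that("constant-dosage SNPs are skipped with a count", {
  n <- 30
  gm <- make_gm(cbind(rep(1L, n), rbinom(n, 2, 0.5)))
  em <- matrix(rnorm(5 * n), 5, dimnames = list(paste0("g", 1:5), NULL))
  r <- map_eqtl(gm, em)
  expect_equal(r$n_skipped, 1)
  expect_false(gm$site_meta$site_id[1] %in% r$associations$site_id)
})

test_that("is_both is the conjunction of the eQTL and eGene flags", {
  cfg <- small_cfg(seed = 64)
  sim <- suppressWarnings(simulate_genotypes(cfg))
  gmf <- suppressWarnings(apply_filters(sim$gm, filter_spec()))$gm
  ex <- simulate_expression(cfg, gmf, sim$truth)
  r <- map_eqtl(gmf, correct_expression(ex$em, 2),
                covariates = as.matrix(gmf$sample_meta[, c("q1", "q2", "q3",
                                                           "q4")]))
  expect_identical(r$genes$is_both, r$genes$is_eqtl & r$genes$is_egene)
  expect_true(all(r$genes$n_targets[r$genes$is_eqtl] >= 1))
})

test_that("the eGenes-per-eQTL logistic model matches a hand IRLS solve and
           detects planted multi-target outliers", {
  # 12-row hand toy against an independent IRLS implementation
  y <- c(0, 0, 0, 0, 1, 1, 0, 1, 0, 1, 1, 1)
  xo <- c(0, 0, 1, 0, 1, 1, 0, 1, 0, 0, 1, 0)
  xs <- c(2, 3, 8, 1, 9, 7, 2, 6, 3, 5, 8, 2)
  irls <- function(y, X) {
    b <- rep(0, ncol(X))
    for (i in 1:50) {
      mu <- plogis(X %*% b)
      W <- as.numeric(mu * (1 - mu))
      b <- b + solve(crossprod(X, X * W), crossprod(X, y - mu))
    }
    b
  }
  oracle <- irls(y, cbind(1, xo, xs))
  fit <- glm(y ~ xo + xs, family = binomial())
  expect_equal(unname(coef(fit)), as.numeric(oracle), tolerance = 1e-6)
  # construction: outlier eQTLs regulate more targets
  genes <- data.frame(gene = paste0("g", 1:60),
                      is_eqtl = TRUE, is_egene = FALSE, is_both = FALSE,
                      n_targets = c(rep(3, 20), rep(1, 40)))
  res <- structure(list(genes = genes), class = "eqtl_result")
  S <- setNames(rpois(60, 5) + 1, genes$gene)
  outlier <- setNames(c(rep(TRUE, 20), rep(FALSE, 40)), genes$gene)
  m <- egene_count_model(res, S, outlier)
  expect_gt(m$beta_outlier, 0)
  expect_lt(m$p, 0.05)
})

test_that("random labels give covering CIs in the count model", {
  set.seed(65)
  cover <- vapply(1:20, function(i) {
    genes <- data.frame(gene = paste0("g", 1:80), is_eqtl = TRUE,
                        is_egene = FALSE, is_both = FALSE,
                        n_targets = 1 + rbinom(80, 2, 0.3))
    res <- structure(list(genes = genes), class = "eqtl_result")
    S <- setNames(rpois(80, 5) + 1, genes$gene)
    outlier <- setNames(sample(c(TRUE, FALSE), 80, TRUE), genes$gene)
    m <- egene_count_model(res, S, outlier)
    m$ci[1] < 0 && m$ci[2] > 0
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})
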