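test_that("genotype PCA scores are orthogonal and pruning halves exact
           duplicates", {
  cfg <- small_cfg(seed = 51)
  gm <- suppressWarnings(simulate_genotypes(cfg))$gm
  pca <- genotype_pca(gm, 4)
  gram <- crossprod(pca$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-6)
  # duplicate every polymorphic SNP, prune at r2 = 0.99
  gm <- suppressWarnings(apply_filters(gm, filter_spec()))$gm
  dup <- subset_genotypes(gm, sites = rep(seq_len(n_sites(gm)), each = 2))
  dup$site_meta$site_id <- paste0(dup$site_meta$site_id, "_",
                                  seq_len(n_sites(dup)))
  pr <- genotype_pca(dup, 2, ld_prune = list(r2_max = 0.99, window = 200))
  expect_equal(length(pr$kept), n_sites(gm))
  expect_error(genotype_pca(gm, 0), "positive")
})

test_that("pcadapt null calibration: lambda near 1 and uniform p", {
  lams <- c(); ps <- c()
  for (s in 1:4) {
    cfg <- synth_config(n_genes = 150, mean_sites = 5, n_clusters = 1,
                        fst_between_clusters = 0, ibd_slope = 0,
                        frac_outlier_genes = 0, seed = 400 + s)
    gm <- suppressWarnings(simulate_genotypes(cfg))$gm
    gmf <- suppressWarnings(apply_filters(gm, filter_spec()))$gm
    sc <- pcadapt_scan(gmf, 4)
    lams <- c(lams, sc$lambda)
    ps <- c(ps, sc$snps$p)
  }
  expect_true(all(lams > 0.8 & lams < 1.2))
  expect_gt(ks.test(ps[!is.na(ps)], "punif")$p.value, 0.01)
})

test_that("a SNP matching PC1 tops the pcadapt ranking", {
  cfg <- small_cfg(seed = 52)
  gm <- suppressWarnings(simulate_genotypes(cfg))$gm
  pca <- genotype_pca(gm, 2)
  planted <- as.integer(cut(pca$scores[, 1], c(-Inf, quantile(pca$scores[, 1],
                                                              c(1 / 3, 2 / 3)),
                                               Inf))) - 1L
  gm$dosages[, 1] <- planted
  sc <- pcadapt_scan(gm, 4)
  expect_lte(rank(-sc$snps$stat)[1], 3)
})

test_that("scans recover planted clinal SNPs with high AUC at defaults", {
  cfg <- synth_config(n_genes = 400, mean_sites = 8, seed = 53)
  sim <- suppressWarnings(simulate_genotypes(cfg))
  gmf <- suppressWarnings(apply_filters(sim$gm, filter_spec()))$gm
  tr_snp <- gmf$site_meta$site_id %in% sim$truth$clinal_sites
  sd <- pcadapt_scan(gmf, 4)
  se <- env_association_scan(gmf, sim$truth$env_pc_values, 4)
  expect_gt(rank_auc(sd$snps$stat, tr_snp), 0.9)
  expect_gt(rank_auc(-log(se$snps$p), tr_snp), 0.9)
})

test_that("pure-noise environmental axes give uniform p-values", {
  ps <- unlist(lapply(1:4, function(s) {
    cfg <- synth_config(n_genes = 150, mean_sites = 5, n_clusters = 1,
                        fst_between_clusters = 0, ibd_slope = 0,
                        frac_outlier_genes = 0, seed = 500 + s)
    sim <- suppressWarnings(simulate_genotypes(cfg))
    gmf <- suppressWarnings(apply_filters(sim$gm, filter_spec()))$gm
    set.seed(s)
    env <- matrix(rnorm(cfg$n_pops), cfg$n_pops,
                  dimnames = list(sprintf("P%02d", 1:cfg$n_pops), NULL))
    env_association_scan(gmf, env, 4)$snps$p
  }))
  expect_gt(ks.test(ps[!is.na(ps)], "punif")$p.value, 0.01)
})

test_that("an env axis collinear with structure loses power versus an
           orthogonal one", {
  cfg <- synth_config(n_genes = 300, mean_sites = 8, seed = 54)
  sim <- suppressWarnings(simulate_genotypes(cfg))
  gmf <- suppressWarnings(apply_filters(sim$gm, filter_spec()))$gm
  tr <- gmf$site_meta$gene %in% sim$truth$outlier_genes
  env_lat <- sim$truth$env_pc_values[, 1, drop = FALSE]
  auc_lat <- rank_auc(-log(env_association_scan(gmf, env_lat, 4)$snps$p), tr)
  # orthogonal-to-cline axis: pure noise carries no signal at all
  set.seed(99)
  env_noise <- matrix(rnorm(cfg$n_pops), cfg$n_pops,
                      dimnames = list(rownames(sim$truth$env_pc_values), NULL))
  auc_noise <- rank_auc(-log(env_association_scan(gmf, env_noise, 4)$snps$p),
                        tr)
  expect_gt(auc_lat, auc_noise)
})

test_that("pcadapt is invariant to allele-label flips", {
  cfg <- small_cfg(seed = 55)
  gm <- suppressWarnings(simulate_genotypes(cfg))$gm
  sc1 <- pcadapt_scan(gm, 3)
  gm2 <- gm
  flip <- seq(1, n_sites(gm), by = 2)
  gm2$dosages[, flip] <- 2L - gm2$dosages[, flip]
  sc2 <- pcadapt_scan(gm2, 3)
  expect_equal(sc1$snps$stat, sc2$snps$stat, tolerance = 1e-8)
})

test_that("Storey q-values: ties, null pi0, and a BH-based oracle bound", {
  expect_equal(length(unique(qvalues(rep(0.2, 30)))), 1)
  set.seed(5)
  p <- runif(10000)
  q <- qvalues(p)
  # pi0 recovered near 1 on uniform input: q ~ BH
  bh <- p.adjust(p, "BH")
  expect_gt(min(q / bh), 0.9)
  expect_lte(max(q / bh), 1 + 1e-12)
  # 20-value toy: q equals pi0-scaled step-up minimum computed directly
  p20 <- c(0.001, 0.004, 0.01, 0.04, seq(0.1, 0.9, length.out = 16))
  q20 <- qvalues(p20)   # m < 100 so pi0 = 1: must equal BH exactly
  expect_equal(q20, p.adjust(p20, "BH"), tolerance = 1e-12)
  expect_error(qvalues(numeric(0)), "empty")
})

test_that("q is monotone nondecreasing in p within a scan", {
  cfg <- small_cfg(seed = 56)
  gm <- suppressWarnings(simulate_genotypes(cfg))$gm
  sc <- pcadapt_scan(gm, 4)
  ok <- !is.na(sc$snps$p)
  o <- order(sc$snps$p[ok])
  expect_true(all(diff(sc$snps$q[ok][o]) >= -1e-12))
})

test_that("gene outlier calls aggregate SNP q-values and report overlap", {
  snps <- data.frame(site_id = paste0("s", 1:3),
                     gene = c("g1", "g2", "g2"),
                     stat = c(5, 1, 1), p = c(1e-4, 0.5, 0.6),
                     q = c(0.04, 0.8, 0.9), axis = 1L)
  sc <- structure(list(snps = snps, lambda = 1, method = "diff", K = 2),
                  class = "scan_result")
  out <- gene_outliers(sc)
  expect_true(out$genes$outlier_diff[out$genes$gene == "g1"])
  expect_false(out$genes$outlier_diff[out$genes$gene == "g2"])
  # overlap of two methods that see the same planted truth
  set.seed(57)
  genes <- rep(paste0("g", 1:200), each = 2)
  truth <- genes %in% paste0("g", 1:20)
  mk <- function(flip) {
    q <- ifelse(truth & runif(400) < 0.8, 0.01, runif(400, 0.1, 1))
    structure(list(snps = data.frame(site_id = paste0("s", 1:400, flip),
                                     gene = genes, stat = -log(q), p = q / 2,
                                     q = q, axis = 1L),
                   lambda = 1, method = flip, K = 2),
              class = "scan_result")
  }
  ou <- gene_outliers(mk("diff"), mk("env"))
  expect_gt(ou$overlap$odds_ratio, 1)
  expect_lt(ou$overlap$p, 0.01)
})

test_that("S-controlled regression matches a normal-equations solve and has
           the forced-sign behavior", {
  min_p <- c(0.9, 0.5, 0.01, 0.7, 0.02, 0.3)
  S <- c(1, 3, 10, 2, 8, 5)
  out <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  got <- s_controlled_regression(min_p, S, out)
  X <- cbind(1, S, as.numeric(out))
  z <- (min_p - mean(min_p)) / sd(min_p)
  beta <- solve(crossprod(X), crossprod(X, z))
  expect_equal(got$beta_S, beta[2], tolerance = 1e-10)
  expect_equal(got$beta_outlier, beta[3], tolerance = 1e-10)
  # response = -S exactly: beta_S < 0, R^2 = 1
  got2 <- s_controlled_regression(-S, S, out)
  expect_lt(got2$beta_S, 0)
  expect_equal(got2$r_squared, 1, tolerance = 1e-10)
  expect_error(s_controlled_regression(rep(0.5, 6), S, out), "variance")
})

test_that("random outlier labels leave the regression coefficient near zero", {
  set.seed(58)
  cover <- vapply(1:20, function(i) {
    S <- rpois(150, 6) + 1
    min_p <- runif(150)
    lab <- sample(c(TRUE, FALSE), 150, replace = TRUE, prob = c(0.1, 0.9))
    r <- s_controlled_regression(min_p, S, lab)
    abs(r$beta_outlier) < 1.96 * r$se_outlier
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})
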