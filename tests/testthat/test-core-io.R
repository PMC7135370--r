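test_that("VCF round trip preserves dosages, positions, genes and polarity", {
  cfg <- small_cfg(seed = 11)
  sim <- suppressWarnings(simulate_genotypes(cfg))
  gm <- sim$gm
  tmp <- tempfile(fileext = ".vcf")
  write_vcf(gm, tmp)
  gm2 <- read_vcf(tmp, sample_meta = gm$sample_meta)
  expect_identical(unname(gm2$dosages), unname(gm$dosages))
  expect_identical(gm2$site_meta$pos, gm$site_meta$pos)
  expect_identical(gm2$site_meta$gene, gm$site_meta$gene)
  expect_identical(gm2$site_meta$ancestral, gm$site_meta$ancestral)
  # depth written as rounded integers
  expect_equal(unname(gm2$depth_matrix), round(unname(gm$depth_matrix)))
})

test_that("simple GT fields are coded as alt-allele dosage, ./. as missing", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "a", "b"), collapse = "\t"),
           paste(c("g1", "5", ".", "A", "T", "50", "PASS", ".", "GT",
                   "0/0", "0/1"), collapse = "\t"),
           paste(c("g1", "9", ".", "C", "G", "50", "PASS", ".", "GT",
                   "./.", "1/1"), collapse = "\t"))
  tmp <- tempfile(fileext = ".vcf")
  writeLines(vcf, tmp)
  gm <- read_vcf(tmp)
  expect_equal(unname(gm$dosages[, 1]), c(0L, 1L))
  expect_true(is.na(gm$dosages[1, 2]))
  expect_equal(unname(gm$dosages[2, 2]), 2L)
  expect_equal(gm$site_meta$ancestral, c("unknown", "unknown"))
})

test_that("filters remove sites by rule and weakest thresholds are identity", {
  # 5 sites: 2 fail MAF at 0.05 (singletons among 20 haplotypes would pass;
  # use monomorphic-ish freqs), rest pass
  dos <- cbind(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),  # maf 0.05 -> keep (>= 0.05)
               rep(0:1, 5),                       # maf 0.25 -> keep
               c(1, rep(0, 9)),                   # maf 0.05 -> keep
               c(rep(0, 10)),                     # maf 0    -> fail
               c(2, rep(0, 9)))                   # maf 0.10 -> keep
  dos[1, 4] <- 0
  gm <- make_gm(dos)
  res <- apply_filters(gm, filter_spec())
  expect_equal(unname(res$removed["maf"]), 1)
  expect_equal(n_sites(res$gm), 4)

  weakest <- filter_spec(site_quality_min = 0, genotype_quality_min = 0,
                         depth_min = 0, max_het_fraction = 1,
                         max_missing_fraction = 1, maf_min = 0)
  res2 <- apply_filters(gm, weakest)
  expect_identical(res2$gm$dosages, gm$dosages)
  expect_true(all(res2$removed == 0))
})

test_that("a site with 90% heterozygotes is removed at the 80% threshold", {
  dos <- cbind(c(rep(1, 9), 0), rep(0:1, 5))
  gm <- make_gm(dos)
  res <- apply_filters(gm, filter_spec(maf_min = 0))
  expect_equal(unname(res$removed["het"]), 1)
  expect_equal(n_sites(res$gm), 1)
})

test_that("filtering is idempotent", {
  cfg <- small_cfg(seed = 3)
  gm <- suppressWarnings(simulate_genotypes(cfg))$gm
  f1 <- apply_filters(gm, filter_spec())
  f2 <- apply_filters(f1$gm, filter_spec())
  expect_identical(f1$gm$dosages, f2$gm$dosages)
  expect_true(all(f2$removed == 0))
})

test_that("maf_min >= 0.5 is rejected", {
  expect_error(filter_spec(maf_min = 0.5), "maf_min")
})

test_that("coverage QC returns near-zero r2 under independence and exact
           values in degenerate cases", {
  cfg <- small_cfg(seed = 5)
  gm <- suppressWarnings(simulate_genotypes(cfg))$gm
  qc <- coverage_genotype_qc(gm)
  expect_lt(qc$r2_additive, 0.01)
  expect_lt(qc$r2_het, 0.01)

  dos <- cbind(c(0, 1, 2, 1), c(2, 0, 1, 0))
  gm2 <- make_gm(dos, depth = 10 * dos)
  qc2 <- coverage_genotype_qc(gm2)
  expect_equal(qc2$r2_additive, 1)

  dos3 <- cbind(c(0, 0, 2, 2), c(2, 2, 0, 0))
  gm3 <- make_gm(dos3, depth = matrix(rlnorm(8, 3), 4))
  expect_equal(coverage_genotype_qc(gm3)$r2_het, 0)
})

test_that("unfolded SFS polarizes, excludes and counts correctly", {
  # one site, 4 haplotypes, derived count 1
  gm <- make_gm(cbind(c(1, 0)))
  s <- unfolded_sfs(gm)
  expect_equal(s$counts, c(1, 0, 0))
  expect_equal(s$n, 4)
  # polarization flip: ancestral = alt converts d to 2 - d
  gm_flip <- make_gm(cbind(c(1, 2)), ancestral = "alt")
  s2 <- unfolded_sfs(gm_flip)   # derived count = 4 - 3 = 1
  expect_equal(s2$counts, c(1, 0, 0))
  # unknown ancestral everywhere errors
  gm_unk <- make_gm(cbind(c(1, 0)), ancestral = "unknown")
  expect_error(unfolded_sfs(gm_unk), "polarized")
})

test_that("neutral equilibrium fixture reproduces the 1/i spectrum shape", {
  cfg <- synth_config(n_genes = 1500, mean_sites = 4, n_clusters = 1,
                      fst_between_clusters = 0, ibd_slope = 0,
                      frac_outlier_genes = 0, n_pops = 4, inds_per_pop = 3,
                      p0_range = c(0.001, 0.999), seed = 8)
  gm <- suppressWarnings(simulate_genotypes(cfg))$gm
  s <- unfolded_sfs(gm, normalized = TRUE)
  n <- s$n
  expected <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  # Monte-Carlo + truncation tolerance on the first few (dominant) classes
  expect_lt(max(abs(s$counts[1:5] - expected[1:5])), 0.05)
  expect_gt(cor(s$counts, expected), 0.98)
})

test_that("per-gene index has exact site counts and drops empty genes", {
  dos <- matrix(0:1, 4, 5)
  gm <- make_gm(dos, gene = c("g1", "g1", "g1", "g2", "g2"))
  idx <- per_gene_index(gm)
  expect_equal(idx$g1$S, 3)
  expect_equal(idx$g2$S, 2)
  expect_false("g3" %in% names(idx))
  # generator truth: per-gene counts round trip
  cfg <- small_cfg(seed = 2)
  gm2 <- suppressWarnings(simulate_genotypes(cfg))$gm
  idx2 <- per_gene_index(gm2)
  expect_equal(sum(vapply(idx2, `[[`, 1, "S")), n_sites(gm2))
  expect_equal(unname(vapply(idx2, `[[`, 1, "S")),
               unname(as.vector(table(gm2$site_meta$gene)[names(idx2)])))
})

test_that("SFS total equals the number of polarized polymorphic sites", {
  cfg <- small_cfg(seed = 4)
  gm <- suppressWarnings(simulate_genotypes(cfg))$gm
  s <- unfolded_sfs(gm)
  n_poly <- sum(colSums(gm$dosages) > 0 &
                  colSums(gm$dosages) < 2 * n_individuals(gm))
  expect_equal(sum(s$counts), n_poly)
})
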