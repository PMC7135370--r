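#' Run the full synthetic analysis pipeline
#'
#' Generates a seeded synthetic dataset (clinal outlier genes, planted
#' sweeps, modular expression with trans-eQTLs), applies the variant
#' filters, and runs every analysis stage: diversity/neutrality statistics
#' with FST and dXY between the transect ends, the CLR sweep scan on one
#' population subset, the PCA-differentiation and environmental-association
#' scans with gene-level outlier calls, trans-eQTL mapping with admixture
#' covariates, the signed co-expression network, and the integration
#' statistics (enrichments, standardized regressions, permutation fit
#' tests).
#'
#' @param cfg a [synth_config()]; its `seed` is overridden by `seed`.
#' @param seed integer master seed.
#' @param n_perm permutations for the fit tests.
#' @param clr_pops how many populations from the southern end form the CLR
#'   subset (keeps the spectrum transform tractable).
#' @return A named list with every stage's output (see the vignette for a
#'   walk-through).
#' @export
run_pipeline <- function(cfg = synth_config(n_genes = 1500, mean_sites = 10,
                                            n_modules = 4),
                         seed = 1, n_perm = 1000, clr_pops = 4) {
  cfg$seed <- seed
  sim <- simulate_genotypes(cfg)
  # sweeps are local events: plant them in the southern range-edge subset,
  # where the sweep scan is also run
  lat_pop <- tapply(sim$gm$sample_meta$lat, sim$gm$sample_meta$population,
                    mean)
  sweep_set <- names(sort(lat_pop))[seq_len(min(clr_pops, length(lat_pop)))]
  gm <- plant_sweep_sfs(sim$gm, sim$truth$outlier_genes, cfg$sweep_alpha,
                        exclude_sites = sim$truth$clinal_sites,
                        populations = sweep_set)
  truth <- sim$truth
  truth$sweep_genes <- truth$outlier_genes
  truth$sweep_populations <- sweep_set
  # the MAF filter applies to the scan and eQTL analyses only; diversity,
  # SFS and CLR statistics use the full filtered site set
  filt_stats <- apply_filters(gm, filter_spec(maf_min = 0))
  filt <- apply_filters(gm, filter_spec())
  gms <- filt_stats$gm
  gmf <- filt$gm
  expr <- simulate_expression(cfg, gmf, truth)
  em <- expr$em
  truth <- expr$truth

  lat_by_pop <- tapply(gmf$sample_meta$lat, gmf$sample_meta$population, mean)
  south <- names(sort(lat_by_pop))[1]
  north <- names(sort(lat_by_pop, decreasing = TRUE))[1]
  # diversity/neutrality statistics and the CLR scan are computed on the
  # swept range-edge subset (mirroring the per-edge analysis design);
  # FST/dXY contrast the transect ends on the full data
  stats_div <- gene_stats(subset_genotypes(gms, sweep_set))
  stats_fst <- gene_stats(gms, pop_pair = c(south, north))
  stats_tab <- merge(stats_div,
                     stats_fst[, c("gene", "fst", "dxy")], by = "gene",
                     all = TRUE)
  clr_tab <- clr_scan(gms, individuals = sweep_set)

  scan_diff <- pcadapt_scan(gmf, K = 4)
  scan_env <- env_association_scan(gmf, truth$env_pc_values, K_latent = 4)
  outl <- gene_outliers(scan_diff, scan_env)
  genes <- merge(outl$genes, stats_tab, by = "gene", all = TRUE)
  genes <- merge(genes, clr_tab[, c("gene", "clr")], by = "gene", all.x = TRUE)

  screg <- list(
    diff = tryCatch(s_controlled_regression(genes$min_p_diff, genes$S,
                                            genes$outlier_diff),
                    error = function(e) NULL),
    env = tryCatch(s_controlled_regression(genes$min_p_env, genes$S,
                                           genes$outlier_env),
                   error = function(e) NULL))

  emc <- correct_expression(em, n_pcs = 2)
  qcols <- grep("^q[0-9]+$", names(gmf$sample_meta), value = TRUE)
  covs <- as.matrix(gmf$sample_meta[, qcols, drop = FALSE])
  eqtl <- map_eqtl(gmf, emc, covariates = covs)

  adj <- signed_adjacency(emc, power = 6)
  k <- connectivity(adj)
  tom <- tom_matrix(adj)
  modules <- detect_modules(tom, min_size = 30)

  genes <- merge(genes, eqtl$genes, by = "gene", all = TRUE)
  genes$connectivity <- k[genes$gene]
  genes$module <- modules[genes$gene]
  genes$expr_level <- rowMeans(em)[genes$gene]
  genes$expr_variance <- apply(em, 1, stats::var)[genes$gene]
  genes$outlier_any <- genes$outlier_diff | genes$outlier_env
  genes$truth_outlier <- genes$gene %in% truth$outlier_genes

  has_flags <- !is.na(genes$is_eqtl) & !is.na(genes$outlier_any)
  gsub_ <- genes[has_flags, ]
  integ <- list(
    eqtl_enrichment = fisher_enrichment(gsub_$outlier_any, gsub_$is_eqtl),
    egene_enrichment = fisher_enrichment(gsub_$outlier_any, gsub_$is_egene),
    eqtl_enrichment_truth = fisher_enrichment(gsub_$truth_outlier,
                                              gsub_$is_eqtl),
    egene_enrichment_truth = fisher_enrichment(gsub_$truth_outlier,
                                               gsub_$is_egene),
    eqtl_pct_outlier = bootstrap_percent_ci(
      gsub_$is_eqtl[gsub_$outlier_any], seed = seed),
    eqtl_pct_background = bootstrap_percent_ci(
      gsub_$is_eqtl[!gsub_$outlier_any], seed = seed),
    eqtl_logistic = eqtl_outlier_logistic(gsub_$is_eqtl, gsub_$S,
                                          gsub_$outlier_any),
    connectivity_model = connectivity_outlier_model(
      gsub_$connectivity, gsub_$expr_level, gsub_$expr_variance,
      gsub_$outlier_any),
    diversity_model_background = diversity_connectivity_model(
      gsub_$theta_pi, gsub_$connectivity, gsub_$expr_level,
      gsub_$expr_variance, subset = !gsub_$outlier_any),
    diversity_model_outliers = tryCatch(diversity_connectivity_model(
      gsub_$theta_pi, gsub_$connectivity, gsub_$expr_level,
      gsub_$expr_variance, subset = gsub_$outlier_any),
      error = function(e) NULL))
  ok_h <- !is.na(genes$fay_wu_h) & !is.na(genes$outlier_any)
  if (sum(genes$outlier_any[ok_h], na.rm = TRUE) >= 2)
    integ$perm_h <- permutation_fit_test(genes$fay_wu_h[ok_h],
                                         genes$S[ok_h],
                                         genes$outlier_any[ok_h],
                                         n_perm = n_perm, seed = seed)
  ok_c <- !is.na(genes$clr) & !is.na(genes$outlier_any)
  if (sum(genes$outlier_any[ok_c], na.rm = TRUE) >= 2)
    integ$perm_clr <- permutation_fit_test(genes$clr[ok_c], genes$S[ok_c],
                                           genes$outlier_any[ok_c],
                                           n_perm = n_perm, seed = seed)
  mod_enr <- tryCatch(
    module_enrichment(modules[genes$gene[has_flags]],
                      genes$outlier_any[has_flags]),
    error = function(e) NULL)

  list(cfg = cfg, truth = truth, filter = filt["removed"],
       genes = genes, scan_diff = scan_diff, scan_env = scan_env,
       overlap = outl$overlap, s_regression = screg, eqtl = eqtl,
       connectivity = k, modules = modules, module_enrichment = mod_enr,
       integration = integ, gm = gmf, expression = em)
}
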