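#' Configuration for the synthetic genotype/expression generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' two ancestral clusters joined by an admixture / isolation-by-distance
#' gradient along latitude, genes with variable numbers of segregating
#' sites, a minority of adaptive genes carrying clinal allele-frequency
#' shifts (and, via [plant_sweep_sfs()], sweep-distorted spectra),
#' trans-eQTL effects concentrated in the adaptive genes and directed at
#' non-adaptive targets, and modular expression covariance with hub genes
#' plus a north-south expression gradient.
#'
#' @param n_pops number of populations along the latitude transect.
#' @param inds_per_pop diploid individuals per population.
#' @param n_genes number of genes (transcript contigs).
#' @param mean_sites mean of the geometric distribution of SNPs per gene.
#' @param n_clusters ancestral clusters (contiguous latitude blocks).
#' @param fst_between_clusters Balding-Nichols drift between global and
#'   cluster allele frequencies.
#' @param ibd_slope additional per-degree-latitude Balding-Nichols drift of
#'   population frequencies around their cluster frequency.
#' @param frac_outlier_genes fraction of genes planted with clinal shifts.
#' @param clinal_shift allele-frequency displacement at each transect end
#'   for planted sites (linear in latitude, gene-specific sign; the full
#'   south-to-north spread is `2 * clinal_shift`).  At planted sites the
#'   cline replaces neutral cluster drift: selection, not shared ancestry,
#'   drives their differentiation.
#' @param sweep_alpha default intensity for [plant_sweep_sfs()].
#' @param frac_eqtl_outliers probability an adaptive gene is a trans-eQTL
#'   source.
#' @param frac_eqtl_background same for non-adaptive genes.
#' @param eqtl_effect absolute trans-eQTL effect per dosage unit.
#' @param eqtl_targets_outlier,eqtl_targets_background Poisson mean of extra
#'   eGene targets per source (every source has at least one target).
#' @param n_modules co-expression modules.
#' @param hub_fraction fraction of each module's genes that are hubs.
#' @param noise_sd independent expression noise standard deviation.
#' @param lat_range latitude span of the transect (degrees).
#' @param p0_range truncation of the neutral 1/p ancestral-frequency law.
#' @param seed integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_pops = 15, inds_per_pop = 5, n_genes = 2000,
                         mean_sites = 30, n_clusters = 2,
                         fst_between_clusters = 0.05, ibd_slope = 0.002,
                         frac_outlier_genes = 0.05, clinal_shift = 0.3,
                         sweep_alpha = 3,
                         frac_eqtl_outliers = 0.40,
                         frac_eqtl_background = 0.10,
                         eqtl_effect = 1.5,
                         eqtl_targets_outlier = 1.0,
                         eqtl_targets_background = 0.6,
                         n_modules = 8, hub_fraction = 0.1, noise_sd = 0.5,
                         lat_range = c(30, 45), p0_range = c(0.02, 0.98),
                         seed = 1) {
  stopifnot(n_pops >= 2, inds_per_pop >= 1, n_genes >= 2, mean_sites >= 1,
            n_clusters >= 1, fst_between_clusters >= 0,
            fst_between_clusters < 1,
            frac_outlier_genes >= 0, frac_outlier_genes <= 1,
            frac_eqtl_outliers >= 0, frac_eqtl_outliers <= 1,
            frac_eqtl_background >= 0, frac_eqtl_background <= 1,
            n_modules >= 1, hub_fraction >= 0, hub_fraction <= 1,
            noise_sd >= 0, length(lat_range) == 2, length(p0_range) == 2,
            p0_range[1] > 0, p0_range[2] < 1)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# draw from the truncated neutral derived-frequency density f(p) ~ 1/p
rneutral_freq <- function(k, lo, hi) lo * (hi / lo)^stats::runif(k)

# sample() without the scalar-x surprise
pick <- function(x, k, prob = NULL) x[sample.int(length(x), k, prob = prob)]

# Balding-Nichols draw: Beta with mean p and "drift" parameter F
rbn <- function(p, f) {
  if (f <= 0) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  stats::rbeta(length(p), pmax(a, 1e-8), pmax(b, 1e-8))
}

#' Simulate genotypes with planted clinal outliers
#'
#' Neutral sites follow a hierarchical Balding-Nichols scheme (global 1/p
#' frequency -> cluster frequency with `fst_between_clusters` drift ->
#' population frequency with isolation-by-distance drift proportional to
#' latitude distance from the cluster centre).  Sites in planted outlier
#' genes additionally receive a monotone frequency cline of total magnitude
#' `clinal_shift` along latitude (gene-specific sign); frequencies are
#' clipped to [0, 1] and clips counted.  Diploid genotypes are binomial
#' draws; the ancestral allele is the reference allele; per-cell read depth
#' is log-normal and independent of genotype, so the coverage QC has a true
#' null.
#'
#' @param cfg a [synth_config()].
#' @return List: `gm`, a [genotype_matrix()]; `truth`, a truth-set list
#'   (`outlier_genes`, `sweep_genes`, `hub_genes`, `module_assignment`,
#'   `eqtl_pairs`, `env_pc_values`, `clipped_sites`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n_pops <- cfg$n_pops
  n_ind <- n_pops * cfg$inds_per_pop
  lats <- seq(cfg$lat_range[1], cfg$lat_range[2], length.out = n_pops)
  lons <- seq(-95, -90, length.out = n_pops)
  cluster <- if (cfg$n_clusters == 1) rep(1L, n_pops) else
    as.integer(cut(lats, breaks = cfg$n_clusters, labels = FALSE))
  # population-level admixture: logistic gradient between the two extreme
  # clusters, mild noise; K_adm = n_clusters
  mid <- mean(range(lats)); scl <- diff(range(lats)) / 8
  q1 <- stats::plogis((lats - mid) / scl)
  q_pop <- matrix(0, n_pops, cfg$n_clusters)
  if (cfg$n_clusters == 1) q_pop[, 1] <- 1 else {
    q_pop[, cfg$n_clusters] <- q1
    q_pop[, 1] <- 1 - q1
    if (cfg$n_clusters > 2) {
      # distribute a small share to middle clusters by latitude proximity
      for (cc in 2:(cfg$n_clusters - 1)) {
        w <- exp(-abs(lats - stats::quantile(lats, (cc - 1) /
                                               (cfg$n_clusters - 1))))
        q_pop[, cc] <- 0.2 * w / max(w)
      }
      q_pop <- q_pop / rowSums(q_pop)
    }
  }
  pop_of <- rep(seq_len(n_pops), each = cfg$inds_per_pop)
  sample_meta <- data.frame(
    sample = sprintf("ind%03d", seq_len(n_ind)),
    population = sprintf("P%02d", pop_of),
    lat = lats[pop_of], lon = lons[pop_of])
  # reported admixture proportions at K = 4, the covariate set the eQTL
  # models consume: the two cluster gradients plus two latitude-local
  # components, mimicking the finer subdivision an admixture analysis
  # returns at larger K
  qa <- cbind(1 - q1, q1,
              0.5 * exp(-((lats - stats::quantile(lats, 0.25)) / 3)^2),
              0.5 * exp(-((lats - stats::quantile(lats, 0.75)) / 3)^2))
  qa <- qa / rowSums(qa)
  for (cc in seq_len(ncol(qa)))
    sample_meta[[paste0("q", cc)]] <- qa[pop_of, cc]

  sites_per_gene <- pmax(1L, stats::rgeom(cfg$n_genes,
                                          1 / cfg$mean_sites))
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  gene_of_site <- rep(genes, sites_per_gene)
  m <- length(gene_of_site)
  pos <- unlist(lapply(sites_per_gene, function(k)
    sort(sample.int(20000L, k))), use.names = FALSE)

  n_out <- round(cfg$frac_outlier_genes * cfg$n_genes)
  outlier_genes <- sort(sample(genes, n_out))
  out_sign <- stats::setNames(sample(c(-1, 1), n_out, TRUE), outlier_genes)
  # within each adaptive gene, ~20% of sites (at least one) carry the cline
  # (the selected variants); the rest are linked neutral sites that
  # [plant_sweep_sfs()] later distorts with the hitchhiking footprint
  is_out_site <- rep(FALSE, m)
  for (g in outlier_genes) {
    js <- which(gene_of_site == g)
    is_out_site[pick(js, max(1, round(0.2 * length(js))))] <- TRUE
  }

  # module / hub / loading structure is decided here so genetic diversity
  # can be coupled to connectivity (purifying selection on connected genes)
  module <- stats::setNames(rep_len(seq_len(cfg$n_modules), cfg$n_genes)[
    sample.int(cfg$n_genes)], genes)
  hubs <- unlist(lapply(seq_len(cfg$n_modules), function(mm) {
    gg <- names(module)[module == mm]
    pick(gg, max(1, round(cfg$hub_fraction * length(gg))))
  }))
  loading <- stats::setNames(stats::runif(cfg$n_genes, 0.25, 0.7), genes)
  loading[hubs] <- stats::runif(length(hubs), 0.88, 0.95)
  # adaptive genes sit in central network positions (the planted analogue
  # of the pattern the analysis is designed to detect), below the hubs
  loading[setdiff(outlier_genes, hubs)] <-
    pmax(loading[setdiff(outlier_genes, hubs)],
         stats::runif(length(setdiff(outlier_genes, hubs)), 0.65, 0.85))

  p0 <- rneutral_freq(m, cfg$p0_range[1], cfg$p0_range[2])
  # stronger purifying selection on more connected genes: push ancestral
  # frequencies toward rarity in proportion to the gene's loading, which
  # lowers per-site diversity without changing S
  gamma_site <- 1 + 1.5 * (loading[gene_of_site] - 0.25)
  p0 <- p0^gamma_site
  # planted clinal sites start from intermediate ancestral frequencies:
  # spatially varying selection acts on common standing variation, and an
  # intermediate start keeps the full cline inside [0, 1]
  p0[is_out_site] <- stats::runif(sum(is_out_site), 0.35, 0.65)
  lat_center <- tapply(lats, cluster, mean)
  # population frequencies: m x n_pops
  p_pop <- matrix(0, m, n_pops)
  p_clu <- matrix(0, m, cfg$n_clusters)
  for (cc in seq_len(cfg$n_clusters))
    p_clu[, cc] <- rbn(p0, cfg$fst_between_clusters)
  # classical sigmoid cline profile in latitude: ~ -1 at the southern end,
  # ~ +1 at the northern end, width 1/10 of the transect
  cline_profile <- 2 * stats::plogis((lats - mid) /
                                       (diff(range(lats)) / 10)) - 1
  clipped <- 0L
  for (j in seq_len(n_pops)) {
    f_ibd <- cfg$ibd_slope * abs(lats[j] - lat_center[cluster[j]])
    base <- rowSums(p_clu * matrix(q_pop[j, ], m, cfg$n_clusters,
                                   byrow = TRUE))
    pj <- rbn(base, f_ibd)
    if (any(is_out_site) && cfg$clinal_shift != 0) {
      # selection-driven loci: the cline (+/- clinal_shift at the transect
      # ends) replaces neutral cluster drift, on top of IBD-scale noise
      shift <- cfg$clinal_shift * cline_profile[j] *
        out_sign[gene_of_site[is_out_site]]
      raw <- rbn(p0[is_out_site], f_ibd) + shift
      clipped <- clipped + sum(raw < 0 | raw > 1)
      pj[is_out_site] <- pmin(1, pmax(0, raw))
    }
    p_pop[, j] <- pj
  }
  if (clipped > 0)
    warning(clipped, " site-population frequencies clipped to [0, 1]")

  dos <- matrix(stats::rbinom(n_ind * m, 2, t(p_pop[, pop_of])),
                nrow = n_ind, ncol = m, byrow = FALSE)
  # depth independent of genotype (true null for the coverage QC)
  dp <- matrix(stats::rlnorm(n_ind * m, log(20), 0.4), n_ind, m)
  site_meta <- data.frame(
    site_id = paste0(gene_of_site, ":", pos),
    gene = gene_of_site, pos = pos,
    ref = "A", alt = "T", ancestral = "ref",
    qual = round(stats::runif(m, 40, 100), 1),
    depth = colMeans(dp))
  rownames(dos) <- sample_meta$sample
  gm <- genotype_matrix(dos, site_meta, sample_meta, depth_matrix = dp)
  env <- cbind(pc1 = as.numeric(scale(lats)),
               pc2 = stats::rnorm(n_pops), pc3 = stats::rnorm(n_pops),
               pc4 = stats::rnorm(n_pops))
  rownames(env) <- sprintf("P%02d", seq_len(n_pops))
  truth <- list(outlier_genes = outlier_genes,
                sweep_genes = character(0),
                clinal_sites = site_meta$site_id[is_out_site],
                hub_genes = sort(hubs),
                module_assignment = module,
                loadings = loading,
                eqtl_pairs = NULL,
                env_pc_values = env,
                clipped_sites = clipped)
  list(gm = gm, truth = truth)
}

#' Plant sweep-distorted spectra in selected genes
#'
#' Within the listed genes, each polarized fully-genotyped polymorphic
#' site's derived-allele count is, with probability `1 - exp(-alpha)`,
#' redrawn from a boundary-weighted kernel `s_i ~ 1/(i (n - i))` (excess
#' rare and high-frequency-derived variants, the post-sweep footprint), and
#' the derived alleles are reassigned to random haplotypes.  `alpha = 0` is
#' the identity.
#'
#' @param gm a [genotype_matrix()].
#' @param genes character vector of gene ids (must exist).
#' @param alpha distortion intensity (>= 0).
#' @param exclude_sites site ids spared from distortion (typically the
#'   clinal sites themselves, so the selected variants keep their
#'   geographic signal while the linked sites show the hitchhiking
#'   footprint).
#' @param populations optional population ids: the sweep footprint is
#'   planted within these individuals only (selective sweeps in this design
#'   are local events at a range edge), leaving the remaining populations'
#'   genotypes untouched.
#' @return A modified [genotype_matrix()].
#' @export
plant_sweep_sfs <- function(gm, genes, alpha, exclude_sites = NULL,
                            populations = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (alpha < 0) stop("alpha must be >= 0")
  if (!all(genes %in% gm$site_meta$gene)) stop("unknown gene id(s)")
  if (alpha == 0) return(gm)
  ii <- if (is.null(populations)) seq_len(n_individuals(gm)) else
    which(gm$sample_meta$population %in% populations)
  if (!length(ii)) stop("no individuals in the selected populations")
  mix <- 1 - exp(-alpha)
  n <- 2L * length(ii)
  kernel <- 1 / (seq_len(n - 1) * (n - seq_len(n - 1)))^2
  kernel <- kernel / sum(kernel)
  dos <- gm$dosages
  target <- which(gm$site_meta$gene %in% genes &
                    gm$site_meta$ancestral != "unknown" &
                    !(gm$site_meta$site_id %in% exclude_sites))
  for (j in target) {
    d <- dos[ii, j]
    if (any(is.na(d))) next
    cnt <- sum(d)
    if (gm$site_meta$ancestral[j] == "alt") cnt <- n - cnt
    if (cnt < 1 || cnt > n - 1) next
    if (stats::runif(1) >= mix) next
    new_cnt <- sample.int(n - 1, 1, prob = kernel)
    # reassign derived alleles with weights favoring the original carriers,
    # so planted clines survive the spectrum distortion
    der0 <- if (gm$site_meta$ancestral[j] == "alt") 2L - d else d
    wts <- rep(der0 + 0.5, each = 2)
    hap <- integer(n)
    hap[sample.int(n, new_cnt, prob = wts)] <- 1L
    der_dos <- hap[seq(1, n, 2)] + hap[seq(2, n, 2)]
    dos[ii, j] <- if (gm$site_meta$ancestral[j] == "alt") 2L - der_dos else
      der_dos
  }
  gm$dosages <- dos
  gm
}

#' Simulate modular expression with planted trans-eQTLs
#'
#' Each module has a latent factor per individual; hub genes load at 0.9,
#' other genes at Uniform(0.3, 0.6).  A north-south latent factor (scaled
#' latitude plus noise) loads on every gene, emulating the expression
#' population structure removed by PC correction.  Trans-eQTL source genes
#' (adaptive genes with probability `frac_eqtl_outliers`, others with
#' `frac_eqtl_background`) act through their highest-MAF SNP on 1 + Poisson
#' targets drawn from non-adaptive genes, with effect `eqtl_effect` per
#' centered dosage unit and random sign.  Independent Gaussian noise
#' (`noise_sd`) is added.
#'
#' @param cfg a [synth_config()].
#' @param gm the [genotype_matrix()] from [simulate_genotypes()].
#' @param truth its truth set.
#' @return List: `em` (genes x individuals matrix), updated `truth` with
#'   `hub_genes`, `module_assignment`, `loadings`, `eqtl_pairs`.
#' @export
simulate_expression <- function(cfg, gm, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  n_ind <- n_individuals(gm)
  module <- truth$module_assignment
  hubs <- truth$hub_genes
  loading <- truth$loadings
  fac <- matrix(stats::rnorm(cfg$n_modules * n_ind), cfg$n_modules, n_ind)
  # two population-structure axes, mirroring the two leading expression PCs
  # the analysis removes: a north-south gradient (same-sign loadings) and a
  # population-level ancestry factor (gene-specific sign); gene-varying
  # loadings keep the two axes genuinely rank-two
  ns <- as.numeric(scale(gm$sample_meta$lat)) + stats::rnorm(n_ind, 0, 0.3)
  pop_fac <- stats::rnorm(length(unique(gm$sample_meta$population)))
  names(pop_fac) <- unique(gm$sample_meta$population)
  ps <- pop_fac[gm$sample_meta$population] + stats::rnorm(n_ind, 0, 0.3)
  l_ns <- stats::runif(cfg$n_genes, 0.4, 0.8)
  l_ps <- stats::runif(cfg$n_genes, -0.7, 0.7)
  em <- matrix(0, cfg$n_genes, n_ind, dimnames = list(genes,
                                                      gm$sample_meta$sample))
  for (g in seq_len(cfg$n_genes))
    em[g, ] <- loading[g] * fac[module[g], ] + l_ns[g] * ns + l_ps[g] * ps

  # trans-eQTL planting
  gene_sites <- per_gene_index(gm)
  has_snp <- names(gene_sites)
  is_out <- genes %in% truth$outlier_genes
  p_src <- ifelse(is_out, cfg$frac_eqtl_outliers, cfg$frac_eqtl_background)
  src <- genes[stats::runif(cfg$n_genes) < p_src & genes %in% has_snp]
  pairs <- NULL
  # trans targets are peripheral downstream genes: non-adaptive, non-hub
  non_adaptive <- setdiff(genes, union(truth$outlier_genes,
                                       truth$hub_genes))
  for (g in src) {
    sites <- gene_sites[[g]]$sites
    d <- gm$dosages[, sites, drop = FALSE]
    p <- colMeans(d, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    if (all(is.na(maf)) || max(maf, na.rm = TRUE) == 0) next
    snp <- sites[which.max(maf)]
    lam <- if (g %in% truth$outlier_genes) cfg$eqtl_targets_outlier else
      cfg$eqtl_targets_background
    k <- 1L + stats::rpois(1, lam)
    targets <- pick(setdiff(non_adaptive, g), min(k, length(setdiff(non_adaptive, g))))
    dose <- gm$dosages[, snp]
    dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
    dose <- dose - mean(dose)
    for (tg in targets) {
      eff <- cfg$eqtl_effect * sample(c(-1, 1), 1)
      em[tg, ] <- em[tg, ] + eff * dose
      pairs <- rbind(pairs, data.frame(source = g, target = tg,
                                       snp = gm$site_meta$site_id[snp],
                                       effect = eff))
    }
  }
  em <- em + matrix(stats::rnorm(length(em), 0, cfg$noise_sd), nrow(em))
  truth$eqtl_pairs <- pairs
  list(em = em, truth = truth)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits plain-text `genotypes.vcf`, `expression.tsv` (genes x samples),
#' `samples.tsv` and `truth.json`, all re-readable with [read_vcf()],
#' [read_expression()], [read_sample_meta()] and [read_truth()].
#'
#' @param dir output directory (created if needed).
#' @param gm a [genotype_matrix()].
#' @param em expression matrix (genes x individuals).
#' @param truth truth-set list.
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(dir, gm, em, truth) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             expr = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(gm, paths["vcf"])
  utils::write.table(data.frame(gene = rownames(em), em,
                                check.names = FALSE),
                     paths["expr"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gm$sample_meta, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- truth
  tr$module_assignment <- as.list(tr$module_assignment)
  tr$loadings <- as.list(tr$loadings)
  tr$env_pc_values <- apply(tr$env_pc_values, 1, as.list, simplify = FALSE)
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Read fixture companions written by [write_fixture()]
#'
#' @param path file path.
#' @return `read_expression`: genes x samples numeric matrix;
#'   `read_sample_meta`: data.frame; `read_truth`: truth-set list.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' @rdname read_expression
#' @export
read_sample_meta <- function(path) utils::read.delim(path)

#' @rdname read_expression
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(tr$module_assignment))
    tr$module_assignment <- unlist(tr$module_assignment)
  if (!is.null(tr$loadings)) tr$loadings <- unlist(tr$loadings)
  if (!is.null(tr$env_pc_values))
    tr$env_pc_values <- do.call(rbind, lapply(tr$env_pc_values, unlist))
  tr
}
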