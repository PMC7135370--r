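# Small in-code fixture builders shared across the suite.

# genotype_matrix from a dosage matrix; one gene unless `gene` given
make_gm <- function(dosages, gene = "g1", pos = NULL, ancestral = "ref",
                    qual = 99, population = NULL, lat = NULL,
                    depth = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  n <- nrow(dosages)
  site_meta <- data.frame(
    site_id = paste0(rep_len(gene, m), ":", seq_len(m)),
    gene = rep_len(gene, m),
    pos = if (is.null(pos)) seq_len(m) * 10L else pos,
    ref = "A", alt = "T",
    ancestral = rep_len(ancestral, m),
    qual = rep_len(qual, m),
    depth = if (is.null(depth)) 20 else colMeans(as.matrix(depth)))
  sample_meta <- data.frame(
    sample = sprintf("s%02d", seq_len(n)),
    population = if (is.null(population)) "P1" else rep_len(population, n),
    lat = if (is.null(lat)) 40 else rep_len(lat, n),
    lon = -93)
  genotype_matrix(dosages, site_meta, sample_meta,
                  depth_matrix = if (is.null(depth)) NULL else depth)
}

# dosage matrix with given per-site derived counts over 2n haplotypes,
# randomly assigned to individuals
dosages_from_counts <- function(counts, n_ind, seed = 1) {
  set.seed(seed)
  vapply(counts, function(k) {
    hap <- integer(2 * n_ind)
    hap[sample.int(2 * n_ind, k)] <- 1L
    hap[seq(1, 2 * n_ind, 2)] + hap[seq(2, 2 * n_ind, 2)]
  }, integer(n_ind))
}

# rank-based AUC of `stat` for recovering `truth` (logical)
rank_auc <- function(stat, truth) {
  ok <- !is.na(stat)
  r <- rank(stat[ok]); tr <- truth[ok]
  (mean(r[tr]) - (sum(tr) + 1) / 2) / sum(!tr)
}

small_cfg <- function(seed = 1, ...) {
  synth_config(n_genes = 200, mean_sites = 6, n_modules = 4, seed = seed, ...)
}
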