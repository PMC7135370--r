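#' Genotype matrix container
#'
#' Holds biallelic-SNP dosages (individuals x sites, alt-allele counts 0/1/2,
#' `NA` for missing) together with per-site and per-sample metadata.  Sites
#' map to genes through the `gene` column of `site_meta` (one contig = one
#' gene); the ancestral allele is recorded as `"ref"`, `"alt"` or
#' `"unknown"` so the site frequency spectrum can be polarized.
#'
#' @param dosages integer matrix, individuals x sites; values 0/1/2 or `NA`.
#' @param site_meta data.frame with columns `site_id`, `gene`, `pos` (1-based
#'   bp), `ref`, `alt`, `ancestral` (`"ref"|"alt"|"unknown"`), `qual`
#'   (site quality, phred) and `depth` (mean read depth).
#' @param sample_meta data.frame with columns `sample`, `population`, `lat`,
#'   `lon` and admixture proportions `q1..qK` (rows summing to 1).
#' @param depth_matrix optional per-cell read-depth matrix (same shape as
#'   `dosages`); used by [coverage_genotype_qc()] and depth filtering.
#' @param gq_matrix optional per-cell genotype-quality matrix.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, site_meta, sample_meta,
                            depth_matrix = NULL, gq_matrix = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  stopifnot(ncol(dosages) == nrow(site_meta),
            nrow(dosages) == nrow(sample_meta))
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  req <- c("site_id", "gene", "pos", "ref", "alt", "ancestral")
  missing_cols <- setdiff(req, names(site_meta))
  if (length(missing_cols))
    stop("site_meta lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(site_meta$ancestral %in% c("ref", "alt", "unknown")))
    stop("ancestral must be 'ref', 'alt' or 'unknown'")
  qcols <- grep("^q[0-9]+$", names(sample_meta), value = TRUE)
  if (length(qcols)) {
    qs <- rowSums(as.matrix(sample_meta[, qcols, drop = FALSE]))
    if (any(abs(qs - 1) > 1e-9))
      stop("admixture proportions must sum to 1 per individual")
  }
  if (!is.null(depth_matrix))
    stopifnot(all(dim(depth_matrix) == dim(dosages)))
  if (!is.null(gq_matrix))
    stopifnot(all(dim(gq_matrix) == dim(dosages)))
  structure(list(dosages = dosages,
                 site_meta = as.data.frame(site_meta),
                 sample_meta = as.data.frame(sample_meta),
                 depth_matrix = depth_matrix,
                 gq_matrix = gq_matrix),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d sites, %d genes\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$site_meta$gene))))
  invisible(x)
}

#' Number of individuals / sites in a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return Integer count.
#' @export
n_individuals <- function(gm) nrow(gm$dosages)

#' @rdname n_individuals
#' @export
n_sites <- function(gm) ncol(gm$dosages)

#' Variant filter thresholds
#'
#' Mirrors a transcriptome SNP-filtering recipe: biallelic SNPs with site
#' quality >= 30, genotype quality >= 20, read coverage >= 6, < 80%
#' heterozygosity across individuals, missing data in < 20% of individuals,
#' and minor allele frequency >= 0.05.
#'
#' @param site_quality_min minimum site QUAL (phred).
#' @param genotype_quality_min minimum per-genotype GQ; genotypes below are
#'   set to missing (as in VCFtools).
#' @param depth_min minimum per-genotype read depth; genotypes below are set
#'   to missing.
#' @param max_het_fraction maximum fraction of non-missing genotypes that are
#'   heterozygous.
#' @param max_missing_fraction maximum fraction of missing genotypes.
#' @param maf_min minimum minor allele frequency (computed on non-missing
#'   genotypes); must be < 0.5.
#' @param biallelic_snps_only logical; kept for interface completeness (the
#'   container only holds biallelic SNPs).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(site_quality_min = 30, genotype_quality_min = 20,
                        depth_min = 6, max_het_fraction = 0.80,
                        max_missing_fraction = 0.20, maf_min = 0.05,
                        biallelic_snps_only = TRUE) {
  stopifnot(max_het_fraction >= 0, max_het_fraction <= 1,
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            maf_min >= 0)
  if (maf_min >= 0.5) stop("maf_min must be < 0.5")
  structure(list(site_quality_min = site_quality_min,
                 genotype_quality_min = genotype_quality_min,
                 depth_min = depth_min,
                 max_het_fraction = max_het_fraction,
                 max_missing_fraction = max_missing_fraction,
                 maf_min = maf_min,
                 biallelic_snps_only = biallelic_snps_only),
            class = "filter_spec")
}

#' Read a VCF into a genotype matrix
#'
#' Reads a VCF 4.2 file (GT required; DP, GQ, QUAL and the INFO `AA=`
#' ancestral-allele tag used when present) and codes genotypes as alt-allele
#' dosages.  Contig names identify genes (one contig per gene) unless
#' `gene_map` supplies a contig -> gene translation.
#'
#' @param path VCF file path.
#' @param gene_map optional named character vector mapping contig to gene id.
#' @param sample_meta optional sample metadata data.frame (see
#'   [genotype_matrix()]); a minimal one is built from sample names otherwise.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, gene_map = NULL, sample_meta = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) stop("VCF contains no GT genotypes")
  # dosage coding; reject non-diploid calls
  gt_chr <- gsub("\\|", "/", gt)
  known <- c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  badgt <- !(gt_chr %in% known | is.na(gt_chr))
  if (any(badgt))
    stop("non-diploid or unsupported GT value(s): ",
         paste(unique(gt_chr[badgt])[1:min(3, sum(badgt))], collapse = ", "))
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt_chr == "0/0"] <- 0L
  dos[gt_chr %in% c("0/1", "1/0")] <- 1L
  dos[gt_chr == "1/1"] <- 2L
  dos <- t(dos)  # individuals x sites
  dp <- tryCatch(t(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
                 error = function(e) NULL)
  gq <- tryCatch(t(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)),
                 error = function(e) NULL)
  if (!is.null(dp) && all(is.na(dp))) dp <- NULL
  if (!is.null(gq) && all(is.na(gq))) gq <- NULL
  gene <- fix$CHROM
  if (!is.null(gene_map)) {
    hit <- gene_map[gene]
    gene <- ifelse(is.na(hit), gene, unname(hit))
  }
  aa <- rep("unknown", nrow(fix))
  if (!is.null(fix$INFO)) {
    has <- !is.na(fix$INFO) & grepl("AA=", fix$INFO)
    aa_base <- rep(NA_character_, nrow(fix))
    aa_base[has] <- sub(".*AA=([^;]+).*", "\\1", fix$INFO[has])
    aa[!is.na(aa_base) & aa_base == fix$REF] <- "ref"
    aa[!is.na(aa_base) & aa_base == fix$ALT] <- "alt"
  }
  site_meta <- data.frame(
    site_id = if (!is.null(fix$ID) && !all(fix$ID %in% c(".", NA)))
      fix$ID else paste0(fix$CHROM, ":", fix$POS),
    gene = gene,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    ancestral = aa,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    depth = if (is.null(dp)) NA_real_ else colMeans(dp, na.rm = TRUE),
    stringsAsFactors = FALSE)
  if (is.null(sample_meta))
    sample_meta <- data.frame(sample = colnames(gt),
                              population = NA_character_,
                              lat = NA_real_, lon = NA_real_,
                              stringsAsFactors = FALSE)
  rownames(dos) <- colnames(gt)
  genotype_matrix(dos, site_meta, sample_meta,
                  depth_matrix = dp, gq_matrix = gq)
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Emits GT (and DP when a per-cell depth matrix is present), the QUAL
#' column, and the ancestral allele as an `AA=` INFO tag, so
#' `read_vcf(write_vcf(gm))` round-trips the container content.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  sm <- gm$site_meta
  n_ind <- n_individuals(gm)
  samples <- as.character(gm$sample_meta$sample)
  gt_code <- c("0/0", "0/1", "1/1")
  has_dp <- !is.null(gm$depth_matrix)
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (has_dp)
    lines <- c(lines,
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  lines <- c(lines,
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  aa_base <- ifelse(sm$ancestral == "ref", sm$ref,
                    ifelse(sm$ancestral == "alt", sm$alt, "."))
  info <- ifelse(aa_base == ".", ".", paste0("AA=", aa_base))
  fmt <- if (has_dp) "GT:DP" else "GT"
  body <- vapply(seq_len(nrow(sm)), function(j) {
    d <- gm$dosages[, j]
    g <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    if (has_dp) {
      dp <- gm$depth_matrix[, j]
      g <- paste0(g, ":", ifelse(is.na(dp), ".", as.character(round(dp))))
    }
    paste(c(sm$gene[j], sm$pos[j], sm$site_id[j], sm$ref[j], sm$alt[j],
            if (is.na(sm$qual[j])) "." else format(sm$qual[j]), "PASS",
            info[j], fmt, g), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Apply variant filters
#'
#' Per-genotype masks are applied first (GQ and depth below threshold set
#' genotypes to missing, as VCFtools does), then sites are removed by the
#' first failing site-level rule, evaluated in the order site quality ->
#' heterozygosity -> missingness -> minor allele frequency, so the removal
#' counts partition the removed sites.
#'
#' @param gm a [genotype_matrix()].
#' @param spec a [filter_spec()].
#' @return A list: `gm`, the filtered [genotype_matrix()]; `removed`, named
#'   counts of sites removed per rule; `masked_genotypes`, named counts of
#'   genotypes set missing by the GQ and depth masks.
#' @export
apply_filters <- function(gm, spec = filter_spec()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "filter_spec"))
  if (n_sites(gm) == 0) stop("empty genotype matrix")
  dos <- gm$dosages
  masked <- c(gq = 0L, depth = 0L)
  if (!is.null(gm$gq_matrix) && spec$genotype_quality_min > 0) {
    m <- !is.na(dos) & !is.na(gm$gq_matrix) &
      gm$gq_matrix < spec$genotype_quality_min
    masked["gq"] <- sum(m)
    dos[m] <- NA_integer_
  }
  if (!is.null(gm$depth_matrix) && spec$depth_min > 0) {
    m <- !is.na(dos) & !is.na(gm$depth_matrix) &
      gm$depth_matrix < spec$depth_min
    masked["depth"] <- sum(m)
    dos[m] <- NA_integer_
  }
  n_nm <- colSums(!is.na(dos))
  het_frac <- ifelse(n_nm > 0, colSums(dos == 1L, na.rm = TRUE) / n_nm, 0)
  miss_frac <- colMeans(is.na(dos))
  p_alt <- ifelse(n_nm > 0, colSums(dos, na.rm = TRUE) / (2 * n_nm), 0)
  maf <- pmin(p_alt, 1 - p_alt)
  qual <- gm$site_meta$qual
  fail_qual <- !is.na(qual) & qual < spec$site_quality_min
  # fractions fail inclusively ("< 80% heterozygosity" keeps het < 0.80);
  # a threshold of 1 disables the rule
  fail_het <- spec$max_het_fraction < 1 & het_frac >= spec$max_het_fraction
  fail_miss <- spec$max_missing_fraction < 1 &
    miss_frac >= spec$max_missing_fraction
  fail_maf <- maf < spec$maf_min
  first_fail <- rep(NA_character_, length(maf))
  first_fail[fail_maf] <- "maf"
  first_fail[fail_miss] <- "missing"
  first_fail[fail_het] <- "het"
  first_fail[fail_qual] <- "quality"
  keep <- is.na(first_fail)
  removed <- c(quality = sum(first_fail == "quality", na.rm = TRUE),
               het = sum(first_fail == "het", na.rm = TRUE),
               missing = sum(first_fail == "missing", na.rm = TRUE),
               maf = sum(first_fail == "maf", na.rm = TRUE))
  out <- genotype_matrix(dos[, keep, drop = FALSE],
                         gm$site_meta[keep, , drop = FALSE],
                         gm$sample_meta,
                         depth_matrix = if (is.null(gm$depth_matrix)) NULL else
                           gm$depth_matrix[, keep, drop = FALSE],
                         gq_matrix = if (is.null(gm$gq_matrix)) NULL else
                           gm$gq_matrix[, keep, drop = FALSE])
  list(gm = out, removed = removed, masked_genotypes = masked)
}

#' Genotype-coverage independence check
#'
#' Squared correlation between read depth and (a) the additive dosage coding
#' 0/1/2 and (b) the heterozygote indicator, over non-missing cells.  In
#' well-filtered data both should be near zero; transcriptome variant sets
#' with residual expression-coverage coupling inflate them.
#'
#' @param gm a [genotype_matrix()] with a per-cell depth matrix.
#' @return List with `r2_additive` and `r2_het` (0 when a variable is
#'   constant).
#' @export
coverage_genotype_qc <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$depth_matrix)) stop("per-cell depth matrix required")
  ok <- !is.na(gm$dosages) & !is.na(gm$depth_matrix)
  d <- gm$dosages[ok]
  dp <- gm$depth_matrix[ok]
  r2 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)^2
  }
  list(r2_additive = r2(d, dp), r2_het = r2(as.numeric(d == 1L), dp))
}

#' Unfolded site frequency spectrum
#'
#' Polarizes dosages with the per-site ancestral-allele annotation (derived
#' dosage is `2 - d` when the alt allele is ancestral), excludes sites with
#' unknown ancestral state, with missing genotypes (so the spectrum has a
#' single haploid size), or monomorphic after polarization, and tallies
#' derived-allele counts 1..n-1.
#'
#' @param gm a [genotype_matrix()].
#' @param sites optional integer vector of site indices to include.
#' @param normalized logical; return class proportions instead of counts.
#' @return An object of class `sfs`: list with `counts` (length n-1), `n`
#'   (haploid sample size), `normalized`, and `excluded` (named counts of
#'   sites left out and why).
#' @export
unfolded_sfs <- function(gm, sites = NULL, normalized = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  idx <- if (is.null(sites)) seq_len(n_sites(gm)) else sites
  anc <- gm$site_meta$ancestral[idx]
  dos <- gm$dosages[, idx, drop = FALSE]
  unpol <- anc == "unknown"
  if (all(unpol)) stop("no polarized sites (all ancestral states unknown)")
  incomplete <- colSums(is.na(dos)) > 0
  use <- !unpol & !incomplete
  n <- 2L * nrow(dos)
  der <- colSums(dos[, use, drop = FALSE])
  flip <- anc[use] == "alt"
  der[flip] <- n - der[flip]
  poly <- der >= 1 & der <= n - 1
  counts <- tabulate(der[poly], nbins = n - 1)
  if (normalized && sum(counts) > 0) counts <- counts / sum(counts)
  structure(list(counts = counts, n = n, normalized = normalized,
                 excluded = c(unpolarized = sum(unpol),
                              incomplete = sum(!unpol & incomplete),
                              monomorphic = sum(!poly))),
            class = "sfs")
}

#' Per-gene site index
#'
#' Maps each gene id to the indices of its sites and its number of
#' segregating sites S; genes with no surviving sites are absent.
#'
#' @param gm a [genotype_matrix()].
#' @return Named list; each element has `sites` (integer indices) and `S`.
#' @export
per_gene_index <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  split_idx <- split(seq_len(n_sites(gm)), gm$site_meta$gene)
  lapply(split_idx, function(ix) list(sites = ix, S = length(ix)))
}

#' Per-site derived-allele counts for a set of sites
#'
#' Helper shared by the diversity and sweep statistics: polarized derived
#' count and site-specific haploid size (2 x non-missing individuals) for
#' each requested site.  Unpolarized sites fall back to the alt allele as
#' the derived state when `require_polarized = FALSE`.
#'
#' @param gm a [genotype_matrix()].
#' @param sites integer site indices.
#' @param require_polarized error on sites with unknown ancestral state.
#' @return data.frame with `site`, `pos`, `count` (derived), `n` (haploid).
#' @export
site_counts <- function(gm, sites, require_polarized = FALSE) {
  dos <- gm$dosages[, sites, drop = FALSE]
  anc <- gm$site_meta$ancestral[sites]
  if (require_polarized && any(anc == "unknown"))
    stop("unpolarized site(s) in input")
  n <- 2L * colSums(!is.na(dos))
  cnt <- colSums(dos, na.rm = TRUE)
  flip <- anc == "alt"
  cnt[flip] <- n[flip] - cnt[flip]
  data.frame(site = sites, pos = gm$site_meta$pos[sites],
             count = as.integer(cnt), n = as.integer(n))
}

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param individuals integer or logical index over individuals, or a
#'   character vector of population ids.
#' @param sites integer or logical index over sites.
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, individuals = NULL, sites = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ii <- seq_len(n_individuals(gm))
  if (!is.null(individuals)) {
    ii <- if (is.character(individuals))
      which(gm$sample_meta$population %in% individuals) else individuals
  }
  jj <- if (is.null(sites)) seq_len(n_sites(gm)) else sites
  genotype_matrix(gm$dosages[ii, jj, drop = FALSE],
                  gm$site_meta[jj, , drop = FALSE],
                  gm$sample_meta[ii, , drop = FALSE],
                  depth_matrix = if (is.null(gm$depth_matrix)) NULL else
                    gm$depth_matrix[ii, jj, drop = FALSE],
                  gq_matrix = if (is.null(gm$gq_matrix)) NULL else
                    gm$gq_matrix[ii, jj, drop = FALSE])
}
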