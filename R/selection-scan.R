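## Genome scans for spatially varying selection: a PCA-differentiation scan
## (Mahalanobis distance of per-axis association z-scores, genomic-inflation
## corrected) and an environmental-association scan (per-SNP regression on
## environmental PCs with genotype-PC latent covariates).  Both report
## Storey q-values over the pooled SNP set.

# centered, unit-scaled dosage matrix with missing cells imputed to the
# site mean; constant sites get zero columns
scaled_dosages <- function(gm) {
  x <- gm$dosages
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  x <- sweep(x, 2, colMeans(x))
  sdv <- sqrt(colMeans(x^2))
  sdv[sdv == 0] <- Inf
  sweep(x, 2, sdv, "/")
}

#' Genotype PCA with optional LD pruning
#'
#' Truncated SVD of the column-centered, unit-scaled dosage matrix (missing
#' imputed to site means).  Pruning greedily drops a SNP whose squared
#' correlation with any retained SNP within the trailing window exceeds
#' `r2_max`.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of components (0 < K < min(individuals, SNPs)).
#' @param ld_prune optional list `list(r2_max = 0.1, window = 200)`.
#' @return List: `scores` (individuals x K), `loadings` (SNPs x K), `d`
#'   singular values, `kept` (site indices used).
#' @export
genotype_pca <- function(gm, K = 4, ld_prune = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (K <= 0) stop("K must be positive")
  x <- scaled_dosages(gm)
  kept <- seq_len(ncol(x))
  if (!is.null(ld_prune)) {
    kept <- ld_prune_indices(x, ld_prune$r2_max, ld_prune$window)
    x <- x[, kept, drop = FALSE]
  }
  if (K >= min(dim(x))) stop("K must be < min(individuals, SNPs)")
  sv <- svd(x, nu = K, nv = K)
  scores <- sv$u %*% diag(sv$d[seq_len(K)], K)
  list(scores = scores, loadings = sv$v, d = sv$d[seq_len(K)], kept = kept)
}

# greedy LD pruning on a scaled dosage matrix
ld_prune_indices <- function(x, r2_max = 0.1, window = 200) {
  m <- ncol(x)
  n <- nrow(x)
  keep <- integer(0)
  for (j in seq_len(m)) {
    if (length(keep)) {
      w <- keep[max(1, length(keep) - window + 1):length(keep)]
      r <- crossprod(x[, w, drop = FALSE], x[, j]) / n
      if (any(r^2 > r2_max, na.rm = TRUE)) next
    }
    keep <- c(keep, j)
  }
  keep
}

#' PCA-differentiation outlier scan
#'
#' Regresses each scaled SNP on the K genotype-PC score vectors, collects
#' the per-axis z-scores, and ranks SNPs by the robust (median-centered)
#' Mahalanobis distance of their z-vector.  Distances are rescaled by the
#' genomic inflation factor `lambda = median(D) / median(chi^2_K)` and
#' converted to p-values from the chi-squared distribution with K degrees
#' of freedom.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of principal components.
#' @return An object of class `scan_result`: data.frame `snps` (site_id,
#'   gene, stat, p, q, axis) plus `lambda`, `method = "diff"`.
#' @export
pcadapt_scan <- function(gm, K = 4) {
  x <- scaled_dosages(gm)
  pca <- genotype_pca(gm, K)
  u <- qr.Q(qr(pca$scores))                 # orthonormal basis of the scores
  n <- nrow(x)
  bet <- crossprod(u, x)                    # K x M projections
  rss <- pmax(colSums(x^2) - colSums(bet^2), 0)
  df <- n - K - 1
  sigma2 <- rss / df
  z <- sweep(bet, 2, sqrt(pmax(sigma2, 1e-12)), "/")  # K x M z-scores
  zc <- z - apply(z, 1, stats::median)
  cv <- tcrossprod(zc) / ncol(zc)
  cv_inv <- tryCatch(solve(cv), error = function(e) {
    warning("singular z covariance; falling back to diagonal")
    diag(1 / pmax(diag(cv), 1e-12), nrow(cv))
  })
  d2 <- colSums((cv_inv %*% zc) * zc)
  lambda <- stats::median(d2) / stats::qchisq(0.5, K)
  p <- stats::pchisq(d2 / lambda, K, lower.tail = FALSE)
  const <- colSums(abs(x)) == 0
  p[const] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- qvalues(p[!is.na(p)])
  structure(list(snps = data.frame(site_id = gm$site_meta$site_id,
                                   gene = gm$site_meta$gene,
                                   stat = d2, p = p, q = q,
                                   axis = apply(abs(z), 2, which.max)),
                 lambda = lambda, method = "diff", K = K),
            class = "scan_result")
}

#' Environmental-association scan
#'
#' For each SNP and each environmental axis, fits the linear model
#' `dosage ~ env axis + K latent genotype-PC covariates` (population-level
#' environmental values broadcast to individuals), takes the t-statistic of
#' the environmental term, applies a genomic-inflation correction to the
#' squared t, and assigns each SNP to the axis with its smallest p-value.
#' This is a declared latent-factor approximation of ridge LFMM: the latent
#' structure is captured by genotype PCs rather than estimated jointly.
#'
#' @param gm a [genotype_matrix()].
#' @param env_pcs matrix of environmental PCs, one row per population (row
#'   names matching `sample_meta$population`) or per individual.
#' @param K_latent number of genotype-PC latent covariates.
#' @return A `scan_result` (method `"env"`); q-values are computed over the
#'   pooled (SNP x axis) test set and each SNP reports its best axis.
#' @export
env_association_scan <- function(gm, env_pcs, K_latent = 4) {
  env_pcs <- as.matrix(env_pcs)
  if (nrow(env_pcs) != n_individuals(gm)) {
    if (is.null(rownames(env_pcs)))
      stop("env_pcs must have population row names or one row per individual")
    env_pcs <- env_pcs[match(gm$sample_meta$population, rownames(env_pcs)), ,
                       drop = FALSE]
  }
  if (any(apply(env_pcs, 2, stats::sd) == 0))
    stop("environmental axis with zero variance")
  x <- scaled_dosages(gm)
  n <- nrow(x)
  lat <- genotype_pca(gm, K_latent)$scores
  # LFMM-style identifiability: the latent covariates are the genotype PCs
  # orthogonalized against the environmental axes, so structure collinear
  # with the environment is attributed to the environment, not absorbed
  qe <- qr.Q(qr(cbind(1, env_pcs)))
  lat <- lat - qe %*% crossprod(qe, lat)
  base <- cbind(1, lat)
  qb <- qr.Q(qr(base))
  x_res <- x - qb %*% crossprod(qb, x)
  m <- ncol(x)
  k_axes <- ncol(env_pcs)
  pmat <- tmat <- matrix(NA_real_, m, k_axes)
  df <- n - ncol(base) - 1
  for (a in seq_len(k_axes)) {
    e <- env_pcs[, a]
    e_res <- e - qb %*% crossprod(qb, e)
    e_norm <- sqrt(sum(e_res^2))
    if (e_norm < 1e-10) {
      warning("environmental axis ", a, " is collinear with the latent ",
              "covariates; skipped")
      next
    }
    r <- as.numeric(crossprod(x_res, e_res)) /
      (pmax(sqrt(colSums(x_res^2)), 1e-12) * e_norm)
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    tt <- r * sqrt(df) / sqrt(1 - r^2)
    # genomic-inflation rescaling of the squared statistic, p from the
    # t reference (exact under the null when lambda is 1)
    lam <- stats::median(tt^2) / stats::qchisq(0.5, 1)
    pmat[, a] <- 2 * stats::pt(abs(tt) / sqrt(lam), df, lower.tail = FALSE)
    tmat[, a] <- tt^2
  }
  # q-values over the pooled (SNP x axis) test set, so flagging a SNP on
  # its best axis keeps the false discovery rate controlled
  qmat <- pmat
  ok <- !is.na(pmat)
  qmat[ok] <- qvalues(pmat[ok])
  axis <- apply(pmat, 1, function(p)
    if (all(is.na(p))) NA_integer_ else which.min(p))
  pick <- cbind(seq_len(m), axis)
  structure(list(snps = data.frame(site_id = gm$site_meta$site_id,
                                   gene = gm$site_meta$gene,
                                   stat = tmat[pick], p = pmat[pick],
                                   q = qmat[pick], axis = axis),
                 lambda = NA_real_, method = "env", K = K_latent),
            class = "scan_result")
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05..0.95 with a
#' cubic smoothing spline evaluated at the largest lambda, then converts
#' p-values to q-values by the step-up minimum of `pi0 * m * p / rank(p)`.
#' With fewer than 100 p-values the spline is unstable and pi0 is set to 1
#' (Benjamini-Hochberg behavior).
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values, same order as `p`.
#' @export
qvalues <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  pi0 <- 1
  if (m >= 100) {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
    pi0 <- min(1, max(stats::predict(fit, x = max(lam))$y, 1e-4))
  }
  o <- order(p, decreasing = TRUE)
  r <- rank(p, ties.method = "max")
  q <- pi0 * m * p / r
  q[o] <- cummin(q[o])
  pmin(q, 1)
}

#' Gene-level outlier calls from a SNP scan
#'
#' A gene is an outlier when any of its SNPs has q below `alpha_q`; the
#' gene-level p is the minimum SNP p.  When two scans are supplied the
#' overlap of their outlier gene sets is tested with Fisher's exact test.
#'
#' @param ... one or more `scan_result` objects.
#' @param alpha_q q-value threshold (default 0.05).
#' @return List: `genes`, data.frame with per-method `min_p_<method>` and
#'   `outlier_<method>` columns; `overlap`, Fisher test summary when two
#'   scans are given.
#' @export
gene_outliers <- function(..., alpha_q = 0.05) {
  scans <- list(...)
  stopifnot(length(scans) >= 1,
            all(vapply(scans, inherits, TRUE, "scan_result")))
  tabs <- lapply(scans, function(s) {
    d <- s$snps
    agg <- do.call(rbind, lapply(split(d, d$gene), function(g)
      data.frame(gene = g$gene[1],
                 min_p = suppressWarnings(min(g$p, na.rm = TRUE)),
                 outlier = any(g$q < alpha_q, na.rm = TRUE))))
    agg$min_p[!is.finite(agg$min_p)] <- NA_real_
    names(agg)[2:3] <- paste0(c("min_p_", "outlier_"), s$method)
    agg
  })
  genes <- Reduce(function(a, b) merge(a, b, by = "gene", all = TRUE), tabs)
  out <- list(genes = genes)
  if (length(scans) == 2) {
    o1 <- genes[[paste0("outlier_", scans[[1]]$method)]]
    o2 <- genes[[paste0("outlier_", scans[[2]]$method)]]
    tab <- table(factor(o1, c(FALSE, TRUE)), factor(o2, c(FALSE, TRUE)))
    ft <- stats::fisher.test(tab)
    out$overlap <- list(table = tab, odds_ratio = unname(ft$estimate),
                        p = ft$p.value)
  }
  out
}

#' Regression of gene-level scan p-values on S and outlier status
#'
#' Standardizes the per-gene minimum p-values (mean 0, sd 1) and fits
#' `z(p) ~ S + outlier` by ordinary least squares; a strongly negative
#' outlier coefficient means outlier genes have smaller p-values than
#' their SNP counts alone explain.
#'
#' @param min_p per-gene minimum p-values.
#' @param S per-gene segregating-site counts.
#' @param outlier logical outlier flags.
#' @return List with `beta_S`, `beta_outlier`, standard errors, p-values
#'   and `r_squared`.
#' @export
s_controlled_regression <- function(min_p, S, outlier) {
  ok <- !is.na(min_p) & !is.na(S) & !is.na(outlier)
  min_p <- min_p[ok]; S <- S[ok]; outlier <- outlier[ok]
  if (length(min_p) < 3) stop("need at least 3 genes")
  if (stats::sd(min_p) == 0) stop("zero variance in response")
  if (length(unique(outlier)) < 2)
    stop("need both outlier classes present")
  z <- as.numeric(scale(min_p))
  out <- as.numeric(outlier)
  fit <- stats::lm(z ~ S + out)
  cf <- summary(fit)$coefficients
  list(beta_S = cf["S", 1], se_S = cf["S", 2], p_S = cf["S", 4],
       beta_outlier = cf["out", 1], se_outlier = cf["out", 2],
       p_outlier = cf["out", 4],
       r_squared = summary(fit)$r.squared)
}
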