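## Trans-eQTL mapping: all SNP x gene pairs, linear model with admixture
## covariates, pooled Storey q-values, eQTL/eGene classification and the
## eGenes-per-eQTL binomial model.

#' Remove leading expression principal components
#'
#' PCA on the individuals-by-genes matrix; each gene's expression is
#' replaced by its residual from a regression on the first `n_pcs` score
#' vectors (with intercept).  `n_pcs = 0` returns the input.
#'
#' @param em expression matrix, genes x individuals.
#' @param n_pcs number of components to remove.
#' @return Residual expression matrix, same shape.
#' @export
correct_expression <- function(em, n_pcs = 2) {
  em <- as.matrix(em)
  n <- ncol(em)
  if (n_pcs == 0) return(em)
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of individuals")
  if (n < n_pcs + 2) stop("need at least n_pcs + 2 individuals")
  pcs <- stats::prcomp(t(em), center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                               drop = FALSE]
  qb <- qr.Q(qr(cbind(1, pcs)))
  t(t(em) - qb %*% crossprod(qb, t(em)))
}

#' Map trans-eQTLs over all SNP x gene pairs
#'
#' For every SNP and every expression trait, fits
#' `expression ~ dosage + covariates` and tests the dosage term.  The
#' computation streams over SNP blocks with both sides projected out of the
#' covariate space (exact algebra: the t statistic equals the one from the
#' full regression).  Storey q-values are computed over the pooled test
#' set; pairs at `q < alpha_q` define eQTL source genes and eGene targets.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param em_corrected expression matrix (genes x individuals), typically
#'   from [correct_expression()].
#' @param covariates matrix of per-individual covariates (e.g. admixture
#'   proportions; one simplex column is dropped automatically when rows sum
#'   to 1), or `NULL`.
#' @param alpha_q significance threshold on q.
#' @param drop_self_pairs drop tests of a SNP against its own host gene
#'   (off by default: transcript SNPs are coding and self-pairs are counted).
#' @param block SNP block size for streaming.
#' @return An `eqtl_result` list: `associations` (significant pairs:
#'   `site_id`, `source`, `target`, `beta`, `t`, `p`, `q`), `candidates`
#'   (all pairs below a generous p cap, with q), `genes` (per-gene
#'   `is_eqtl`, `is_egene`, `is_both`, `n_targets`), `n_tests`,
#'   `n_skipped` (monomorphic), `alpha_q`.
#' @export
map_eqtl <- function(gm, em_corrected, covariates = NULL, alpha_q = 0.05,
                     drop_self_pairs = FALSE, block = 512L) {
  em <- as.matrix(em_corrected)
  n <- ncol(em)
  stopifnot(n == n_individuals(gm))
  x <- gm$dosages
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  covs <- NULL
  if (!is.null(covariates)) {
    covs <- as.matrix(covariates)
    if (all(abs(rowSums(covs) - 1) < 1e-6) && ncol(covs) > 1)
      covs <- covs[, -ncol(covs), drop = FALSE]     # simplex redundancy
  }
  qb <- qr.Q(qr(cbind(rep(1, n), covs)))
  df <- n - ncol(qb) - 1
  # residualize both sides once
  e_res <- em - (em %*% qb) %*% t(qb)
  e_norm <- sqrt(rowSums(e_res^2))
  x_res <- x - qb %*% crossprod(qb, x)
  x_norm <- sqrt(colSums(x_res^2))
  mono <- x_norm < 1e-10
  n_skipped <- sum(mono)
  m <- ncol(x)
  g <- nrow(em)
  gene_of_snp <- gm$site_meta$gene
  p_all <- numeric(0)
  hits <- vector("list", 0)
  blocks <- split(which(!mono), ceiling(seq_along(which(!mono)) / block))
  n_tests <- 0L
  # first pass: p-values (kept) per block; retain candidate pairs loosely
  # (p below a generous cap) so q can be assigned after pooling
  cap <- max(10 * alpha_q, 0.2)
  for (bl in blocks) {
    xb <- x_res[, bl, drop = FALSE]
    r <- (e_res %*% xb) / (pmax(e_norm, 1e-12) %o% pmax(x_norm[bl], 1e-12))
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tt <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    if (drop_self_pairs) {
      self <- outer(rownames(em), gene_of_snp[bl], "==")
      p[self] <- NA_real_
    }
    keep <- !is.na(p)
    n_tests <- n_tests + sum(keep)
    p_all <- c(p_all, p[keep])
    cand <- which(keep & p < cap, arr.ind = TRUE)
    if (nrow(cand)) {
      beta <- r * (e_norm / pmax(x_norm[bl], 1e-12)[col(r)])
      hits[[length(hits) + 1]] <- data.frame(
        site_id = gm$site_meta$site_id[bl[cand[, 2]]],
        source = gene_of_snp[bl[cand[, 2]]],
        target = rownames(em)[cand[, 1]],
        beta = beta[cand], t = tt[cand], p = p[cand])
    }
  }
  q_all <- qvalues(p_all)
  # map candidate p to q by rank interpolation (q is monotone in p)
  op <- order(p_all)
  cand <- if (length(hits)) do.call(rbind, hits) else
    data.frame(site_id = character(0), source = character(0),
               target = character(0), beta = numeric(0), t = numeric(0),
               p = numeric(0))
  pos <- findInterval(cand$p, p_all[op])
  cand$q <- q_all[op][pmax(pos, 1)]
  sig <- cand[cand$q < alpha_q, , drop = FALSE]
  all_genes <- union(rownames(em), gene_of_snp)
  is_eqtl <- all_genes %in% sig$source
  is_egene <- all_genes %in% sig$target
  n_targets <- vapply(all_genes, function(gg)
    length(unique(sig$target[sig$source == gg])), integer(1))
  genes <- data.frame(gene = all_genes, is_eqtl = is_eqtl,
                      is_egene = is_egene,
                      is_both = is_eqtl & is_egene,
                      n_targets = n_targets, row.names = NULL)
  structure(list(associations = sig, candidates = cand, genes = genes,
                 n_tests = n_tests, n_skipped = n_skipped,
                 alpha_q = alpha_q),
            class = "eqtl_result")
}

#' eGenes-per-eQTL binomial model
#'
#' Codes each eQTL source gene as 0 (single eGene) or 1 (multiple eGenes)
#' and fits a logistic regression of that indicator on outlier status with
#' S as a covariate; a positive outlier coefficient means adaptive eQTLs
#' regulate more targets.  Complete separation triggers a Firth-penalized
#' refit, flagged in the result.
#'
#' @param result an `eqtl_result` from [map_eqtl()].
#' @param S named per-gene segregating-site counts.
#' @param outlier named per-gene logical outlier flags.
#' @return List: `beta_outlier`, `se_outlier`, `ci` (Wald 95%), `p`,
#'   `firth` (fallback used), `n` (eQTL genes modeled).
#' @export
egene_count_model <- function(result, S, outlier) {
  stopifnot(inherits(result, "eqtl_result"))
  g <- result$genes[result$genes$is_eqtl, ]
  if (nrow(g) < 10) stop("need at least 10 eQTL genes")
  y <- as.integer(g$n_targets > 1)
  xo <- as.integer(outlier[g$gene])
  xs <- as.numeric(S[g$gene])
  ok <- !is.na(xo) & !is.na(xs)
  fit <- logistic_wald(y[ok], cbind(outlier = xo[ok], S = xs[ok]))
  list(beta_outlier = fit$beta["outlier"], se_outlier = fit$se["outlier"],
       ci = fit$ci["outlier", ], p = fit$p["outlier"], firth = fit$firth,
       n = sum(ok))
}

# logistic regression with Wald CIs and a Firth-penalized fallback on
# (quasi-)separation; shared by the eQTL and integration models
logistic_wald <- function(y, x) {
  x <- as.matrix(x)
  dat <- data.frame(y = y, x)
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
  sep <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 10)
  firth <- FALSE
  if (sep) {
    firth <- TRUE
    fit_f <- firth_logistic(y, cbind(1, x))
    beta <- fit_f$beta[-1]
    se <- fit_f$se[-1]
  } else {
    beta <- stats::coef(fit)[-1]
    se <- summary(fit)$coefficients[-1, 2]
  }
  names(beta) <- names(se) <- colnames(x)
  ci <- cbind(lo = beta - 1.96 * se, hi = beta + 1.96 * se)
  p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  list(beta = beta, se = se, ci = ci, p = p, firth = firth)
}

# Firth-penalized logistic regression (Jeffreys-prior score correction)
firth_logistic <- function(y, X, max_iter = 50, tol = 1e-8) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- solve(info + diag(1e-10, ncol(X)))
    h <- rowSums((X %*% info_inv) * XW)
    u <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- info_inv %*% u
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  se <- sqrt(diag(solve(crossprod(X, X * w) + diag(1e-10, ncol(X)))))
  list(beta = beta, se = se)
}
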