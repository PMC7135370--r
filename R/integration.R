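## Cross-cutting statistics: enrichment with bootstrap CIs, standardized
## multiple regressions with analytic 95% CIs, the label-permutation model
## fit test, and the connectivity / p-value trend summary.

#' Fisher enrichment of one gene set in another
#'
#' Two-sided Fisher's exact test on the 2x2 table of two logical flags
#' over the same gene universe; the conditional-MLE odds ratio is reported
#' (infinite when one margin is empty the right way).
#'
#' @param set_a,set_b logical vectors over the same genes.
#' @return List: `odds_ratio`, `p`, `table`.
#' @export
fisher_enrichment <- function(set_a, set_b) {
  stopifnot(length(set_a) == length(set_b), length(set_a) >= 1)
  tab <- table(factor(set_a, c(FALSE, TRUE)), factor(set_b, c(FALSE, TRUE)))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Percentile bootstrap CI for a flagged percentage
#'
#' @param flags logical (or 0/1) vector over genes (n >= 2).
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return List: `percent`, `lo`, `hi`.
#' @export
bootstrap_percent_ci <- function(flags, B = 1000, seed = 1, conf = 0.95) {
  n <- length(flags)
  stopifnot(n >= 2)
  flags <- as.numeric(flags)
  set.seed(seed)
  stat <- vapply(seq_len(B), function(b)
    100 * mean(flags[sample.int(n, n, replace = TRUE)]), numeric(1))
  qs <- stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2))
  list(percent = 100 * mean(flags), lo = unname(qs[1]), hi = unname(qs[2]))
}

#' Permutation test of the outlier term in `stat ~ S + outlier`
#'
#' Fits the observed linear model, then refits with the outlier labels
#' randomly permuted `n_perm` times; the add-one p-value is the fraction of
#' permuted fits whose R-squared reaches the observed one.
#'
#' @param stat per-gene statistic (e.g. Fay and Wu's H or CLR).
#' @param S per-gene segregating-site counts.
#' @param labels logical outlier flags (both classes present).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return List of class `permutation_test`: `observed_r2`, `p`, `n_perm`,
#'   and the permuted R-squared vector.
#' @export
permutation_fit_test <- function(stat, S, labels, n_perm = 10000, seed = 1) {
  ok <- !is.na(stat) & !is.na(S) & !is.na(labels)
  stat <- stat[ok]; S <- S[ok]; labels <- as.logical(labels[ok])
  if (stats::sd(stat) == 0) stop("constant statistic")
  if (length(unique(labels)) < 2 || min(table(labels)) < 2)
    stop("need at least 2 genes in each label class")
  y <- stat - mean(stat)
  tss <- sum(y^2)
  r2_of <- function(lab) {
    X <- cbind(1, S, lab)
    f <- stats::lm.fit(X, y)
    1 - sum(f$residuals^2) / tss
  }
  obs <- r2_of(labels)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    r2_of(sample(labels)), numeric(1))
  structure(list(observed_r2 = obs,
                 p = (1 + sum(perm >= obs)) / (n_perm + 1),
                 n_perm = n_perm, permuted_r2 = perm),
            class = "permutation_test")
}

# standardized OLS with analytic 95% CIs, condition-number guard
standardized_lm <- function(response, predictors) {
  X <- as.matrix(predictors)
  ok <- stats::complete.cases(X) & !is.na(response)
  X <- X[ok, , drop = FALSE]; y <- response[ok]
  if (length(y) < ncol(X) + 2) stop("too few observations")
  Xs <- scale(X)
  if (any(!is.finite(Xs))) stop("constant predictor")
  if (kappa(crossprod(Xs)) > 1e8) stop("collinear predictors")
  ys <- as.numeric(scale(y))
  fit <- stats::lm(ys ~ Xs)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  rn <- paste0("Xs", colnames(X))
  list(beta = stats::setNames(cf[rn, 1], colnames(X)),
       se = stats::setNames(cf[rn, 2], colnames(X)),
       p = stats::setNames(cf[rn, 4], colnames(X)),
       ci = matrix(ci[rn, ], ncol = 2,
                   dimnames = list(colnames(X), c("lo", "hi"))),
       r_squared = summary(fit)$r.squared, n = length(y))
}

#' Diversity ~ connectivity regression (standardized)
#'
#' Multiple regression of a per-gene diversity statistic on connectivity,
#' expression level and expression variance (all standardized), run
#' separately on a gene subset (outliers or background).
#'
#' @param theta per-gene diversity (theta-pi or theta-W).
#' @param connectivity per-gene network connectivity.
#' @param expr_level per-gene mean expression.
#' @param expr_variance per-gene expression variance.
#' @param subset optional logical subset of genes (>= 10 genes).
#' @return List with standardized `beta`, `se`, `p`, `ci` (95%),
#'   `r_squared`, `n`.
#' @export
diversity_connectivity_model <- function(theta, connectivity, expr_level,
                                         expr_variance, subset = NULL) {
  if (is.null(subset)) subset <- rep(TRUE, length(theta))
  d <- data.frame(theta, connectivity, expr_level, expr_variance)[subset, ]
  if (nrow(d) < 8) stop("need at least 8 genes")
  standardized_lm(d$theta, d[, c("connectivity", "expr_level",
                                 "expr_variance")])
}

#' Connectivity ~ outlier regression (standardized)
#'
#' Tests whether outlier genes are more connected after controlling for
#' expression level and variance; the outlier flag enters unstandardized
#' (0/1) so its coefficient is in connectivity-SD units.
#'
#' @param connectivity per-gene connectivity.
#' @param expr_level,expr_variance per-gene expression moments.
#' @param outlier logical outlier flags.
#' @return As [diversity_connectivity_model()], with `beta_outlier` the
#'   outlier coefficient.
#' @export
connectivity_outlier_model <- function(connectivity, expr_level,
                                       expr_variance, outlier) {
  ok <- stats::complete.cases(connectivity, expr_level, expr_variance,
                              outlier)
  k <- as.numeric(scale(connectivity[ok]))
  X <- cbind(level = as.numeric(scale(expr_level[ok])),
             variance = as.numeric(scale(expr_variance[ok])),
             outlier = as.numeric(outlier[ok]))
  fit <- stats::lm(k ~ X)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  rn <- paste0("X", colnames(X))
  list(beta = stats::setNames(cf[rn, 1], colnames(X)),
       se = stats::setNames(cf[rn, 2], colnames(X)),
       p = stats::setNames(cf[rn, 4], colnames(X)),
       ci = matrix(ci[rn, ], ncol = 2,
                   dimnames = list(colnames(X), c("lo", "hi"))),
       beta_outlier = cf["Xoutlier", 1],
       r_squared = summary(fit)$r.squared, n = sum(ok))
}

#' Logistic eQTL ~ outlier model
#'
#' Logistic regression of eQTL status on outlier status with S (scaled) as
#' a covariate; Wald 95% CIs, Firth-penalized fallback on separation.
#'
#' @param is_eqtl logical per-gene eQTL flags.
#' @param S per-gene segregating sites.
#' @param outlier logical per-gene outlier flags.
#' @return List: `beta_outlier`, `se_outlier`, `ci`, `p`, `firth`, `n`.
#' @export
eqtl_outlier_logistic <- function(is_eqtl, S, outlier) {
  ok <- stats::complete.cases(is_eqtl, S, outlier)
  fit <- logistic_wald(as.integer(is_eqtl[ok]),
                       cbind(outlier = as.integer(outlier[ok]),
                             S = as.numeric(scale(S[ok]))))
  list(beta_outlier = fit$beta["outlier"], se_outlier = fit$se["outlier"],
       ci = fit$ci["outlier", ], p = fit$p["outlier"], firth = fit$firth,
       n = sum(ok))
}

#' Connectivity / p-value trend summary
#'
#' Penalized-spline fit (`mgcv::gam`) of the per-gene scan p-values on
#' connectivity; reports the sign of the overall trend, whether the fitted
#' curve has an interior mode, and the CI of the linear slope for
#' flat-trend detection.
#'
#' @param connectivity per-gene connectivity (>= 50 genes).
#' @param min_p per-gene minimum scan p-values.
#' @param grid_n evaluation grid size.
#' @return List: `trend` (-1, 0, 1), `interior_mode` (logical),
#'   `slope`, `slope_ci`, `fitted` (grid data.frame), `edf`.
#' @export
connectivity_pvalue_trend <- function(connectivity, min_p, grid_n = 101) {
  ok <- !is.na(connectivity) & !is.na(min_p)
  k <- connectivity[ok]; p <- min_p[ok]
  if (length(k) < 50) stop("need at least 50 genes")
  d <- data.frame(k = k, y = as.numeric(scale(p)))
  fit <- mgcv::gam(y ~ s(k), data = d)
  grid <- data.frame(k = seq(min(k), max(k), length.out = grid_n))
  fhat <- as.numeric(stats::predict(fit, grid))
  # interior mode: a fitted value that rises above (or dips below) BOTH
  # curve endpoints by more than the tolerance; the response is on the
  # standardized scale, so the floor of 0.1 SD suppresses flat-fit wiggles
  tol <- max(0.1, 0.05 * diff(range(fhat)))
  inner <- 6:(grid_n - 5)
  peak <- any(fhat[inner] > fhat[1] + tol & fhat[inner] > fhat[grid_n] + tol)
  dip <- any(fhat[inner] < fhat[1] - tol & fhat[inner] < fhat[grid_n] - tol)
  interior <- peak || dip
  lfit <- stats::lm(y ~ k, data = d)
  ci <- stats::confint(lfit)["k", ]
  slope <- stats::coef(lfit)["k"]
  trend <- if (ci[1] > 0) 1L else if (ci[2] < 0) -1L else 0L
  list(trend = trend, interior_mode = interior, slope = unname(slope),
       slope_ci = unname(ci),
       fitted = data.frame(k = grid$k, fit = fhat),
       edf = sum(fit$edf))
}
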