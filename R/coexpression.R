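## Signed weighted co-expression network: soft-threshold adjacency at power
## six, topological overlap, average-linkage module detection with a static
## height cut, per-gene connectivity, and module-level outlier enrichment.

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^power` with Pearson correlation over
#' individuals (pairwise-complete).  Zero-variance genes get correlation 0
#' (adjacency `(1/2)^power`) with a warning.  The diagonal is set to 0 so
#' row sums are connectivities.
#'
#' @param em expression matrix, genes x individuals (>= 3 individuals).
#' @param power soft-thresholding exponent (default 6).
#' @return Symmetric adjacency matrix in [0, 1] with zero diagonal.
#' @export
signed_adjacency <- function(em, power = 6) {
  em <- as.matrix(em)
  if (ncol(em) < 3) stop("need at least 3 individuals")
  v <- apply(em, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s); correlations set to 0")
  }
  cr <- suppressWarnings(stats::cor(t(em), use = "pairwise.complete.obs"))
  cr[!is.finite(cr)] <- 0
  a <- ((1 + cr) / 2)^power
  diag(a) <- 0
  a
}

#' Per-gene connectivity
#'
#' Sum of a gene's adjacencies to all other genes (row sums of the
#' zero-diagonal adjacency).
#'
#' @param adjacency matrix from [signed_adjacency()].
#' @return Named numeric vector.
#' @export
connectivity <- function(adjacency) {
  a <- as.matrix(adjacency)
  diag(a) <- 0
  rowSums(a)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, and 1 on the diagonal; shared-neighborhood similarity used for
#' module clustering.
#'
#' @param adjacency matrix from [signed_adjacency()].
#' @return Symmetric matrix in [0, 1].
#' @export
tom_matrix <- function(adjacency) {
  a <- as.matrix(adjacency)
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Detect network modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' `1 - TOM`, cut at a quantile of the merge heights; clusters smaller than
#' `min_size` are left unassigned (label 0).  Labels are renumbered by
#' decreasing module size.
#'
#' @param tom matrix from [tom_matrix()].
#' @param min_size minimum module size (default 30).
#' @param cut_q quantile of merge heights used as the static cut (default
#'   0.99).
#' @return Integer vector of module labels (0 = unassigned), named by gene.
#' @export
detect_modules <- function(tom, min_size = 30, cut_q = 0.99) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  h <- stats::quantile(hc$height, cut_q)
  raw <- stats::cutree(hc, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- integer(length(raw))
  ord <- keep[order(-sizes[keep])]
  for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  names(labels) <- rownames(tom)
  labels
}

#' Module-level outlier enrichment
#'
#' Per assigned module, Fisher's exact test of the 2x2 table (in module x
#' outlier), with q-values over modules.
#'
#' @param labels module labels from [detect_modules()] (0 = unassigned).
#' @param outlier named or aligned logical outlier flags.
#' @return data.frame: `module`, `n_genes`, `n_outliers`, `odds_ratio`,
#'   `p`, `q`.
#' @export
module_enrichment <- function(labels, outlier) {
  stopifnot(length(labels) == length(outlier))
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) < 1) stop("no assigned modules")
  rows <- lapply(mods, function(mm) {
    inm <- labels == mm
    tab <- table(factor(inm, c(FALSE, TRUE)),
                 factor(outlier, c(FALSE, TRUE)))
    ft <- stats::fisher.test(tab)
    data.frame(module = mm, n_genes = sum(inm),
               n_outliers = sum(inm & outlier),
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- qvalues(out$p)
  out
}
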