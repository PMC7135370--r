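## Composite likelihood ratio sweep scan.
##
## The background is the dataset-wide unfolded SFS; at a candidate sweep
## position, a lineage at distance d escapes the sweep with probability
## 1 - exp(-d / alpha), where alpha is the sweep footprint length in bp
## (larger alpha = stronger/wider sweep; alpha -> 0 recovers the background).
## Escaped lineages retain their pre-sweep alleles (hypergeometric draw from
## the background class), while trapped lineages all inherit the allele of
## the sweeping haplotype.  Spectra are conditioned on polymorphism
## (invariant-class handling is off: transcript data lack reliable invariant
## counts).

#' Background site frequency spectrum for the CLR scan
#'
#' Normalized unfolded SFS pooled over all polarized, fully-genotyped sites.
#'
#' @param gm a [genotype_matrix()].
#' @param sites optional site subset.
#' @return A normalized `sfs` (see [unfolded_sfs()]); warns when fewer than
#'   100 polarized sites support it.
#' @export
background_sfs <- function(gm, sites = NULL) {
  sfs <- unfolded_sfs(gm, sites = sites, normalized = FALSE)
  total <- sum(sfs$counts)
  if (total < 100)
    warning("background SFS built from ", total,
            " sites; CLR estimates will be unstable")
  if (total == 0) stop("no usable sites for background SFS")
  sfs$counts <- sfs$counts / total
  sfs$normalized <- TRUE
  sfs
}

#' CLR model: background spectrum plus sweep-transform cache
#'
#' @param background a normalized unfolded `sfs`.
#' @param n_alpha number of sweep-footprint grid values per gene.
#' @param pe_floor smallest escape probability used when evaluating the
#'   spectrum at the candidate position itself (distance 0).
#' @return An object of class `clr_model`.
#' @export
clr_model <- function(background, n_alpha = 20, pe_floor = 1e-4) {
  stopifnot(inherits(background, "sfs"), background$normalized)
  stopifnot(abs(sum(background$counts) - 1) < 1e-8)
  structure(list(background = background, n_alpha = n_alpha,
                 pe_floor = pe_floor, cache = new.env(parent = emptyenv())),
            class = "clr_model")
}

#' Sweep-distorted sample spectrum
#'
#' Probability of each derived-allele class 1..n-1 after a sweep in which
#' every lineage independently escapes with probability `pe`: the escaped
#' subset keeps a hypergeometric draw from the pre-sweep class, the trapped
#' lineages inherit the sweeping haplotype's allele (derived with the
#' pre-sweep frequency).  `pe = 1` returns the background exactly; the
#' result is conditioned on polymorphism.
#'
#' @param b background class probabilities (length n-1, summing to 1).
#' @param n haploid sample size.
#' @param pe per-lineage escape probability in (0, 1].
#' @return Numeric vector of length n-1 (sums to 1).
#' @export
sweep_spectrum <- function(b, n, pe) {
  stopifnot(length(b) == n - 1, pe > 0, pe <= 1)
  out <- numeric(n + 1)  # classes 0..n
  wB <- stats::dbinom(0:n, n, pe)
  for (k in seq_len(n - 1)) {
    if (b[k] == 0) next
    q <- k / n
    for (B in 0:n) {
      if (wB[B + 1] < 1e-14) next
      h <- max(0, B - (n - k)):min(B, k)
      dh <- stats::dhyper(h, k, n - k, B)
      # trapped lineages (n - B copies) all derived w.p. q, ancestral w.p. 1-q
      jd <- h + (n - B)
      out[jd + 1] <- out[jd + 1] + b[k] * wB[B + 1] * dh * q
      out[h + 1] <- out[h + 1] + b[k] * wB[B + 1] * dh * (1 - q)
    }
  }
  poly <- out[2:n]
  s <- sum(poly)
  if (s < 1e-12) stop("sweep spectrum has no polymorphic mass")
  poly / s
}

# cache sweep spectra by escape probability rounded to 2 significant digits
sweep_spectrum_cached <- function(model, pe) {
  pe <- max(model$pe_floor, min(1, pe))
  key <- format(signif(pe, 2), scientific = TRUE)
  hit <- model$cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- sweep_spectrum(model$background$counts, model$background$n,
                        signif(pe, 2))
  assign(key, val, envir = model$cache)
  val
}

#' Alpha grid for a gene
#'
#' 20 log-spaced sweep footprint lengths chosen so the escape probability at
#' the gene's half-width spans (0.01, 0.99).
#'
#' @param half_width half the positional extent of the gene's sites (bp,
#'   floored at 1).
#' @param n_alpha grid size.
#' @return Increasing numeric vector.
#' @export
clr_alpha_grid <- function(half_width, n_alpha = 20) {
  hw <- max(half_width, 1)
  a_min <- hw / (-log(1 - 0.99))   # escape 0.99 at half-width (weak sweep)
  a_max <- hw / (-log(1 - 0.01))   # escape 0.01 at half-width (strong sweep)
  exp(seq(log(a_min), log(a_max), length.out = n_alpha))
}

#' Composite likelihood ratio for one gene
#'
#' Grid search over every variable site as the candidate sweep position and
#' over the per-gene alpha grid; returns `2 * (max log composite likelihood
#' under the sweep model - log composite likelihood under the background)`,
#' clamped at 0 (the background is a nested limit), with the argmax alpha
#' and position.  Ties are resolved toward the smallest (weakest) alpha.
#'
#' @param sites data.frame with `pos`, `count` (derived, 1..n-1) and `n`
#'   (haploid; must equal the background's n).
#' @param model a [clr_model()].
#' @return List: `clr`, `alpha_hat`, `pos_hat`, `n_sites`.
#' @export
clr_gene <- function(sites, model) {
  stopifnot(inherits(model, "clr_model"), nrow(sites) >= 1)
  n <- model$background$n
  if (any(sites$n != n))
    stop("site haploid size differs from background SFS (", n, ")")
  if (any(sites$count <= 0 | sites$count >= n))
    stop("sites must be polymorphic (derived count in 1..n-1)")
  b <- model$background$counts
  log_b <- log(pmax(b, 1e-300))
  ll0 <- sum(log_b[sites$count])
  hw <- (max(sites$pos) - min(sites$pos)) / 2
  alphas <- clr_alpha_grid(hw, model$n_alpha)
  best <- list(ll = -Inf, alpha = alphas[1], pos = sites$pos[1])
  for (x in sites$pos) {
    d <- abs(sites$pos - x)
    for (a in alphas) {
      pe <- 1 - exp(-d / a)
      ll <- 0
      for (s in seq_len(nrow(sites))) {
        sp <- sweep_spectrum_cached(model, pe[s])
        ll <- ll + log(max(sp[sites$count[s]], 1e-300))
      }
      # strict improvement required, so ties keep the smaller alpha
      if (ll > best$ll + 1e-12) best <- list(ll = ll, alpha = a, pos = x)
    }
  }
  list(clr = max(0, 2 * (best$ll - ll0)), alpha_hat = best$alpha,
       pos_hat = best$pos, n_sites = nrow(sites))
}

#' CLR sweep scan over all genes
#'
#' Builds the dataset-wide background SFS (optionally on a sample subset,
#' e.g. one population) and runs [clr_gene()] for every gene with at least
#' one polarized, fully-genotyped polymorphic site.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param individuals optional subset passed to [subset_genotypes()].
#' @param n_alpha alpha grid size per gene.
#' @return data.frame: `gene`, `clr`, `alpha_hat`, `pos_hat`, `n_sites`.
#' @export
clr_scan <- function(gm, individuals = NULL, n_alpha = 20) {
  if (!is.null(individuals)) gm <- subset_genotypes(gm, individuals)
  model <- clr_model(background_sfs(gm), n_alpha = n_alpha)
  n <- model$background$n
  idx <- per_gene_index(gm)
  rows <- lapply(names(idx), function(g) {
    js <- idx[[g]]$sites
    ok <- gm$site_meta$ancestral[js] != "unknown" &
      colSums(is.na(gm$dosages[, js, drop = FALSE])) == 0
    js <- js[ok]
    if (!length(js)) return(NULL)
    sc <- site_counts(gm, js, require_polarized = TRUE)
    sc <- sc[sc$count > 0 & sc$count < sc$n, , drop = FALSE]
    if (!nrow(sc)) return(NULL)
    r <- clr_gene(sc, model)
    data.frame(gene = g, clr = r$clr, alpha_hat = r$alpha_hat,
               pos_hat = r$pos_hat, n_sites = r$n_sites,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
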