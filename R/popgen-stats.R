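## Per-gene diversity, neutrality and differentiation statistics.
## Genes (transcript contigs) are the unit of analysis; "span" is the number
## of callable sites considered, so theta values are comparable within a run
## but are not absolute per-bp rates.

harmonic <- function(n, power = 1) if (n < 1) 0 else sum(1 / seq_len(n)^power)

#' Nucleotide diversity (theta-pi)
#'
#' Average number of pairwise differences per site:
#' `sum_site 2 i (n - i) / (n (n - 1)) / span`, with site-specific haploid
#' size `n` (pairwise deletion of missing genotypes).
#'
#' @param counts per-site derived (or minor) allele counts.
#' @param n_per_site per-site haploid sample sizes (recycled if scalar).
#' @param span number of sites considered (> 0).
#' @return Per-site diversity.
#' @export
theta_pi <- function(counts, n_per_site, span = length(counts)) {
  if (span <= 0) stop("span must be > 0")
  if (!length(counts)) return(0)
  n <- rep_len(n_per_site, length(counts))
  stopifnot(all(counts > 0), all(counts < n))
  sum(2 * counts * (n - counts) / (n * (n - 1))) / span
}

#' Watterson's theta
#'
#' `S / a1 / span` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S number of segregating sites.
#' @param n haploid sample size (>= 2).
#' @param span number of sites considered (> 0).
#' @return Per-site estimate.
#' @export
theta_w <- function(S, n, span = S) {
  stopifnot(n >= 2)
  if (S == 0) return(0)
  if (span <= 0) stop("span must be > 0")
  (S / harmonic(n - 1)) / span
}

#' Tajima's D
#'
#' Scaled difference between pairwise diversity and Watterson's estimator,
#' using the 1989 variance constants; undefined (NA) when S = 0.
#'
#' @param counts per-site derived or minor allele counts.
#' @param n_per_site per-site haploid sizes.
#' @return Unitless D, or `NA` when undefined.
#' @export
tajimas_d <- function(counts, n_per_site) {
  S <- length(counts)
  if (S == 0) return(NA_real_)
  n_site <- rep_len(n_per_site, S)
  n <- round(mean(n_site))
  if (n < 3) return(NA_real_)
  pi_tot <- theta_pi(counts, n_site, span = 1)
  a1 <- harmonic(n - 1)
  a2 <- harmonic(n - 1, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_tot - S / a1) / sqrt(v)
}

#' Normalized Fay and Wu's H
#'
#' Contrast between pairwise diversity and the high-frequency-weighted
#' estimator `theta_L = sum(i) / (n - 1)` over polarized sites, standardized
#' by its neutral variance (estimated with Watterson's theta and the
#' unbiased theta-squared estimator).  Strongly negative values indicate an
#' excess of high-frequency derived alleles, the footprint of a completed
#' or ongoing sweep.
#'
#' @param counts per-site derived-allele counts (unfolded; polarized input
#'   required).
#' @param n haploid sample size (single value; sites with other sizes should
#'   be projected or dropped by the caller).
#' @param normalized return the variance-standardized statistic (default);
#'   otherwise the raw `theta_pi - theta_L` difference.
#' @return Unitless H (or `NA` when S = 0).
#' @export
fay_wu_h <- function(counts, n, normalized = TRUE) {
  S <- length(counts)
  if (S == 0) return(NA_real_)
  stopifnot(n >= 3, all(counts > 0), all(counts < n))
  pi_tot <- theta_pi(counts, n, span = 1)
  theta_l <- sum(counts) / (n - 1)
  if (!normalized) return(pi_tot - theta_l)
  a1 <- harmonic(n - 1)
  a2 <- harmonic(n - 1, 2)
  b_np1 <- harmonic(n, 2)
  theta_hat <- S / a1
  theta_sq <- S * (S - 1) / (a1^2 + a2)
  v <- theta_hat * (n - 2) / (6 * (n - 1)) +
    theta_sq * (18 * n^2 * (3 * n + 2) * b_np1 -
                  (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  if (v <= 0) return(NA_real_)
  (pi_tot - theta_l) / sqrt(v)
}

#' Hudson's FST (ratio of averages)
#'
#' Per-site numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`, aggregated as a ratio of sums; sites
#' fixed for the same allele in both populations are excluded.
#'
#' @param counts1,counts2 per-site allele counts in each population.
#' @param n1,n2 per-site haploid sizes (recycled if scalar; >= 2).
#' @return List with `fst` (ratio of sums), `num` and `den` site sums.
#' @export
hudson_fst <- function(counts1, counts2, n1, n2) {
  k <- length(counts1)
  stopifnot(length(counts2) == k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  if (any(n1 < 2) || any(n2 < 2)) stop("haploid sizes must be >= 2")
  p1 <- counts1 / n1; p2 <- counts2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  use <- den > 0 | num != 0
  if (!any(use)) return(list(fst = NA_real_, num = 0, den = 0))
  ns <- sum(num[use]); ds <- sum(den[use])
  list(fst = if (ds > 0) ns / ds else NA_real_, num = ns, den = ds)
}

#' Absolute divergence dXY
#'
#' `sum_site [p1(1-p2) + p2(1-p1)] / span`: the mean between-population
#' pairwise difference per site.
#'
#' @inheritParams hudson_fst
#' @param span number of sites considered (> 0).
#' @return Per-site divergence.
#' @export
dxy <- function(counts1, counts2, n1, n2, span = length(counts1)) {
  if (span <= 0) stop("span must be > 0")
  k <- length(counts1)
  if (!k) return(0)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  p1 <- counts1 / n1; p2 <- counts2 / n2
  sum(p1 * (1 - p2) + p2 * (1 - p1)) / span
}

#' Per-gene diversity and neutrality statistics
#'
#' Computes S, theta-pi, Watterson's theta, Tajima's D and (for polarized
#' sites) normalized Fay and Wu's H per gene; optionally Hudson's FST and
#' dXY between two declared population subsets.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param pop_pair optional character vector of two population ids (matched
#'   against `sample_meta$population`) for FST/dXY.
#' @return data.frame, one row per gene: `gene`, `S`, `theta_pi`, `theta_w`,
#'   `tajima_d`, `fay_wu_h`, and `fst`, `dxy` when `pop_pair` is given.
#' @export
gene_stats <- function(gm, pop_pair = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  idx <- per_gene_index(gm)
  pops <- gm$sample_meta$population
  if (!is.null(pop_pair)) {
    stopifnot(length(pop_pair) == 2)
    i1 <- which(pops == pop_pair[1]); i2 <- which(pops == pop_pair[2])
    if (!length(i1) || !length(i2))
      stop("population id(s) not found: ", paste(pop_pair, collapse = ", "))
  }
  rows <- lapply(names(idx), function(g) {
    sites <- idx[[g]]$sites
    sc <- site_counts(gm, sites)
    seg <- sc$count > 0 & sc$count < sc$n
    sc <- sc[seg, , drop = FALSE]
    S <- nrow(sc)
    span <- max(S, 1L)
    tp <- if (S) theta_pi(sc$count, sc$n, span) else 0
    n_mode <- if (S) round(mean(sc$n)) else 2L * n_individuals(gm)
    tw <- theta_w(S, max(n_mode, 2), span)
    td <- if (S) tajimas_d(sc$count, sc$n) else NA_real_
    pol <- gm$site_meta$ancestral[sc$site] != "unknown"
    complete <- colSums(is.na(gm$dosages[, sc$site, drop = FALSE])) == 0
    hp <- pol & complete
    h <- if (sum(hp) > 0) {
      scp <- site_counts(gm, sc$site[hp], require_polarized = TRUE)
      fay_wu_h(scp$count, 2L * n_individuals(gm))
    } else NA_real_
    out <- data.frame(gene = g, S = S, theta_pi = tp, theta_w = tw,
                      tajima_d = td, fay_wu_h = h, stringsAsFactors = FALSE)
    if (!is.null(pop_pair)) {
      d1 <- gm$dosages[i1, sc$site, drop = FALSE]
      d2 <- gm$dosages[i2, sc$site, drop = FALSE]
      m1 <- 2L * colSums(!is.na(d1)); m2 <- 2L * colSums(!is.na(d2))
      ok <- m1 >= 2 & m2 >= 2
      if (any(ok)) {
        c1 <- colSums(d1, na.rm = TRUE)[ok]; c2 <- colSums(d2, na.rm = TRUE)[ok]
        f <- hudson_fst(c1, c2, m1[ok], m2[ok])
        out$fst <- f$fst
        out$dxy <- dxy(c1, c2, m1[ok], m2[ok], span = sum(ok))
      } else {
        out$fst <- NA_real_; out$dxy <- NA_real_
      }
    }
    out
  })
  do.call(rbind, rows)
}
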