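#' Simulation configuration for the pleiotropic-QTL forward model
#'
#' Builds the parameter set for a Wright-Fisher simulation of a single
#' additive QTL region controlling `n_phen` correlated phenotypes under
#' Gaussian stabilizing selection around a displaced optimum.  Defaults are
#' the full-scale study conditions: a 50 kb region with a 10 kb genic core,
#' N = 10,000 diploids, mu = 1.5e-8 and r = 5e-8 per site per generation,
#' a 10N-generation neutral burn-in, after which 10% of new genic mutations
#' (1% elsewhere) become QTL mutations with multivariate-Gaussian effects
#' (sd 1, pairwise covariance 0.1), and population mean fitness recorded
#' 0.1N generations after selection starts.
#'
#' @param N diploid population size.
#' @param L region length in bp.
#' @param genic_start,genic_end genic-core interval, half-open `[start, end)`,
#'   0-based bp; defaults to the central fifth of the region.
#' @param mu per-site per-generation mutation rate.
#' @param r per-site per-generation recombination rate.
#' @param p_qtl_genic probability a post-burn-in genic mutation is a QTL mutation.
#' @param p_qtl_nongenic same outside the genic core.
#' @param n_phen number of phenotypes the QTL controls.
#' @param z0 phenotypic optimum (shared by all phenotypes; initial value is 0).
#' @param Vs variance of the Gaussian fitness profile.
#' @param effect_sd standard deviation of mutational effects.
#' @param effect_cov covariance between effect components (0 removes the
#'   trait-modularity coupling).
#' @param burn_in number of neutral burn-in generations (default 10N).
#' @param sample_at generations after selection onset at which mean fitness is
#'   recorded (default 0.1N).
#' @param fitness_form `"printed"` uses the doubly-damped published form
#'   `exp(-0.5 * sum((z - z0)^2) / (2 Vs))`; `"standard"` uses
#'   `exp(-sum((z - z0)^2) / (2 Vs))`.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [scaled_sim_config()] for a desk-scale variant preserving the
#'   per-site population-scaled rates.
#' @export
sim_config <- function(N = 10000, L = 50000,
                       genic_start = 0.4 * L, genic_end = 0.6 * L,
                       mu = 1.5e-8, r = 5e-8,
                       p_qtl_genic = 0.10, p_qtl_nongenic = 0.01,
                       n_phen = 1, z0 = 1, Vs = 10,
                       effect_sd = 1, effect_cov = 0.1,
                       burn_in = 10 * N, sample_at = round(0.1 * N),
                       fitness_form = c("printed", "standard")) {
  fitness_form <- match.arg(fitness_form)
  stopifnot(N >= 2, L > 0, mu >= 0, r >= 0,
            p_qtl_genic >= 0, p_qtl_genic <= 1,
            p_qtl_nongenic >= 0, p_qtl_nongenic <= 1,
            n_phen >= 1, Vs > 0, effect_sd >= 0,
            burn_in >= 0, sample_at >= 1)
  if (!(genic_start >= 0 && genic_end <= L && genic_start < genic_end))
    stop("genic interval must lie inside [0, L)")
  sigma <- effect_sigma(n_phen, effect_sd, effect_cov)  # errors if not PSD
  cfg <- list(N = as.integer(N), L = L,
              genic_start = genic_start, genic_end = genic_end,
              mu = mu, r = r,
              p_qtl_genic = p_qtl_genic, p_qtl_nongenic = p_qtl_nongenic,
              n_phen = as.integer(n_phen), z0 = z0, Vs = Vs,
              effect_sd = effect_sd, effect_cov = effect_cov,
              burn_in = as.integer(burn_in), sample_at = as.integer(sample_at),
              fitness_form = fitness_form, sigma_chol = sigma)
  class(cfg) <- "sim_config"
  cfg
}

#' Desk-scale simulation configuration
#'
#' Rescales the full-scale model to N = 200 diploids and a 5 kb region with
#' mutation and recombination rates multiplied by 50, which preserves the
#' per-site population-scaled rates 4N*mu and 4N*r.  Burn-in keeps its 10N
#' proportion (2,000 generations).  The selection phase is kept at 10,000
#' generations so that its total expected mutational input matches the
#' full-scale protocol (15,000 mutations over 0.1N generations at 15 per
#' generation); selection coefficients and effect sizes are not rescaled, so
#' shortening the phase in proportion to N would truncate the adaptive walk
#' instead of rescaling it.
#'
#' @param sample_at selection-phase length in generations.
#' @param N,L,mu,r scaled population size, region length and rates.
#' @param ... further overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
scaled_sim_config <- function(sample_at = 10000, N = 200, L = 5000,
                              mu = 1.5e-8 * 50, r = 5e-8 * 50, ...) {
  sim_config(N = N, L = L, mu = mu, r = r, sample_at = sample_at, ...)
}

# Cholesky factor of the effect covariance matrix (diag effect_sd^2,
# off-diagonal effect_cov); errors when the matrix is not PSD.
effect_sigma <- function(n_phen, effect_sd, effect_cov) {
  sigma <- matrix(effect_cov, n_phen, n_phen)
  diag(sigma) <- effect_sd^2
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("effect covariance matrix is not positive semidefinite"))
  ch
}

#' Gaussian stabilizing-selection fitness
#'
#' `w = exp(-0.5 * sum_i (z_i - z0)^2 / (2 Vs))` for the default doubly-damped
#' published form, or `exp(-sum_i (z_i - z0)^2 / (2 Vs))` for
#' `form = "standard"`.
#'
#' @param z phenotype vector, or a matrix with one individual per row.
#' @param z0 optimum (scalar, shared across phenotypes).
#' @param Vs fitness-profile variance (> 0).
#' @param form `"printed"` (default) or `"standard"`.
#' @return Fitness value(s) in (0, 1].
#' @export
fitness <- function(z, z0, Vs, form = c("printed", "standard")) {
  form <- match.arg(form)
  stopifnot(Vs > 0)
  if (is.matrix(z)) ss <- rowSums((z - z0)^2) else ss <- sum((z - z0)^2)
  damp <- if (form == "printed") 0.5 else 1
  exp(-damp * ss / (2 * Vs))
}

#' Draw mutational effect vectors
#'
#' Multivariate Gaussian with mean 0, component standard deviation
#' `effect_sd` and pairwise covariance `effect_cov`; every QTL mutation
#' affects all phenotypes.
#'
#' @param n number of draws.
#' @param n_phen number of phenotype components.
#' @param effect_sd component standard deviation.
#' @param effect_cov pairwise covariance.
#' @return `n` x `n_phen` matrix of effects.
#' @export
draw_effects <- function(n, n_phen, effect_sd = 1, effect_cov = 0.1) {
  ch <- effect_sigma(n_phen, effect_sd, effect_cov)
  z <- matrix(stats::rnorm(n * n_phen), n, n_phen)
  z %*% ch
}

#' Run one Wright-Fisher replicate
#'
#' Discrete, non-overlapping generations; haplotypes carry sets of
#' infinite-sites mutations at uniform positions.  During burn-in every
#' mutation is neutral and parents are sampled uniformly.  After selection
#' onset each new mutation becomes a QTL mutation with the position-dependent
#' probability and receives a multivariate-Gaussian effect vector; individual
#' phenotypes are the additive sums of effect vectors over carried copies,
#' and parents are sampled proportionally to Gaussian stabilizing-selection
#' fitness around the optimum `z0`.  Population mean fitness is recorded
#' `sample_at` generations after selection onset.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed for this replicate.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation of the same model; much slower, kept as a cross-check).
#' @return A list: `mean_fitness` at the sampling generation, `mean_phenotype`
#'   (length `n_phen`), `n_qtl_segregating`, and `S_burnin`, the count of
#'   segregating sites at the end of burn-in.
#' @export
run_replicate <- function(cfg, seed = NULL, engine = c("cpp", "r")) {
  stopifnot(inherits(cfg, "sim_config"))
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  if (engine == "cpp") {
    damp <- if (cfg$fitness_form == "printed") 0.5 else 1
    out <- wf_replicate_cpp(cfg$N, cfg$L, cfg$genic_start, cfg$genic_end,
                            cfg$mu, cfg$r, cfg$p_qtl_genic, cfg$p_qtl_nongenic,
                            cfg$n_phen, cfg$z0, cfg$Vs, cfg$sigma_chol,
                            cfg$burn_in, cfg$sample_at, damp)
  } else {
    out <- wf_replicate_r(cfg)
  }
  # adaptive gain relative to the unadapted (all-zero) phenotype, in log
  # mean-fitness units; removes the exp(-n*z0^2/(4 Vs)) baseline so classes
  # with different n_phen are comparable
  w0 <- fitness(rep(0, cfg$n_phen), cfg$z0, cfg$Vs, cfg$fitness_form)
  out$log_gain <- log(out$mean_fitness) - log(w0)
  out
}

# Pure-R reference implementation of the Wright-Fisher core; same model as
# wf_replicate_cpp but with its own (vectorized) draw order, so the two
# engines agree in distribution, not draw-for-draw.
wf_replicate_r <- function(cfg) {
  N <- cfg$N; L <- cfg$L; two_n <- 2L * N
  n_phen <- cfg$n_phen
  # haplotypes x mutations; columns: position pos[], effects eff[,] (0 rows
  # for neutral), qtl flag
  H <- matrix(0, two_n, 0)
  pos <- numeric(0)
  eff <- matrix(0, 0, n_phen)
  is_qtl <- logical(0)
  base_z <- numeric(n_phen)        # contribution of fixed QTL mutations
  mu_tot <- 2 * N * L * cfg$mu     # expected new mutations per generation
  r_tot <- cfg$r * L               # expected crossovers per gamete
  total_gen <- cfg$burn_in + cfg$sample_at
  S_burnin <- NA_integer_
  damp <- if (cfg$fitness_form == "printed") 0.5 else 1
  w <- rep(1, N)
  odd <- seq(1L, two_n, by = 2L); even <- odd + 1L

  for (gen in seq_len(total_gen)) {
    selecting <- gen > cfg$burn_in
    # --- reproduction: one gamete per parent draw, 2N gametes
    if (selecting && any(w < 1)) {
      parents <- sample.int(N, two_n, replace = TRUE, prob = w)
    } else {
      parents <- sample.int(N, two_n, replace = TRUE)
    }
    # total crossover count per generation, then assigned to random gametes
    # (equivalent to independent Poisson(r*L) per gamete)
    n_co_tot <- stats::rpois(1L, two_n * r_tot)
    nco <- integer(two_n)
    if (n_co_tot > 0L) {
      tb <- tabulate(sample.int(two_n, n_co_tot, replace = TRUE), two_n)
      nco <- tb
    }
    hap_choice <- sample.int(2L, two_n, replace = TRUE) - 1L
    rows <- 2L * parents - 1L + hap_choice
    co <- if (n_co_tot > 0L) which(nco > 0L) else integer(0)
    H_par <- H
    H <- H[rows, , drop = FALSE]
    if (length(co) && length(pos)) {
      for (g in co) {
        p <- parents[g]
        bk <- stats::runif(nco[g], 0, L)
        if (nco[g] > 1L) bk <- sort.int(bk)
        # crossover parity: even segments from the starting haplotype,
        # odd segments from the homolog
        odd_seg <- findInterval(pos, bk) %% 2L == 1L
        if (any(odd_seg)) {
          homolog <- 2L * p - 1L + (1L - hap_choice[g])
          H[g, odd_seg] <- H_par[homolog, odd_seg]
        }
      }
    }
    # --- new mutations
    nm <- stats::rpois(1L, mu_tot)
    if (nm > 0L) {
      newcols <- matrix(0, two_n, nm)
      newcols[cbind(sample.int(two_n, nm, replace = TRUE), seq_len(nm))] <- 1
      newpos <- stats::runif(nm, 0, L)
      H <- cbind(H, newcols)
      pos <- c(pos, newpos)
      if (selecting) {
        p_qtl <- ifelse(newpos >= cfg$genic_start & newpos < cfg$genic_end,
                        cfg$p_qtl_genic, cfg$p_qtl_nongenic)
        qtl_new <- stats::runif(nm) < p_qtl
        eff_new <- matrix(0, nm, n_phen)
        if (any(qtl_new))
          eff_new[qtl_new, ] <- draw_effects(sum(qtl_new), n_phen,
                                             cfg$effect_sd, cfg$effect_cov)
        eff <- rbind(eff, eff_new)
        is_qtl <- c(is_qtl, qtl_new)
      } else {
        eff <- rbind(eff, matrix(0, nm, n_phen))
        is_qtl <- c(is_qtl, rep(FALSE, nm))
      }
    }
    # --- purge lost / fixed columns
    if (ncol(H)) {
      cs <- colSums(H)
      lost <- cs == 0; fixed <- cs == two_n
      if (any(fixed)) {
        fq <- fixed & is_qtl
        if (any(fq)) base_z <- base_z + 2 * colSums(eff[fq, , drop = FALSE])
      }
      keep <- !(lost | fixed)
      if (!all(keep)) {
        H <- H[, keep, drop = FALSE]
        pos <- pos[keep]; eff <- eff[keep, , drop = FALSE]
        is_qtl <- is_qtl[keep]
      }
    }
    if (gen == cfg$burn_in) S_burnin <- ncol(H)
    # --- phenotypes & fitness (needed from selection onset)
    if (gen >= cfg$burn_in) {
      if (any(is_qtl)) {
        D <- H[odd, is_qtl, drop = FALSE] + H[even, is_qtl, drop = FALSE]
        Z <- sweep(D %*% eff[is_qtl, , drop = FALSE], 2, -base_z)
      } else {
        Z <- matrix(rep(base_z, each = N), N, n_phen)
      }
      w <- exp(-damp * rowSums((Z - cfg$z0)^2) / (2 * cfg$Vs))
    }
  }
  list(mean_fitness = mean(w),
       mean_phenotype = colMeans(Z),
       n_qtl_segregating = sum(is_qtl),
       S_burnin = S_burnin)
}

#' Run a grid of simulation classes
#'
#' Runs `reps` replicates for every combination of pleiotropy level
#' (`n_list`) and optimum (`z0_list`), with per-replicate seeds derived
#' reproducibly from `seed`, and summarizes each class by the median and
#' interquartile range of population mean fitness.  Within each optimum the
#' fitness values are normalized against the non-pleiotropic class
#' (`n_phen = 1`): subtract its median, divide by its IQR.
#'
#' @param cfg template [sim_config()]; `n_phen` and `z0` are overridden.
#' @param n_list pleiotropy levels (must include 1 for normalization).
#' @param z0_list optima.
#' @param reps replicates per class (>= 2).
#' @param seed master seed.
#' @param engine simulation engine, see [run_replicate()].
#' @return A list of class `sim_result`: `replicates`, a data.frame with one
#'   row per replicate (`n_phen`, `z0`, `rep`, `mean_fitness`, `normalized`),
#'   and `classes`, per-class medians and IQRs (raw and normalized).
#' @export
run_grid <- function(cfg, n_list = c(1, 5, 10, 15, 20), z0_list = c(1, 5, 10),
                     reps = 300, seed = 1, engine = c("cpp", "r")) {
  stopifnot(inherits(cfg, "sim_config"))
  engine <- match.arg(engine)
  if (reps < 2) stop("reps must be >= 2 (IQR undefined otherwise)")
  if (!1 %in% n_list)
    stop("n_list must include the non-pleiotropic class n_phen = 1")
  grid <- expand.grid(n_phen = n_list, z0 = z0_list, rep = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  grid$mean_fitness <- NA_real_
  grid$log_gain <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg_i <- cfg
    cfg_i$n_phen <- as.integer(grid$n_phen[i])
    cfg_i$z0 <- grid$z0[i]
    cfg_i$sigma_chol <- effect_sigma(cfg_i$n_phen, cfg$effect_sd, cfg$effect_cov)
    rep_i <- run_replicate(cfg_i, seed = grid$seed[i], engine = engine)
    grid$mean_fitness[i] <- rep_i$mean_fitness
    grid$log_gain[i] <- rep_i$log_gain
  }
  grid$normalized <- normalize_fitness(grid$mean_fitness, grid$n_phen, grid$z0)
  grid$normalized_gain <- normalize_fitness(grid$log_gain, grid$n_phen, grid$z0)
  cls <- aggregate(cbind(mean_fitness, normalized, log_gain, normalized_gain) ~
                     n_phen + z0, data = grid,
                   FUN = function(x) c(median = stats::median(x),
                                       iqr = stats::IQR(x)))
  classes <- data.frame(n_phen = cls$n_phen, z0 = cls$z0,
                        median_fitness = cls$mean_fitness[, "median"],
                        iqr_fitness = cls$mean_fitness[, "iqr"],
                        median_normalized = cls$normalized[, "median"],
                        iqr_normalized = cls$normalized[, "iqr"],
                        median_log_gain = cls$log_gain[, "median"],
                        median_normalized_gain = cls$normalized_gain[, "median"])
  out <- list(replicates = grid[, c("n_phen", "z0", "rep", "mean_fitness",
                                    "log_gain", "normalized",
                                    "normalized_gain")],
              classes = classes)
  class(out) <- "sim_result"
  out
}

#' Normalize fitness against the non-pleiotropic class
#'
#' Within each optimum `z0`, subtracts the median and divides by the IQR of
#' the `n_phen = 1` class, so that class has median exactly 0 and IQR
#' exactly 1.
#'
#' @param x raw mean-fitness values.
#' @param n_phen pleiotropy level per value.
#' @param z0 optimum per value.
#' @return Normalized values, same length as `x`.
#' @export
normalize_fitness <- function(x, n_phen, z0) {
  stopifnot(length(x) == length(n_phen), length(x) == length(z0))
  out <- rep(NA_real_, length(x))
  for (z in unique(z0)) {
    ref <- x[z0 == z & n_phen == 1]
    if (!length(ref)) stop("no n_phen = 1 reference class for z0 = ", z)
    m <- stats::median(ref); iqr <- stats::IQR(ref)
    if (iqr == 0) stop("reference class IQR is 0; cannot normalize")
    out[z0 == z] <- (x[z0 == z] - m) / iqr
  }
  out
}
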