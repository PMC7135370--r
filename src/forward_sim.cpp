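#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Wright-Fisher core for a single recombining QTL region.
// Haplotypes are stored mutation-major in a flat buffer: row m holds the 2N
// allele states (0/1) of mutation m, with continuous (infinite-sites)
// positions.  Burn-in mutations are permanently neutral; after selection
// onset new mutations become QTL mutations with a position-dependent
// probability and carry an additive effect vector over all n_phen
// phenotypes.  Uses R's RNG so set.seed() in R makes replicates
// reproducible.
// [[Rcpp::export]]
List wf_replicate_cpp(int N, double L, double genic_start, double genic_end,
                      double mu, double r,
                      double p_qtl_genic, double p_qtl_nongenic,
                      int n_phen, double z0, double Vs,
                      NumericMatrix sigma_chol,
                      int burn_in, int sample_at, double damp) {
  const int twoN = 2 * N;
  int M = 0;                                 // current number of mutations
  std::vector<double> pos;                   // per mutation
  std::vector<char> qtl;
  std::vector<double> eff;                   // M x n_phen, row-major
  std::vector<unsigned char> alle, newalle;  // M x twoN, row-major
  std::vector<double> base_z(n_phen, 0.0);
  std::vector<double> w(N, 1.0), cumw(N), ss(N), Z((size_t)N * n_phen, 0.0);
  std::vector<int> par(twoN), prow(twoN), nco(twoN);
  std::vector<double> bk, zz(n_phen);
  bool have_w = false;
  const double mu_tot = 2.0 * N * L * mu;
  const double r_tot = r * L;
  const int total_gen = burn_in + sample_at;
  int S_burnin = NA_INTEGER;

  for (int gen = 1; gen <= total_gen; ++gen) {
    const bool selecting = gen > burn_in;

    // --- parent and starting-haplotype choice per gamete (one uniform draw
    // per gamete; its position inside the parent interval gives the
    // haplotype bit)
    if (selecting && have_w) {
      double tot = 0.0;
      for (int i = 0; i < N; ++i) { tot += w[i]; cumw[i] = tot; }
      for (int g = 0; g < twoN; ++g) {
        double u = unif_rand() * tot;
        int p = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) -
                      cumw.begin());
        if (p >= N) p = N - 1;
        par[g] = p;
        double lo = (p == 0) ? 0.0 : cumw[p - 1];
        double frac = (u - lo) / (cumw[p] - lo);
        prow[g] = 2 * p + (frac < 0.5 ? 0 : 1);
      }
    } else {
      for (int g = 0; g < twoN; ++g) {
        int row = (int)(unif_rand() * twoN);
        if (row >= twoN) row = twoN - 1;
        prow[g] = row;
        par[g] = row / 2;
      }
    }

    // --- crossovers: total count ~ Poisson(2N * r * L), assigned to
    // uniform gametes (equivalent to independent Poisson(r*L) per gamete)
    int n_co_tot = (int) R::rpois(twoN * r_tot);
    if (n_co_tot > 0) {
      std::fill(nco.begin(), nco.end(), 0);
      for (int k = 0; k < n_co_tot; ++k) {
        int g = (int)(unif_rand() * twoN);
        ++nco[g >= twoN ? twoN - 1 : g];
      }
    }

    // --- transmit gametes: bulk copy along the chosen haplotype rows,
    // then patch the (rare) recombinant gametes
    newalle.resize((size_t)M * twoN);
    for (int m = 0; m < M; ++m) {
      const unsigned char *src = alle.data() + (size_t)m * twoN;
      unsigned char *dst = &newalle[(size_t)m * twoN];
      for (int g = 0; g < twoN; ++g) dst[g] = src[prow[g]];
    }
    if (n_co_tot > 0 && M > 0) {
      for (int g = 0; g < twoN; ++g) {
        if (nco[g] == 0) continue;
        bk.resize(nco[g]);
        for (int k = 0; k < nco[g]; ++k) bk[k] = unif_rand() * L;
        std::sort(bk.begin(), bk.end());
        const int row0 = prow[g];
        const int row1 = (row0 % 2 == 0) ? row0 + 1 : row0 - 1;
        for (int m = 0; m < M; ++m) {
          int seg = (int)(std::upper_bound(bk.begin(), bk.end(), pos[m]) -
                          bk.begin());
          if (seg % 2 == 1)
            newalle[(size_t)m * twoN + g] = alle[(size_t)m * twoN + row1];
        }
      }
    }
    std::swap(alle, newalle);

    // --- new mutations
    int nm = (int) R::rpois(mu_tot);
    for (int k = 0; k < nm; ++k) {
      double p = unif_rand() * L;
      alle.resize((size_t)(M + 1) * twoN, 0);
      int carrier = (int)(unif_rand() * twoN);
      alle[(size_t)M * twoN + (carrier >= twoN ? twoN - 1 : carrier)] = 1;
      bool q = false;
      eff.resize((size_t)(M + 1) * n_phen, 0.0);
      if (selecting) {
        double pq = (p >= genic_start && p < genic_end) ? p_qtl_genic
                                                        : p_qtl_nongenic;
        if (unif_rand() < pq) {
          q = true;
          for (int i = 0; i < n_phen; ++i) zz[i] = norm_rand();
          for (int j = 0; j < n_phen; ++j) {
            double s = 0.0;
            for (int i = 0; i <= j; ++i) s += zz[i] * sigma_chol(i, j);
            eff[(size_t)M * n_phen + j] = s;
          }
        }
      }
      pos.push_back(p); qtl.push_back(q);
      ++M;
    }

    // --- purge lost and fixed mutations (fixed QTL fold into base_z)
    {
      int keep = 0;
      for (int m = 0; m < M; ++m) {
        const unsigned char *row = alle.data() + (size_t)m * twoN;
        int cs = 0;
        for (int i = 0; i < twoN; ++i) cs += row[i];
        if (cs == 0) continue;
        if (cs == twoN) {
          if (qtl[m])
            for (int t = 0; t < n_phen; ++t)
              base_z[t] += 2.0 * eff[(size_t)m * n_phen + t];
          continue;
        }
        if (keep != m) {
          std::copy(row, row + twoN, alle.data() + (size_t)keep * twoN);
          std::copy(eff.data() + (size_t)m * n_phen, eff.data() + (size_t)(m + 1) * n_phen,
                    eff.data() + (size_t)keep * n_phen);
          pos[keep] = pos[m]; qtl[keep] = qtl[m];
        }
        ++keep;
      }
      M = keep;
      alle.resize((size_t)M * twoN);
      eff.resize((size_t)M * n_phen);
      pos.resize(M); qtl.resize(M);
    }
    if (gen == burn_in) S_burnin = M;

    // --- phenotypes and fitness (needed from selection onset onwards)
    if (gen >= burn_in) {
      for (int i = 0; i < N; ++i)
        for (int t = 0; t < n_phen; ++t) Z[(size_t)i * n_phen + t] = base_z[t];
      for (int m = 0; m < M; ++m) {
        if (!qtl[m]) continue;
        const unsigned char *row = alle.data() + (size_t)m * twoN;
        const double *e = eff.data() + (size_t)m * n_phen;
        for (int i = 0; i < N; ++i) {
          int d = row[2 * i] + row[2 * i + 1];
          if (d)
            for (int t = 0; t < n_phen; ++t)
              Z[(size_t)i * n_phen + t] += d * e[t];
        }
      }
      // selection weights computed with a shift so they survive underflow
      double min_ss = R_PosInf;
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        for (int t = 0; t < n_phen; ++t) {
          double dz = Z[(size_t)i * n_phen + t] - z0;
          s += dz * dz;
        }
        ss[i] = s;
        if (s < min_ss) min_ss = s;
      }
      for (int i = 0; i < N; ++i)
        w[i] = std::exp(-damp * (ss[i] - min_ss) / (2.0 * Vs));
      have_w = true;
      if (gen == total_gen)          // report true (unshifted) fitness
        for (int i = 0; i < N; ++i)
          w[i] = std::exp(-damp * ss[i] / (2.0 * Vs));
    }
  }

  int n_qtl = 0;
  for (int m = 0; m < M; ++m) if (qtl[m]) ++n_qtl;
  NumericVector mean_phen(n_phen);
  double mw = 0.0;
  for (int i = 0; i < N; ++i) {
    mw += w[i];
    for (int t = 0; t < n_phen; ++t) mean_phen[t] += Z[(size_t)i * n_phen + t];
  }
  mw /= N;
  for (int t = 0; t < n_phen; ++t) mean_phen[t] /= N;
  return List::create(_["mean_fitness"] = mw,
                      _["mean_phenotype"] = mean_phen,
                      _["n_qtl_segregating"] = n_qtl,
                      _["S_burnin"] = S_burnin);
}
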