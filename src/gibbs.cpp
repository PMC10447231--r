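// Dirichlet-process mixture sampler for multi-sample mutation clustering in
// cancer-cell-fraction space.
//
// The R caller precomputes M(i, j, s): the emission log-likelihood of site i
// in sample s if its cluster's CCF sits at grid point j. The emission is a
// beta-binomial with mean expected_vaf(grid_j; purity, CN, multiplicity)
// and configurable overdispersion (rho = 0 gives the plain binomial), so
// the sampler itself is emission-agnostic: assignment and CCF updates are
// table lookups.
//
// Truncated stick-breaking representation. Cluster CCFs move by Metropolis
// steps on the grid (mixture of local and global proposals; their full
// conditionals are evaluated from per-cluster column sums during the
// annealed initialization). Concentration alpha is resampled by the
// Escobar-West auxiliary-variable scheme. Uses R's RNG, so results are
// reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static int sample_cat(const arma::rowvec &logp) {
  arma::rowvec p = arma::exp(logp - logp.max());
  double tot = arma::accu(p);
  double u = unif_rand() * tot, c = 0.0;
  for (arma::uword k = 0; k < p.n_elem; ++k) {
    c += p(k);
    if (u <= c) return (int)k;
  }
  return (int)p.n_elem - 1;
}

// [[Rcpp::export(name = ".gibbs_dp_cpp")]]
List gibbs_dp_cpp(const arma::cube &M, int K, int n_iter, int burn_in,
                  int thin, double alpha_shape, double alpha_rate,
                  int init_sweeps, int mh_steps) {
  RNGScope scope;
  const int N = M.n_rows, J = M.n_cols, S = M.n_slices;

  arma::imat piIdx(K, S);
  for (int k = 0; k < K; ++k)
    for (int s = 0; s < S; ++s)
      piIdx(k, s) = (int)std::floor(unif_rand() * J);
  arma::ivec z(N);
  int K0 = std::min(K, 8);
  for (int i = 0; i < N; ++i) z(i) = (int)std::floor(unif_rand() * K0);
  double alpha = 1.0;
  arma::vec logw(K, arma::fill::value(-std::log((double)K)));

  auto site_ll = [&](int i, int k) {
    double ll = 0.0;
    for (int s = 0; s < S; ++s) ll += M(i, piIdx(k, s), s);
    return ll;
  };

  // per-cluster member lists, rebuilt once per sweep/iteration
  std::vector<std::vector<int>> members(K);
  auto rebuild_members = [&]() {
    for (auto &m : members) m.clear();
    for (int i = 0; i < N; ++i) members[z(i)].push_back(i);
  };

  arma::vec grid_ll(J);
  auto cluster_grid_ll = [&](int k, int s) {
    grid_ll.zeros();
    for (int i : members[k])
      for (int j = 0; j < J; ++j) grid_ll(j) += M(i, j, s);
  };

  // ---- annealed (hard-EM) initialization: monotone classification loglik
  arma::vec init_ll(init_sweeps);
  for (int sweep = 0; sweep < init_sweeps; ++sweep) {
    rebuild_members();
    for (int k = 0; k < K; ++k) {
      if (members[k].empty()) continue;
      for (int s = 0; s < S; ++s) {
        cluster_grid_ll(k, s);
        piIdx(k, s) = (int)grid_ll.index_max();
      }
    }
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      double best = -INFINITY; int bk = 0;
      for (int k = 0; k < K; ++k) {
        double ll = site_ll(i, k);
        if (ll > best) { best = ll; bk = k; }
      }
      z(i) = bk;
      tot += best;
    }
    init_ll(sweep) = tot;
  }

  // ---- Gibbs with Metropolis CCF moves
  int n_keep = 0;
  for (int it = burn_in; it < n_iter; ++it) if ((it - burn_in) % thin == 0) ++n_keep;
  arma::imat draws(n_keep, N);
  arma::vec trace(n_iter), kocc_trace(n_iter);
  int keep = 0;

  arma::ivec nk(K);
  for (int it = 0; it < n_iter; ++it) {
    rebuild_members();
    nk.zeros();
    for (int i = 0; i < N; ++i) nk(z(i)) += 1;

    // CCF updates: per (cluster, sample), mh_steps Metropolis moves over
    // the grid; empty clusters draw fresh positions from the prior
    for (int k = 0; k < K; ++k) {
      if (nk(k) == 0) {
        // refresh empty components half from the prior, half seeded at a
        // random site's per-sample ML position so multi-sample splits can
        // nucleate (k-means++-style data seeding)
        if (unif_rand() < 0.5) {
          for (int s = 0; s < S; ++s)
            piIdx(k, s) = (int)std::floor(unif_rand() * J);
        } else {
          int i = (int)std::floor(unif_rand() * N);
          for (int s = 0; s < S; ++s) {
            double best = -INFINITY; int bj = 0;
            for (int j = 0; j < J; ++j)
              if (M(i, j, s) > best) { best = M(i, j, s); bj = j; }
            piIdx(k, s) = bj;
          }
        }
        continue;
      }
      for (int s = 0; s < S; ++s) {
        int j_cur = piIdx(k, s);
        double ll_cur = 0.0;
        for (int i : members[k]) ll_cur += M(i, j_cur, s);
        for (int m = 0; m < mh_steps; ++m) {
          int j_prop;
          if (unif_rand() < 0.2) {
            j_prop = (int)std::floor(unif_rand() * J);
          } else {
            int step = 1 + (int)std::floor(unif_rand() * 3.0);
            j_prop = j_cur + (unif_rand() < 0.5 ? -step : step);
            if (j_prop < 0 || j_prop >= J) continue;
          }
          double ll_prop = 0.0;
          for (int i : members[k]) ll_prop += M(i, j_prop, s);
          if (std::log(unif_rand()) < ll_prop - ll_cur) {
            j_cur = j_prop; ll_cur = ll_prop;
          }
        }
        piIdx(k, s) = j_cur;
      }
    }

    // assignments
    nk.zeros();
    double tot = 0.0;
    arma::rowvec lp(K);
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < K; ++k) lp(k) = logw(k) + site_ll(i, k);
      int k = sample_cat(lp);
      z(i) = k; nk(k) += 1;
      tot += lp(k) - logw(k);
    }
    trace(it) = tot;

    // stick-breaking weights
    double rest = 0.0;
    arma::vec tail(K);
    for (int k = K - 1; k >= 0; --k) { tail(k) = rest; rest += nk(k); }
    double log_remain = 0.0;
    for (int k = 0; k < K; ++k) {
      if (k == K - 1) { logw(k) = log_remain; break; }
      double b = R::rbeta(1.0 + nk(k), alpha + tail(k));
      b = std::min(std::max(b, 1e-12), 1.0 - 1e-12);
      logw(k) = log_remain + std::log(b);
      log_remain += std::log1p(-b);
    }

    // concentration (Escobar & West 1995)
    int kOcc = 0;
    for (int k = 0; k < K; ++k) if (nk(k) > 0) ++kOcc;
    kocc_trace(it) = kOcc;
    double eta = R::rbeta(alpha + 1.0, (double)N);
    double rate = alpha_rate - std::log(eta);
    double odds = (alpha_shape + kOcc - 1.0) / ((double)N * rate);
    double pi_eta = odds / (1.0 + odds);
    if (unif_rand() < pi_eta)
      alpha = R::rgamma(alpha_shape + kOcc, 1.0 / rate);
    else
      alpha = R::rgamma(alpha_shape + kOcc - 1.0, 1.0 / rate);

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int i = 0; i < N; ++i) draws(keep, i) = z(i);
      ++keep;
    }
  }

  return List::create(_["draws"] = draws, _["pi_idx"] = piIdx,
                      _["loglik"] = trace, _["init_loglik"] = init_ll,
                      _["k_occupied"] = kocc_trace, _["alpha"] = alpha);
}

// Posterior similarity matrix from assignment draws (n_keep x N).
// [[Rcpp::export(name = ".psm_cpp")]]
arma::mat psm_cpp(const arma::imat &draws) {
  const int R = draws.n_rows, N = draws.n_cols;
  arma::mat psm(N, N, arma::fill::zeros);
  std::vector<std::vector<int>> buckets;
  for (int r = 0; r < R; ++r) {
    int K = draws.row(r).max() + 1;
    buckets.assign(K, {});
    for (int i = 0; i < N; ++i) buckets[draws(r, i)].push_back(i);
    for (auto &b : buckets)
      for (size_t a = 0; a < b.size(); ++a)
        for (size_t c = a; c < b.size(); ++c) {
          psm(b[a], b[c]) += 1.0;
        }
  }
  psm /= (double)R;
  psm = arma::symmatu(psm);
  psm.diag().ones();
  return psm;
}
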