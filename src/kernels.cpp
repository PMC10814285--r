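#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Discrepancy codes: 0 = squared Euclidean (mean centers),
//                    1 = Manhattan (componentwise lower-median centers).

namespace {

// Center of a member set under the configured rule. Lower median: the
// ((n+1)/2)-th order statistic, deterministic for even cluster sizes.
void rule_center(const NumericMatrix& U, const std::vector<int>& mem,
                 const int loss, std::vector<double>& cen) {
  const int d = U.ncol();
  const int n = (int)mem.size();
  cen.assign(d, 0.0);
  if (n == 0) return;
  if (loss == 0) {
    for (int j = 0; j < d; ++j) {
      double s = 0.0;
      for (int q = 0; q < n; ++q) s += U(mem[q], j);
      cen[j] = s / n;
    }
  } else {
    std::vector<double> v(n);
    const int k = (n - 1) / 2;  // lower median, 0-indexed
    for (int j = 0; j < d; ++j) {
      for (int q = 0; q < n; ++q) v[q] = U(mem[q], j);
      std::nth_element(v.begin(), v.begin() + k, v.end());
      cen[j] = v[k];
    }
  }
}

double discrepancy(const NumericMatrix& U, const int i,
                   const std::vector<double>& cen, const int loss) {
  const int d = U.ncol();
  double s = 0.0;
  if (loss == 0) {
    for (int j = 0; j < d; ++j) { const double e = U(i, j) - cen[j]; s += e * e; }
  } else {
    for (int j = 0; j < d; ++j) s += std::abs(U(i, j) - cen[j]);
  }
  return s;
}

// Sum of discrepancies of a member set from its rule center.
double cluster_term(const NumericMatrix& U, const std::vector<int>& mem,
                    const int loss) {
  if (mem.empty()) return 0.0;
  std::vector<double> cen;
  rule_center(U, mem, loss, cen);
  double s = 0.0;
  for (size_t q = 0; q < mem.size(); ++q) s += discrepancy(U, mem[q], cen, loss);
  return s;
}

double total_loss(const NumericMatrix& U,
                  const std::vector<std::vector<int> >& mem, const int loss) {
  double s = 0.0;
  for (size_t k = 0; k < mem.size(); ++k) s += cluster_term(U, mem[k], loss);
  return s;
}

void build_membership(const std::vector<int>& lab, const int K,
                      std::vector<std::vector<int> >& mem) {
  mem.assign(K, std::vector<int>());
  for (size_t i = 0; i < lab.size(); ++i) mem[lab[i]].push_back((int)i);
}

void erase_member(std::vector<int>& v, const int i) {
  v.erase(std::find(v.begin(), v.end(), i));
}

// One full-conditional reallocation sweep (sequential or random-scan order).
// Singleton units must stay put: the uniform prior has support only on
// partitions with exactly K blocks.
void do_sweep(std::vector<int>& lab, std::vector<std::vector<int> >& mem,
              const NumericMatrix& U, const int K, const double lambda,
              const int loss, const bool random_scan) {
  const int m = (int)lab.size();
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  if (random_scan) {
    for (int i = m - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
  }
  std::vector<double> delta(K), w(K);
  for (int q = 0; q < m; ++q) {
    const int i = order[q];
    const int k0 = lab[i];
    if (mem[k0].size() == 1) continue;  // must keep K nonempty blocks
    erase_member(mem[k0], i);
    double dmin = R_PosInf;
    for (int k = 0; k < K; ++k) {
      const double t_minus = cluster_term(U, mem[k], loss);
      mem[k].push_back(i);
      const double t_plus = cluster_term(U, mem[k], loss);
      mem[k].pop_back();
      delta[k] = t_plus - t_minus;
      if (delta[k] < dmin) dmin = delta[k];
    }
    double tot = 0.0;
    for (int k = 0; k < K; ++k) { w[k] = std::exp(-lambda * (delta[k] - dmin)); tot += w[k]; }
    const double u = unif_rand() * tot;
    double acc = 0.0;
    int knew = K - 1;
    for (int k = 0; k < K; ++k) { acc += w[k]; if (u <= acc) { knew = k; break; } }
    lab[i] = knew;
    mem[knew].push_back(i);
  }
}

// Fairlet centers induced by an owner vector: u_i = (x1_i + sum of owned x2_j)/(t+1).
void fairlet_centers(const NumericMatrix& X1, const NumericMatrix& X2,
                     const std::vector<int>& owner, const int t,
                     NumericMatrix& U) {
  const int n1 = X1.nrow(), d = X1.ncol();
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < d; ++j) U(i, j) = X1(i, j);
  for (size_t jj = 0; jj < owner.size(); ++jj)
    for (int j = 0; j < d; ++j) U(owner[jj], j) += X2((int)jj, j);
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < d; ++j) U(i, j) /= (t + 1);
}

}  // namespace

// [[Rcpp::export]]
double cpp_cluster_loss(IntegerVector labels, NumericMatrix U, int K, int loss) {
  std::vector<int> lab(labels.size());
  for (int i = 0; i < labels.size(); ++i) lab[i] = labels[i] - 1;
  std::vector<std::vector<int> > mem;
  build_membership(lab, K, mem);
  return total_loss(U, mem, loss);
}

// [[Rcpp::export]]
IntegerVector cpp_gibbs_sweep(IntegerVector labels, NumericMatrix U, int K,
                              double lambda, int loss, bool random_scan) {
  std::vector<int> lab(labels.size());
  for (int i = 0; i < labels.size(); ++i) lab[i] = labels[i] - 1;
  std::vector<std::vector<int> > mem;
  build_membership(lab, K, mem);
  do_sweep(lab, mem, U, K, lambda, loss, random_scan);
  IntegerVector out(labels.size());
  for (int i = 0; i < labels.size(); ++i) out[i] = lab[i] + 1;
  return out;
}

// [[Rcpp::export]]
List cpp_sweep_chain(IntegerVector labels, NumericMatrix U, int K,
                     double lambda, int loss, int n_sweeps, int burn, int thin,
                     bool random_scan) {
  std::vector<int> lab(labels.size());
  for (int i = 0; i < labels.size(); ++i) lab[i] = labels[i] - 1;
  std::vector<std::vector<int> > mem;
  build_membership(lab, K, mem);
  const int m = (int)lab.size();
  const int T = (n_sweeps - burn + thin - 1) / thin;
  IntegerMatrix draws(T > 0 ? T : 0, m);
  NumericVector loss_trace(T > 0 ? T : 0);
  int s = 0;
  for (int it = 0; it < n_sweeps; ++it) {
    do_sweep(lab, mem, U, K, lambda, loss, random_scan);
    if (it >= burn && ((it - burn) % thin == 0)) {
      for (int i = 0; i < m; ++i) draws(s, i) = lab[i] + 1;
      loss_trace[s] = total_loss(U, mem, loss);
      ++s;
    }
  }
  return List::create(_["draws"] = draws, _["loss"] = loss_trace);
}

// Weighted rectangular-loop chain over fixed-margin binary matrices, encoded
// by the owner vector (row index holding the single 1 of each column; row
// sums t are conserved automatically by checkerboard swaps). Targets
// P(H) proportional to the product of w at occupied cells.
// [[Rcpp::export]]
List cpp_wrla_chain(IntegerVector owner, NumericMatrix logW, int n_steps,
                    int burn, int thin, bool store) {
  const int n1 = logW.nrow();
  const int n2 = logW.ncol();
  std::vector<int> own(owner.size());
  for (int j = 0; j < owner.size(); ++j) own[j] = owner[j] - 1;
  int n_acc = 0, n_cb = 0;
  const int T = store ? (n_steps - burn + thin - 1) / thin : 0;
  IntegerMatrix draws(T, store ? n2 : 0);
  int s = 0;
  for (int it = 0; it < n_steps; ++it) {
    if (n1 >= 2 && n2 >= 2) {
      int i1 = (int)std::floor(unif_rand() * n1); if (i1 >= n1) i1 = n1 - 1;
      int i2 = (int)std::floor(unif_rand() * (n1 - 1)); if (i2 >= n1 - 1) i2 = n1 - 2;
      if (i2 >= i1) ++i2;
      int j1 = (int)std::floor(unif_rand() * n2); if (j1 >= n2) j1 = n2 - 1;
      int j2 = (int)std::floor(unif_rand() * (n2 - 1)); if (j2 >= n2 - 1) j2 = n2 - 2;
      if (j2 >= j1) ++j2;
      const int o1 = own[j1], o2 = own[j2];
      const bool cb = (o1 == i1 && o2 == i2) || (o1 == i2 && o2 == i1);
      if (cb) {
        ++n_cb;
        // proposed: column j1 -> o2, column j2 -> o1
        const double dlog = logW(o2, j1) + logW(o1, j2)
                          - logW(o1, j1) - logW(o2, j2);
        if (dlog >= 0.0 || std::log(unif_rand()) < dlog) {
          own[j1] = o2; own[j2] = o1; ++n_acc;
        }
      }
    }
    if (store && it >= burn && ((it - burn) % thin == 0)) {
      for (int j = 0; j < n2; ++j) draws(s, j) = own[j] + 1;
      ++s;
    }
  }
  IntegerVector fin(own.size());
  for (size_t j = 0; j < own.size(); ++j) fin[j] = own[j] + 1;
  return List::create(_["owner"] = fin, _["draws"] = draws,
                      _["n_accept"] = n_acc, _["n_checkerboard"] = n_cb);
}

// Joint Metropolis-within-Gibbs over (B, C). Each outer iteration makes
// inner_steps checkerboard proposals on B -- accepted with the product-weight
// ratio times exp(-lambda_c * change in clustering loss), the exact full
// conditional of B given C -- then one label sweep given the induced fairlet
// centers. With update_B = false the decomposition stays fixed (MC-EM).
// [[Rcpp::export]]
List cpp_joint_mcmc(NumericMatrix X1, NumericMatrix X2, IntegerVector owner0,
                    IntegerVector labels0, NumericMatrix L, double lambda_f,
                    double lambda_c, int K, int loss, int t, int inner_steps,
                    int n_iter, int burn, int thin, bool update_B,
                    bool random_scan) {
  const int n1 = X1.nrow();
  const int n2 = X2.nrow();
  const int d = X1.ncol();
  std::vector<int> own(owner0.size());
  for (int j = 0; j < owner0.size(); ++j) own[j] = owner0[j] - 1;
  std::vector<int> lab(labels0.size());
  for (int i = 0; i < labels0.size(); ++i) lab[i] = labels0[i] - 1;
  std::vector<std::vector<int> > mem;
  build_membership(lab, K, mem);
  NumericMatrix U(n1, d);
  fairlet_centers(X1, X2, own, t, U);

  const int T = (n_iter - burn + thin - 1) / thin;
  IntegerMatrix lab_draws(T, n1);
  IntegerMatrix own_draws(T, n2);
  NumericVector lf_trace(T), lc_trace(T), logj_trace(T);
  int n_acc = 0, n_cb = 0, s = 0;
  std::vector<double> u1_old(d), u2_old(d);

  for (int it = 0; it < n_iter; ++it) {
    if (update_B && n1 >= 2 && n2 >= 2) {
      for (int step = 0; step < inner_steps; ++step) {
        int i1 = (int)std::floor(unif_rand() * n1); if (i1 >= n1) i1 = n1 - 1;
        int i2 = (int)std::floor(unif_rand() * (n1 - 1)); if (i2 >= n1 - 1) i2 = n1 - 2;
        if (i2 >= i1) ++i2;
        int j1 = (int)std::floor(unif_rand() * n2); if (j1 >= n2) j1 = n2 - 1;
        int j2 = (int)std::floor(unif_rand() * (n2 - 1)); if (j2 >= n2 - 1) j2 = n2 - 2;
        if (j2 >= j1) ++j2;
        const int o1 = own[j1], o2 = own[j2];
        if (!((o1 == i1 && o2 == i2) || (o1 == i2 && o2 == i1))) continue;
        ++n_cb;
        double dlog = -lambda_f * (L(o2, j1) + L(o1, j2) - L(o1, j1) - L(o2, j2));
        const int k1 = lab[o1], k2 = lab[o2];
        double term_old = cluster_term(U, mem[k1], loss);
        if (k2 != k1) term_old += cluster_term(U, mem[k2], loss);
        // fairlets o1 and o2 exchange one label-2 member each
        for (int j = 0; j < d; ++j) {
          u1_old[j] = U(o1, j); u2_old[j] = U(o2, j);
          U(o1, j) += (X2(j2, j) - X2(j1, j)) / (t + 1);
          U(o2, j) += (X2(j1, j) - X2(j2, j)) / (t + 1);
        }
        double term_new = cluster_term(U, mem[k1], loss);
        if (k2 != k1) term_new += cluster_term(U, mem[k2], loss);
        dlog += -lambda_c * (term_new - term_old);
        if (dlog >= 0.0 || std::log(unif_rand()) < dlog) {
          own[j1] = o2; own[j2] = o1; ++n_acc;
        } else {
          for (int j = 0; j < d; ++j) { U(o1, j) = u1_old[j]; U(o2, j) = u2_old[j]; }
        }
      }
    }
    do_sweep(lab, mem, U, K, lambda_c, loss, random_scan);
    if (it >= burn && ((it - burn) % thin == 0)) {
      double lf = 0.0;
      for (int j = 0; j < n2; ++j) lf += L(own[j], j);
      const double lc = total_loss(U, mem, loss);
      for (int i = 0; i < n1; ++i) lab_draws(s, i) = lab[i] + 1;
      for (int j = 0; j < n2; ++j) own_draws(s, j) = own[j] + 1;
      lf_trace[s] = lf;
      lc_trace[s] = lc;
      logj_trace[s] = -lambda_f * lf - lambda_c * lc;
      ++s;
    }
  }
  return List::create(_["labels"] = lab_draws, _["owners"] = own_draws,
                      _["Lf"] = lf_trace, _["Lc"] = lc_trace,
                      _["log_joint"] = logj_trace,
                      _["n_accept"] = n_acc, _["n_checkerboard"] = n_cb);
}
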