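// Core numerics for Potts models over sequences of pairs of repeats.
//
// Conventions shared with the R layer:
//   - symbols are 0-based integers in [0, q); index q-1 is the gap when q = 21
//   - h is a q x n matrix (one column per site), n = 2L sites
//   - pairs is an m x 2 integer matrix of 0-based site indices, i < j
//   - J is a flat vector of length m*q*q; J[p*q*q + a*q + b] couples
//     symbol a at site pairs(p,0) with symbol b at site pairs(p,1)
//   - lambda has length L+1 and is indexed by the repeat-overlap statistic
//     ID(sigma) = #{ i in [0,L) : sigma[i] == sigma[i+L] }
//   - the interpolated energy is E_alpha = -sum_i h + alpha * (-sum_p J + lambda[ID])
//
// All randomness goes through R's RNG so set.seed() in R governs everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Adj {
  // for each site: indices of incident pairs, the partner site, and whether
  // the site is the first member of the pair
  std::vector<std::vector<int>> pair_idx;
  std::vector<std::vector<int>> partner;
  std::vector<std::vector<bool>> is_first;
};

Adj build_adj(const IntegerMatrix& pairs, int n) {
  Adj a;
  a.pair_idx.resize(n);
  a.partner.resize(n);
  a.is_first.resize(n);
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0), j = pairs(p, 1);
    a.pair_idx[i].push_back(p); a.partner[i].push_back(j); a.is_first[i].push_back(true);
    a.pair_idx[j].push_back(p); a.partner[j].push_back(i); a.is_first[j].push_back(false);
  }
  return a;
}

inline int overlap_id(const std::vector<int>& s, int Lhalf) {
  int id = 0;
  for (int i = 0; i < Lhalf; ++i) if (s[i] == s[i + Lhalf]) ++id;
  return id;
}

inline double pair_sum(const std::vector<int>& s, const IntegerMatrix& pairs,
                       const NumericVector& J, int q) {
  double tot = 0.0;
  const int qq = q * q;
  for (int p = 0; p < pairs.nrow(); ++p)
    tot += J[p * qq + s[pairs(p, 0)] * q + s[pairs(p, 1)]];
  return tot;
}

inline double field_sum(const std::vector<int>& s, const NumericMatrix& h) {
  double tot = 0.0;
  for (int i = 0; i < (int)s.size(); ++i) tot += h(s[i], i);
  return tot;
}

double energy_of(const std::vector<int>& s, const NumericMatrix& h,
                 const IntegerMatrix& pairs, const NumericVector& J,
                 const NumericVector& lambda, double alpha, int Lhalf, int q) {
  double e = -field_sum(s, h);
  double inter = -pair_sum(s, pairs, J, q);
  if (lambda.size() > 0) inter += lambda[overlap_id(s, Lhalf)];
  return e + alpha * inter;
}

// change in -sum J if site flips a -> b, given current sequence
inline double coupling_delta(const std::vector<int>& s, int site, int a, int b,
                             const Adj& adj, const NumericVector& J, int q) {
  double d = 0.0;
  const int qq = q * q;
  const std::vector<int>& pidx = adj.pair_idx[site];
  const std::vector<int>& prt = adj.partner[site];
  const std::vector<bool>& fst = adj.is_first[site];
  for (size_t k = 0; k < pidx.size(); ++k) {
    int p = pidx[k], other = s[prt[k]];
    const double* Jp = &J[p * qq];
    if (fst[k]) d -= Jp[b * q + other] - Jp[a * q + other];
    else        d -= Jp[other * q + b] - Jp[other * q + a];
  }
  return d;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_energy(const IntegerMatrix& seqs, const NumericMatrix& h,
                         const IntegerMatrix& pairs, const NumericVector& J,
                         const NumericVector& lambda, double alpha, int Lhalf) {
  const int N = seqs.nrow(), n = seqs.ncol(), q = h.nrow();
  NumericVector out(N);
  std::vector<int> s(n);
  for (int r = 0; r < N; ++r) {
    for (int i = 0; i < n; ++i) s[i] = seqs(r, i);
    out[r] = energy_of(s, h, pairs, J, lambda, alpha, Lhalf, q);
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_metropolis(const NumericMatrix& h, const IntegerMatrix& pairs,
                             const NumericVector& J, const NumericVector& lambda,
                             double alpha, int Lhalf, int n_samples, int thinning,
                             int burn_in, IntegerVector init) {
  const int q = h.nrow(), n = h.ncol(), m = pairs.nrow();
  const bool use_lambda = lambda.size() > 0;
  const double* hp = &h(0, 0);
  const double* Jp = (m > 0) ? &J[0] : nullptr;
  const double* lam = use_lambda ? &lambda[0] : nullptr;
  const int qq = q * q;

  // CSR adjacency: for each site, (J block offset, partner site, row stride)
  // so that the coupling of (site = a, partner = c) reads base[a * stride_a],
  // with the partner's contribution folded into the offset at use time.
  std::vector<int> deg(n, 0);
  for (int p = 0; p < m; ++p) { ++deg[pairs(p, 0)]; ++deg[pairs(p, 1)]; }
  std::vector<int> off(n + 1, 0);
  for (int i = 0; i < n; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> a_block(m * 2), a_partner(m * 2), a_stride(m * 2);
  {
    std::vector<int> cur(off.begin(), off.end() - 1);
    for (int p = 0; p < m; ++p) {
      int i = pairs(p, 0), j = pairs(p, 1);
      a_block[cur[i]] = p * qq; a_partner[cur[i]] = j; a_stride[cur[i]] = q; ++cur[i];
      a_block[cur[j]] = p * qq; a_partner[cur[j]] = i; a_stride[cur[j]] = 1; ++cur[j];
    }
  }

  std::vector<int> s(n);
  if (init.size() == n) {
    for (int i = 0; i < n; ++i) s[i] = init[i];
  } else {
    for (int i = 0; i < n; ++i) { int v = (int)(unif_rand() * q); s[i] = v < q ? v : q - 1; }
  }
  int id = overlap_id(s, Lhalf);

  IntegerMatrix out(n_samples, n);
  int* outp = &out(0, 0);
  long long total = (long long)burn_in + (long long)n_samples * thinning;
  int kept = 0;
  for (long long step = 1; step <= total && kept < n_samples; ++step) {
    int site = (int)(unif_rand() * n); if (site >= n) site = n - 1;
    int a = s[site];
    int b = (int)(unif_rand() * (q - 1)); if (b >= q - 1) b = q - 2;
    if (b >= a) ++b;

    const double* hcol = hp + (size_t)site * q;
    double dE = -(hcol[b] - hcol[a]);
    double dInter = 0.0;
    for (int k = off[site]; k < off[site + 1]; ++k) {
      // partner symbol contributes with the complementary stride
      const int other = s[a_partner[k]];
      const int st = a_stride[k];
      const int ot = (st == q) ? 1 : q;
      const double* base = Jp + a_block[k] + other * ot;
      dInter -= base[(size_t)b * st] - base[(size_t)a * st];
    }
    int id_new = id;
    if (use_lambda) {
      int hom = (site < Lhalf) ? site + Lhalf : site - Lhalf;
      id_new += (b == s[hom]) - (a == s[hom]);
      dInter += lam[id_new] - lam[id];
    }
    double d = dE + alpha * dInter;
    if (d <= 0.0 || unif_rand() < std::exp(-d)) {
      s[site] = b;
      id = id_new;
    }

    if (step > burn_in && (step - burn_in) % thinning == 0) {
      for (int i = 0; i < n; ++i) outp[(size_t)i * n_samples + kept] = s[i];
      ++kept;
    }
  }
  return out;
}

// Zero-temperature quench: repeatedly pick uniformly among strictly
// energy-decreasing moves (single-site substitutions, plus synchronized
// double substitutions on homologous positions carrying the same symbol).
// lambda is deliberately absent: quenches run with the overlap term off.
// [[Rcpp::export]]
List cpp_quench(const NumericMatrix& h, const IntegerMatrix& pairs,
                const NumericVector& J, IntegerVector start, int Lhalf,
                bool allow_paired_double) {
  const int q = h.nrow(), n = h.ncol();
  Adj adj = build_adj(pairs, n);
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = start[i];

  std::vector<int> m_site1, m_site2, m_sym;
  std::vector<double> m_dE;
  int steps = 0;
  NumericVector no_lambda(0);

  for (;;) {
    m_site1.clear(); m_site2.clear(); m_sym.clear(); m_dE.clear();
    // single mutations
    for (int site = 0; site < n; ++site) {
      int a = s[site];
      for (int b = 0; b < q; ++b) {
        if (b == a) continue;
        double dE = -(h(b, site) - h(a, site)) + coupling_delta(s, site, a, b, adj, J, q);
        if (dE < 0.0) {
          m_site1.push_back(site); m_site2.push_back(-1); m_sym.push_back(b); m_dE.push_back(dE);
        }
      }
    }
    // synchronized double mutations on matching homologous positions
    if (allow_paired_double) {
      for (int i = 0; i < Lhalf; ++i) {
        int jte = i + Lhalf;
        if (s[i] != s[jte]) continue;
        int a = s[i];
        for (int b = 0; b < q; ++b) {
          if (b == a) continue;
          double d1 = -(h(b, i) - h(a, i)) + coupling_delta(s, i, a, b, adj, J, q);
          s[i] = b; // apply first half temporarily for an exact joint delta
          double d2 = -(h(b, jte) - h(a, jte)) + coupling_delta(s, jte, a, b, adj, J, q);
          s[i] = a;
          double dE = d1 + d2;
          if (dE < 0.0) {
            m_site1.push_back(i); m_site2.push_back(jte); m_sym.push_back(b); m_dE.push_back(dE);
          }
        }
      }
    }
    if (m_dE.empty()) break;
    int pick = (int)std::floor(unif_rand() * m_dE.size());
    if (pick == (int)m_dE.size()) pick = m_dE.size() - 1;
    s[m_site1[pick]] = m_sym[pick];
    if (m_site2[pick] >= 0) s[m_site2[pick]] = m_sym[pick];
    ++steps;
  }

  IntegerVector mini(n);
  for (int i = 0; i < n; ++i) mini[i] = s[i];
  double E = energy_of(s, h, pairs, J, no_lambda, 1.0, Lhalf, q);
  return List::create(_["minimum"] = mini, _["E_min"] = E, _["n_steps"] = steps);
}

// [[Rcpp::export]]
List cpp_observables(const IntegerMatrix& seqs, const NumericVector& w,
                     const IntegerMatrix& pairs, int q, int Lhalf) {
  const int N = seqs.nrow(), n = seqs.ncol(), m = pairs.nrow();
  NumericMatrix f1(q, n);
  NumericVector f2((R_xlen_t)m * q * q);
  NumericVector pid(Lhalf + 1);
  double wtot = 0.0;
  const int qq = q * q;
  for (int r = 0; r < N; ++r) {
    double wr = w[r];
    wtot += wr;
    for (int i = 0; i < n; ++i) f1(seqs(r, i), i) += wr;
    for (int p = 0; p < m; ++p)
      f2[(R_xlen_t)p * qq + seqs(r, pairs(p, 0)) * q + seqs(r, pairs(p, 1))] += wr;
    int id = 0;
    for (int i = 0; i < Lhalf; ++i) if (seqs(r, i) == seqs(r, i + Lhalf)) ++id;
    pid[id] += wr;
  }
  for (R_xlen_t k = 0; k < f1.size(); ++k) f1[k] /= wtot;
  for (R_xlen_t k = 0; k < f2.size(); ++k) f2[k] /= wtot;
  for (int k = 0; k <= Lhalf; ++k) pid[k] /= wtot;
  return List::create(_["f1"] = f1, _["f2"] = f2, _["pid"] = pid, _["w_total"] = wtot);
}

// Exact enumeration of all q^n states: partition function, mean energy,
// Shannon entropy, and (optionally) exact observables / per-state energies.
// [[Rcpp::export]]
List cpp_enumerate(const NumericMatrix& h, const IntegerMatrix& pairs,
                   const NumericVector& J, const NumericVector& lambda,
                   double alpha, int Lhalf, bool want_obs, bool want_energies) {
  const int q = h.nrow(), n = h.ncol(), m = pairs.nrow();
  double nstates_d = std::pow((double)q, n);
  if (nstates_d > 2e7) stop("state space too large for enumeration");
  const R_xlen_t nstates = (R_xlen_t)std::llround(nstates_d);

  std::vector<double> E(nstates);
  std::vector<int> s(n, 0);
  double Emin = R_PosInf;
  for (R_xlen_t k = 0; k < nstates; ++k) {
    double e = energy_of(s, h, pairs, J, lambda, alpha, Lhalf, q);
    E[k] = e;
    if (e < Emin) Emin = e;
    // odometer increment, site 0 fastest
    for (int i = 0; i < n; ++i) { if (++s[i] < q) break; s[i] = 0; }
  }
  double Zs = 0.0;
  for (R_xlen_t k = 0; k < nstates; ++k) Zs += std::exp(-(E[k] - Emin));
  double logZ = -Emin + std::log(Zs);
  double meanE = 0.0;
  for (R_xlen_t k = 0; k < nstates; ++k) meanE += E[k] * std::exp(-E[k] - logZ);
  double S = meanE + logZ; // S = <E> - F, F = -log Z

  List out = List::create(_["logZ"] = logZ, _["mean_E"] = meanE, _["S_nats"] = S);
  if (want_obs) {
    NumericMatrix f1(q, n);
    NumericVector f2((R_xlen_t)m * q * q);
    NumericVector pid(Lhalf + 1);
    const int qq = q * q;
    std::fill(s.begin(), s.end(), 0);
    for (R_xlen_t k = 0; k < nstates; ++k) {
      double p = std::exp(-E[k] - logZ);
      for (int i = 0; i < n; ++i) f1(s[i], i) += p;
      for (int pp = 0; pp < m; ++pp)
        f2[(R_xlen_t)pp * qq + s[pairs(pp, 0)] * q + s[pairs(pp, 1)]] += p;
      pid[overlap_id(s, Lhalf)] += p;
      for (int i = 0; i < n; ++i) { if (++s[i] < q) break; s[i] = 0; }
    }
    out["f1"] = f1; out["f2"] = f2; out["pid"] = pid;
  }
  if (want_energies) out["energies"] = NumericVector(E.begin(), E.end());
  return out;
}

// Greedy incremental identity clustering (CD-HIT-like reweighting):
// a sequence joins the first earlier cluster whose representative shares
// >= thr identical columns (fraction over all columns, gaps included).
// [[Rcpp::export]]
IntegerVector cpp_cluster_greedy(const IntegerMatrix& seqs, double thr) {
  const int N = seqs.nrow(), n = seqs.ncol();
  std::vector<int> reps;
  IntegerVector cl(N);
  for (int r = 0; r < N; ++r) {
    int assigned = 0;
    for (size_t c = 0; c < reps.size(); ++c) {
      int rep = reps[c], match = 0;
      for (int i = 0; i < n; ++i) if (seqs(r, i) == seqs(rep, i)) ++match;
      if ((double)match / n >= thr) { assigned = (int)c + 1; break; }
    }
    if (!assigned) { reps.push_back(r); assigned = (int)reps.size(); }
    cl[r] = assigned;
  }
  return cl;
}
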