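// Structured coalescent for a three-population divergence model with
// epoch-restricted migration, per-lineage size changes and per-locus
// rescaling of Ne / migration (linked-selection heterogeneity).
//
// Populations (backward in time):
//   0 = P1, 1 = P2, 2 = P3           on [0, Ts12)
//   3 = ancestor of P1/P2, 2 = P3    on [Ts12, Ts123)
//   4 = root                         on [Ts123, inf)
// Sizes are diploid individuals: pairwise coalescence rate 1/(2N) per
// generation; a scaled migration rate M (4Nm units) between demes a,b gives
// a per-lineage backward move rate M/(4*N_a) out of deme a.
// All randomness comes from R's RNG (unif_rand/exp_rand/rpois), so seeding
// is done with set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Dem {
  double N[3], Nf[3], Tc[3];
  double Nanc12, Nanc123, Ts12, Ts123;
  double M12, M13, M23, t12lo, t12hi;
  double fNe, fM;

  // epoch boundaries belong to the older (larger t) epoch: t >= Tc -> founder
  double rawsize(int p, double t) const {
    double n;
    if (p < 3) n = (t >= Tc[p]) ? Nf[p] : N[p];
    else if (p == 3) n = Nanc12;
    else n = Nanc123;
    return n;
  }
  // linked-selection Ne rescaling applies to drift (coalescence) only; the
  // scaled migration rate M = 4Nm is converted with the deme's unscaled
  // size, so a low-Ne locus does not see inflated gene flow (effective
  // migration has its own per-locus factor fM)
  double popsize(int p, double t) const { return rawsize(p, t) * fNe; }

  // scaled migration (4Nm units) between demes a and b at time t
  double mpair(int a, int b, double t) const {
    if (a > b) std::swap(a, b);
    double m = 0.0;
    if (t < Ts12) {
      if (a == 0 && b == 1) { if (t >= t12lo && t < t12hi) m = M12; }
      else if (a == 0 && b == 2) m = M13;
      else if (a == 1 && b == 2) m = M23;
    } else if (t < Ts123) {
      if (a == 2 && b == 3) m = M13 + M23;
    }
    return m * fM;
  }
};

// dem vector layout (see .pack_demography in R/coalsim.R)
Dem unpack(const NumericVector& d, double fNe, double fM) {
  Dem m;
  m.N[0] = d[0];  m.N[1] = d[1];  m.N[2] = d[2];
  m.Nf[0] = d[3]; m.Nf[1] = d[4]; m.Nf[2] = d[5];
  m.Tc[0] = d[6]; m.Tc[1] = d[7]; m.Tc[2] = d[8];
  m.Nanc12 = d[9]; m.Nanc123 = d[10];
  m.Ts12 = d[11]; m.Ts123 = d[12];
  m.M12 = d[13]; m.M13 = d[14]; m.M23 = d[15];
  m.t12lo = d[16]; m.t12hi = d[17];
  m.fNe = (fNe > 0.0) ? fNe : 1e-12;
  m.fM = fM;
  return m;
}

struct Genealogy {
  std::vector<int> parent;   // -1 for root
  std::vector<double> time;  // generations before present
  int ntip;
};

// which demes can receive a migrant at time t
inline void demes_at(const Dem& d, double t, int* demes, int& nd) {
  if (t < d.Ts12) { demes[0] = 0; demes[1] = 1; demes[2] = 2; nd = 3; }
  else if (t < d.Ts123) { demes[0] = 2; demes[1] = 3; nd = 2; }
  else { demes[0] = 4; nd = 1; }
}

Genealogy simulate_core(const Dem& dem, int n1, int n2, int n3) {
  const int n = n1 + n2 + n3;
  const int ntot = 2 * n - 1;
  Genealogy g;
  g.ntip = n;
  g.parent.assign(ntot, -1);
  g.time.assign(ntot, 0.0);

  std::vector<int> act(n), lpop(n);
  for (int i = 0; i < n; i++) {
    act[i] = i;
    lpop[i] = (i < n1) ? 0 : (i < n1 + n2 ? 1 : 2);
  }

  std::vector<double> bnd = {dem.Tc[0], dem.Tc[1], dem.Tc[2],
                             dem.t12lo, dem.t12hi, dem.Ts12, dem.Ts123};
  std::sort(bnd.begin(), bnd.end());
  bnd.erase(std::unique(bnd.begin(), bnd.end()), bnd.end());

  int nact = n, nextnode = n;
  double t = 0.0;
  size_t bi = 0;

  // degenerate split times at (or before) the present: merge immediately
  if (dem.Ts12 <= 0.0)
    for (int i = 0; i < nact; i++) if (lpop[i] <= 1) lpop[i] = 3;
  if (dem.Ts123 <= 0.0)
    for (int i = 0; i < nact; i++) if (lpop[i] == 2 || lpop[i] == 3) lpop[i] = 4;
  while (bi < bnd.size() && bnd[bi] <= 0.0) bi++;

  int k[5];
  double Np[5], coal[5], migl[5];  // migl = per-lineage out-rate from deme p

  while (nact > 1) {
    const double tnext = (bi < bnd.size()) ? bnd[bi] : R_PosInf;

    for (int p = 0; p < 5; p++) { k[p] = 0; coal[p] = 0.0; migl[p] = 0.0; }
    for (int i = 0; i < nact; i++) k[lpop[i]]++;

    int demes[3], nd;
    demes_at(dem, t, demes, nd);

    double total = 0.0;
    for (int di = 0; di < nd; di++) {
      const int p = demes[di];
      if (k[p] == 0) continue;
      Np[p] = dem.popsize(p, t);
      if (k[p] >= 2) {
        coal[p] = k[p] * (k[p] - 1) / 2.0 / (2.0 * Np[p]);
        total += coal[p];
      }
      double r = 0.0;
      for (int dj = 0; dj < nd; dj++) {
        const int q = demes[dj];
        if (q == p) continue;
        r += dem.mpair(p, q, t) / (4.0 * dem.rawsize(p, t));
      }
      migl[p] = r;
      total += k[p] * r;
    }

    bool advance = (total <= 0.0);
    double dt = 0.0;
    if (!advance) {
      dt = R::exp_rand() / total;
      advance = (t + dt >= tnext);
    }

    if (advance) {
      if (!std::isfinite(tnext))
        stop("coalescent did not complete: isolated lineages with no path to the root");
      t = tnext;
      while (bi < bnd.size() && bnd[bi] <= t) bi++;
      if (t >= dem.Ts12)
        for (int i = 0; i < nact; i++) if (lpop[i] <= 1) lpop[i] = 3;
      if (t >= dem.Ts123)
        for (int i = 0; i < nact; i++) if (lpop[i] == 2 || lpop[i] == 3) lpop[i] = 4;
      continue;
    }

    t += dt;
    double u = R::unif_rand() * total;
    int event_pop = -1;
    bool is_coal = false;

    for (int di = 0; di < nd && event_pop < 0; di++) {
      const int p = demes[di];
      if (coal[p] > 0.0) {
        if (u < coal[p]) { event_pop = p; is_coal = true; break; }
        u -= coal[p];
      }
    }
    if (event_pop < 0) {
      for (int di = 0; di < nd; di++) {
        const int p = demes[di];
        const double mp = k[p] * migl[p];
        if (mp > 0.0) {
          if (u < mp) { event_pop = p; break; }
          u -= mp;
        }
      }
      if (event_pop < 0) event_pop = demes[nd - 1];  // numerical slack
    }

    if (is_coal) {
      const int p = event_pop;
      int ia = (int)std::floor(R::unif_rand() * k[p]);
      int ib = (int)std::floor(R::unif_rand() * (k[p] - 1));
      if (ia >= k[p]) ia = k[p] - 1;
      if (ib >= k[p] - 1) ib = k[p] - 2;
      if (ib >= ia) ib++;
      int posa = -1, posb = -1, seen = 0;
      for (int i = 0; i < nact; i++) {
        if (lpop[i] == p) {
          if (seen == ia) posa = i;
          if (seen == ib) posb = i;
          seen++;
        }
      }
      const int node = nextnode++;
      g.parent[act[posa]] = node;
      g.parent[act[posb]] = node;
      g.time[node] = t;
      act[posa] = node;
      act[posb] = act[nact - 1];
      lpop[posb] = lpop[nact - 1];
      nact--;
    } else {
      // migration: pick source lineage uniformly within event_pop, then target
      const int p = event_pop;
      int il = (int)std::floor(R::unif_rand() * k[p]);
      if (il >= k[p]) il = k[p] - 1;
      int pos = -1, seen = 0;
      for (int i = 0; i < nact; i++)
        if (lpop[i] == p) { if (seen == il) { pos = i; break; } seen++; }
      double v = R::unif_rand() * migl[p];
      int target = -1;
      for (int dj = 0; dj < nd; dj++) {
        const int q = demes[dj];
        if (q == p) continue;
        const double r = dem.mpair(p, q, t) / (4.0 * dem.rawsize(p, t));
        if (r > 0.0) {
          if (v < r) { target = q; break; }
          v -= r;
        }
      }
      if (target >= 0) lpop[pos] = target;
    }
  }
  return g;
}

// --- mutation placement --------------------------------------------------

// Returns, per mutation, the branch (node id) it falls on. mode 0 = theta
// (Poisson with intensity mu_site * L * total tree length), mode 1 = fixed
// (exactly s_obs mutations). nmut is capped at L (one column per base pair).
std::vector<int> place_mutations(const Genealogy& g, int mode,
                                 double theta_rate, int s_obs, int L) {
  const int ntot = (int)g.parent.size();
  std::vector<double> cum(ntot - 1);
  double tot = 0.0;
  for (int v = 0; v < ntot - 1; v++) {  // root is the last node
    tot += g.time[g.parent[v]] - g.time[v];
    cum[v] = tot;
  }
  int nmut;
  if (mode == 0) {
    nmut = (tot > 0.0) ? (int)R::rpois(theta_rate * tot) : 0;
  } else {
    nmut = s_obs;
  }
  if (nmut > L) nmut = L;  // finite-sites saturation guard
  std::vector<int> branch(nmut);
  for (int m = 0; m < nmut; m++) {
    const double u = R::unif_rand() * tot;
    branch[m] = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (branch[m] >= ntot - 1) branch[m] = ntot - 2;
  }
  return branch;
}

// derived-allele counts per population for each mutation
void derived_counts(const Genealogy& g, const std::vector<int>& branch,
                    int n1, int n2, IntegerMatrix& cnt,
                    IntegerMatrix* snp) {
  const int ntot = (int)g.parent.size();
  std::vector<int> ch1(ntot, -1), ch2(ntot, -1);
  for (int v = 0; v < ntot - 1; v++) {
    const int p = g.parent[v];
    if (ch1[p] < 0) ch1[p] = v; else ch2[p] = v;
  }
  std::vector<int> stack;
  for (size_t m = 0; m < branch.size(); m++) {
    int c1 = 0, c2 = 0, c3 = 0;
    stack.clear();
    stack.push_back(branch[m]);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      if (v < g.ntip) {
        if (v < n1) c1++;
        else if (v < n1 + n2) c2++;
        else c3++;
        if (snp) (*snp)(v, m) = 1;
      } else {
        stack.push_back(ch1[v]);
        stack.push_back(ch2[v]);
      }
    }
    cnt(0, m) = c1; cnt(1, m) = c2; cnt(2, m) = c3;
  }
}

// --- per-locus summary statistics ----------------------------------------

inline double tajima_d_from(double pitot, int S, int n) {
  if (S < 1 || n < 2) return NA_REAL;
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i <= n - 1; i++) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  const double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  const double b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  const double c1 = b1 - 1.0 / a1;
  const double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  const double e1 = c1 / a1;
  const double e2 = c2 / (a1 * a1 + a2);
  const double var = e1 * S + e2 * (double)S * (S - 1.0);
  if (var <= 0.0) return NA_REAL;
  return (pitot - S / a1) / std::sqrt(var);
}

// cnt: 3 x S derived counts, stats vector of length 33 (see locus_stat_names())
NumericVector stats_from_counts(const IntegerMatrix& cnt, int n1, int n2,
                                int n3, int L) {
  const int S = cnt.ncol();
  const int n[3] = {n1, n2, n3};
  NumericVector out(33);

  double pitot[3] = {0, 0, 0};   // count units (avg pairwise differences)
  int Spop[3] = {0, 0, 0};
  double dxy[3] = {0, 0, 0};     // pair order 12, 13, 23; count units
  double pipool[3] = {0, 0, 0};  // pooled pair pi, count units
  int ss[3] = {0, 0, 0}, sf[3] = {0, 0, 0}, sxA[3] = {0, 0, 0}, sxB[3] = {0, 0, 0};
  double dnum = 0.0, dden = 0.0;
  const int pa[3] = {0, 0, 1}, pb[3] = {1, 2, 2};

  for (int s = 0; s < S; s++) {
    const int c[3] = {cnt(0, s), cnt(1, s), cnt(2, s)};
    for (int p = 0; p < 3; p++) {
      if (n[p] >= 2) {
        pitot[p] += (double)c[p] * (n[p] - c[p]) / (n[p] * (n[p] - 1.0) / 2.0);
        if (c[p] > 0 && c[p] < n[p]) Spop[p]++;
      }
    }
    for (int q = 0; q < 3; q++) {
      const int x = pa[q], y = pb[q];
      if (n[x] < 1 || n[y] < 1) continue;
      dxy[q] += ((double)c[x] * (n[y] - c[y]) + (double)(n[x] - c[x]) * c[y]) /
                ((double)n[x] * n[y]);
      const int cp = c[x] + c[y], np = n[x] + n[y];
      pipool[q] += (double)cp * (np - cp) / (np * (np - 1.0) / 2.0);
      const bool polx = (c[x] > 0 && c[x] < n[x]);
      const bool poly = (c[y] > 0 && c[y] < n[y]);
      if (polx && poly) ss[q]++;
      else if (polx && !poly) sxA[q]++;
      else if (!polx && poly) sxB[q]++;
      else if ((c[x] == 0 && c[y] == n[y]) || (c[x] == n[x] && c[y] == 0)) sf[q]++;
    }
    const double p1 = (double)c[0] / n[0], p2 = (double)c[1] / n[1],
                 p3 = (double)c[2] / n[2];
    dnum += (1.0 - p1) * p2 * p3 - p1 * (1.0 - p2) * p3;
    dden += (1.0 - p1) * p2 * p3 + p1 * (1.0 - p2) * p3;
  }

  for (int p = 0; p < 3; p++) {
    out[p] = (n[p] >= 2) ? pitot[p] / L : NA_REAL;
    if (n[p] >= 2) {
      double a1 = 0.0;
      for (int i = 1; i <= n[p] - 1; i++) a1 += 1.0 / i;
      out[3 + p] = Spop[p] / (a1 * L);
    } else out[3 + p] = NA_REAL;
    out[6 + p] = (n[p] >= 2) ? tajima_d_from(pitot[p], Spop[p], n[p]) : NA_REAL;
  }
  for (int q = 0; q < 3; q++) {
    const int x = pa[q], y = pb[q];
    out[9 + q] = dxy[q] / L;
    const double pix = (n[x] >= 2) ? pitot[x] / L : NA_REAL;
    const double piy = (n[y] >= 2) ? pitot[y] / L : NA_REAL;
    out[12 + q] = out[9 + q] - (pix + piy) / 2.0;
    const double pit = pipool[q] / L;
    out[15 + q] = (pit > 0.0) ? 1.0 - ((pix + piy) / 2.0) / pit : NA_REAL;
    out[18 + 4 * q] = ss[q];
    out[19 + 4 * q] = sf[q];
    out[20 + 4 * q] = sxA[q];
    out[21 + 4 * q] = sxB[q];
  }
  out[30] = dnum;
  out[31] = dden;
  out[32] = (dden > 0.0) ? dnum / dden : NA_REAL;
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_sim_genealogy(NumericVector dem, int n1, int n2, int n3,
                       double f_ne, double f_m) {
  Dem d = unpack(dem, f_ne, f_m);
  Genealogy g = simulate_core(d, n1, n2, n3);
  return List::create(_["parent"] = IntegerVector(g.parent.begin(), g.parent.end()),
                      _["time"] = NumericVector(g.time.begin(), g.time.end()),
                      _["n_tip"] = g.ntip);
}

// [[Rcpp::export]]
List cpp_mutate(IntegerVector parent, NumericVector time, int n1, int n2,
                int n3, int mode, double theta_rate, int s_obs, int L,
                bool return_matrix) {
  Genealogy g;
  g.parent.assign(parent.begin(), parent.end());
  g.time.assign(time.begin(), time.end());
  g.ntip = n1 + n2 + n3;
  std::vector<int> branch = place_mutations(g, mode, theta_rate, s_obs, L);
  const int S = (int)branch.size();
  IntegerMatrix cnt(3, S);
  if (return_matrix) {
    IntegerMatrix snp(g.ntip, S);
    derived_counts(g, branch, n1, n2, cnt, &snp);
    return List::create(_["counts"] = cnt, _["snp"] = snp,
                        _["branch"] = IntegerVector(branch.begin(), branch.end()));
  }
  derived_counts(g, branch, n1, n2, cnt, nullptr);
  return List::create(_["counts"] = cnt, _["snp"] = R_NilValue,
                      _["branch"] = IntegerVector(branch.begin(), branch.end()));
}

// [[Rcpp::export]]
NumericVector cpp_stats_from_counts(IntegerMatrix counts, int n1, int n2,
                                    int n3, int L) {
  return stats_from_counts(counts, n1, n2, n3, L);
}

// [[Rcpp::export]]
NumericVector cpp_locus_stats(IntegerMatrix snp, int n1, int n2, int n3,
                              int L) {
  const int S = snp.ncol();
  IntegerMatrix cnt(3, S);
  for (int s = 0; s < S; s++) {
    int c1 = 0, c2 = 0, c3 = 0;
    for (int i = 0; i < n1; i++) c1 += snp(i, s);
    for (int i = n1; i < n1 + n2; i++) c2 += snp(i, s);
    for (int i = n1 + n2; i < n1 + n2 + n3; i++) c3 += snp(i, s);
    cnt(0, s) = c1; cnt(1, s) = c2; cnt(2, s) = c3;
  }
  return stats_from_counts(cnt, n1, n2, n3, L);
}

// Simulate a whole multi-locus dataset and return the per-locus statistic
// matrix directly (hot path for reference-table building). In theta mode
// monomorphic loci are dropped; `kept` holds 1-based indices of retained
// locus specs.
// [[Rcpp::export]]
List cpp_sim_dataset_stats(NumericVector dem, int n1, int n2, int n3,
                           NumericVector f_ne, NumericVector f_m,
                           IntegerVector lengths, int mode, double mu,
                           IntegerVector s_obs) {
  const int nloc = lengths.size();
  std::vector<int> kept;
  std::vector<double> rows;
  kept.reserve(nloc);
  rows.reserve((size_t)nloc * 33);
  for (int l = 0; l < nloc; l++) {
    Dem d = unpack(dem, f_ne[l], f_m[l]);
    Genealogy g = simulate_core(d, n1, n2, n3);
    const int L = lengths[l];
    std::vector<int> branch =
        place_mutations(g, mode, mu * L, mode == 1 ? s_obs[l] : 0, L);
    if (branch.empty()) continue;  // monomorphic (theta mode)
    IntegerMatrix cnt(3, (int)branch.size());
    derived_counts(g, branch, n1, n2, cnt, nullptr);
    NumericVector st = stats_from_counts(cnt, n1, n2, n3, L);
    kept.push_back(l + 1);
    for (int j = 0; j < 33; j++) rows.push_back(st[j]);
  }
  const int nk = (int)kept.size();
  NumericMatrix stats(nk, 33);
  for (int i = 0; i < nk; i++)
    for (int j = 0; j < 33; j++) stats(i, j) = rows[(size_t)i * 33 + j];
  return List::create(_["stats"] = stats,
                      _["kept"] = IntegerVector(kept.begin(), kept.end()));
}

// Full locus simulation (SNP matrix + distinct sorted site positions),
// used by the user-facing simulate_dataset()/synthetic-data path.
// [[Rcpp::export]]
List cpp_sim_locus(NumericVector dem, int n1, int n2, int n3, double f_ne,
                   double f_m, int L, int mode, double mu, int s_obs) {
  Dem d = unpack(dem, f_ne, f_m);
  Genealogy g = simulate_core(d, n1, n2, n3);
  std::vector<int> branch = place_mutations(g, mode, mu * L, s_obs, L);
  const int S = (int)branch.size();
  IntegerMatrix cnt(3, S);
  IntegerMatrix snp(g.ntip, S);
  derived_counts(g, branch, n1, n2, cnt, &snp);
  // distinct positions via partial Fisher-Yates over 0..L-1
  std::vector<int> pool(L);
  for (int i = 0; i < L; i++) pool[i] = i;
  IntegerVector pos(S);
  for (int m = 0; m < S; m++) {
    int j = m + (int)std::floor(R::unif_rand() * (L - m));
    if (j >= L) j = L - 1;
    std::swap(pool[m], pool[j]);
    pos[m] = pool[m];
  }
  // order columns by position
  std::vector<int> ord(S);
  for (int i = 0; i < S; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return pos[a] < pos[b]; });
  IntegerMatrix snp2(g.ntip, S), cnt2(3, S);
  IntegerVector pos2(S);
  for (int j = 0; j < S; j++) {
    pos2[j] = pos[ord[j]];
    for (int i = 0; i < g.ntip; i++) snp2(i, j) = snp(i, ord[j]);
    for (int i = 0; i < 3; i++) cnt2(i, j) = cnt(i, ord[j]);
  }
  return List::create(_["snp"] = snp2, _["counts"] = cnt2,
                      _["positions"] = pos2);
}
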