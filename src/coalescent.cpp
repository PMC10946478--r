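#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Structured-coalescent Monte-Carlo estimator of the expected joint SFS.
//
// Time runs backward from the present in units of 2*N_ref generations.
// Epochs are supplied most-recent-first; within an epoch the size of deme k
// at backward-local time u is nu_k(u) = A_k * exp(B_k * u), covering
// constant (B = 0) and exponential trajectories in closed form.  Pairwise
// coalescence in deme k occurs at rate C(k_lin, 2) / nu_k(u); a lineage in
// deme k migrates (backward) at per-lineage rate r_k.  The last row is the
// root epoch: on entry every deme-1 lineage is moved into deme 2.
//
// Each lineage carries the number of sampled descendants (i, j) it
// subtends; the class is constant over the lineage's lifetime, so its
// contribution to cell (i, j) is (coalescence time - birth time), an O(1)
// accrual per lineage.
//
// Constant-size epochs use a single total-rate exponential draw per event
// (Gillespie); epochs with an exponential trajectory invert the integrated
// coalescent hazard analytically per deme and take the competing minimum.

namespace {

// xoshiro256++ (public-domain algorithm), seeded via splitmix64
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return (double)((next() >> 11) + 1) * 1.1102230246251565e-16;
  }
  inline double expo() { return -std::log(unif()); }
};

// waiting time to integrate E units of coalescent hazard for pair rate
// c2 / (A * exp(B u)), starting at backward-local time u; +Inf when the
// decaying rate can never accumulate E
inline double coal_wait_exp(double E, double c2, double A, double B,
                            double u) {
  double rhs = std::exp(-B * u) - E * A * B / c2;
  if (rhs <= 0.0) return R_PosInf;
  double w = -std::log(rhs) / B - u;
  return (w > 0.0) ? w : 0.0;
}

}  // namespace

// [[Rcpp::export(name = ".sim_jsfs_cpp")]]
List sim_jsfs_cpp(NumericMatrix epochs, int n1, int n2, int nreps,
                  double seed, double event_budget) {
  // epochs columns: duration, A1, B1, A2, B2, r1, r2 (most recent first;
  // last row = root, infinite duration, single deme 2)
  const int nep = epochs.nrow();
  if (nep < 1 || !std::isinf(epochs(nep - 1, 0)))
    stop("last epoch must be the root (infinite duration)");
  for (int e = 0; e < nep; ++e)
    if (epochs(e, 1) <= 0.0 || epochs(e, 3) <= 0.0)
      stop("non-positive population size in epoch %d", e + 1);
  const int n = n1 + n2;
  if (n < 2) stop("need at least two sampled lineages");

  std::vector<double> ep_end(nep), dur(nep), A1v(nep), B1v(nep), A2v(nep),
      B2v(nep), r1v(nep), r2v(nep), inv_A1(nep), inv_A2(nep);
  std::vector<bool> constant_ep(nep);
  double tcum = 0.0;
  for (int e = 0; e < nep; ++e) {
    dur[e] = epochs(e, 0);
    tcum += dur[e];
    ep_end[e] = tcum;
    A1v[e] = epochs(e, 1); B1v[e] = epochs(e, 2);
    A2v[e] = epochs(e, 3); B2v[e] = epochs(e, 4);
    r1v[e] = epochs(e, 5); r2v[e] = epochs(e, 6);
    inv_A1[e] = 1.0 / A1v[e]; inv_A2[e] = 1.0 / A2v[e];
    constant_ep[e] = (B1v[e] == 0.0 && B2v[e] == 0.0);
  }

  Rng rng((uint64_t)seed * 2685821657736338717ULL + 1442695040888963407ULL);

  const int nr = n1 + 1, nc = n2 + 1, ncell = nr * nc;
  std::vector<double> acc(ncell), sum(ncell, 0.0), sumsq(ncell, 0.0);

  // lineage storage: class and birth time indexed by id; per-deme id lists
  std::vector<int> cls(2 * n);        // packed class i * nc + j
  std::vector<double> birth(2 * n);
  std::vector<int> d1, d2;
  d1.reserve(n); d2.reserve(n);
  double events = 0.0;
  bool truncated = false;

  int reps_done = 0;
  for (int rep = 0; rep < nreps; ++rep) {
    if (events > event_budget) { truncated = true; break; }
    std::fill(acc.begin(), acc.end(), 0.0);
    d1.clear(); d2.clear();
    int next_id = 0;
    for (int a = 0; a < n1; ++a) {
      cls[next_id] = 1 * nc + 0; birth[next_id] = 0.0; d1.push_back(next_id++);
    }
    for (int a = 0; a < n2; ++a) {
      cls[next_id] = 0 * nc + 1; birth[next_id] = 0.0; d2.push_back(next_id++);
    }

    double t = 0.0;
    int e = 0;
    int nlin = n;
    bool root_entered = (nep == 1);
    if (root_entered) {  // degenerate: root only
      for (int id : d1) d2.push_back(id);
      d1.clear();
    }

    while (nlin > 1) {
      events += 1.0;
      const int k1 = (int)d1.size(), k2 = (int)d2.size();
      const double c21 = 0.5 * k1 * (k1 - 1), c22 = 0.5 * k2 * (k2 - 1);
      double w;
      int ev;  // 0 coal d1, 1 coal d2, 2 mig d1->d2, 3 mig d2->d1

      if (constant_ep[e]) {
        const double rc1 = c21 * inv_A1[e], rc2 = c22 * inv_A2[e];
        const double rm1 = k1 * r1v[e], rm2 = k2 * r2v[e];
        const double R = rc1 + rc2 + rm1 + rm2;
        if (R <= 0.0) { t = ep_end[e]; ++e; goto advance; }
        w = rng.expo() / R;
        if (t + w > ep_end[e]) { t = ep_end[e]; ++e; goto advance; }
        {
          double u = rng.unif() * R;
          if (u < rc1) ev = 0;
          else if (u < rc1 + rc2) ev = 1;
          else if (u < rc1 + rc2 + rm1) ev = 2;
          else ev = 3;
        }
      } else {
        const double u0 = t - (ep_end[e] - dur[e]);
        double w1 = R_PosInf, w2 = R_PosInf, wm1 = R_PosInf, wm2 = R_PosInf;
        if (c21 > 0.0)
          w1 = (B1v[e] == 0.0) ? rng.expo() * A1v[e] / c21
             : coal_wait_exp(rng.expo(), c21, A1v[e], B1v[e], u0);
        if (c22 > 0.0)
          w2 = (B2v[e] == 0.0) ? rng.expo() * A2v[e] / c22
             : coal_wait_exp(rng.expo(), c22, A2v[e], B2v[e], u0);
        if (k1 > 0 && r1v[e] > 0.0) wm1 = rng.expo() / (k1 * r1v[e]);
        if (k2 > 0 && r2v[e] > 0.0) wm2 = rng.expo() / (k2 * r2v[e]);
        w = w1; ev = 0;
        if (w2 < w) { w = w2; ev = 1; }
        if (wm1 < w) { w = wm1; ev = 2; }
        if (wm2 < w) { w = wm2; ev = 3; }
        if (t + w > ep_end[e]) { t = ep_end[e]; ++e; goto advance; }
      }
      t += w;

      if (ev <= 1) {  // coalescence
        std::vector<int> &d = (ev == 0) ? d1 : d2;
        const int k = (int)d.size();
        int p1 = (int)(rng.unif() * k); if (p1 >= k) p1 = k - 1;
        int p2 = (int)(rng.unif() * (k - 1)); if (p2 >= k - 1) p2 = k - 2;
        if (p2 >= p1) ++p2;
        const int id1 = d[p1], id2 = d[p2];
        acc[cls[id1]] += t - birth[id1];
        acc[cls[id2]] += t - birth[id2];
        const int pcls = cls[id1] + cls[id2];  // packed classes add
        cls[id1] = pcls; birth[id1] = t;       // id1 becomes the parent
        const int phi = (p1 > p2) ? p1 : p2;
        d[phi] = d.back(); d.pop_back();
        if (d[(p1 < p2) ? p1 : p2] == id2) d[(p1 < p2) ? p1 : p2] = id1;
        --nlin;
      } else {  // migration
        std::vector<int> &src = (ev == 2) ? d1 : d2;
        std::vector<int> &dst = (ev == 2) ? d2 : d1;
        const int k = (int)src.size();
        int p = (int)(rng.unif() * k); if (p >= k) p = k - 1;
        const int id = src[p];
        src[p] = src.back(); src.pop_back();
        dst.push_back(id);
      }
      continue;

    advance:
      if (!root_entered && e == nep - 1) {
        for (int id : d1) d2.push_back(id);
        d1.clear();
        root_entered = true;
      }
    }

    for (int c = 0; c < ncell; ++c) {
      sum[c] += acc[c];
      sumsq[c] += acc[c] * acc[c];
    }
    ++reps_done;
    if ((rep & 4095) == 0) Rcpp::checkUserInterrupt();
  }
  if (reps_done < 1) reps_done = 1;

  NumericMatrix mean_bl(nr, nc), se(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      const double m = sum[i * nc + j] / reps_done;
      mean_bl(i, j) = m;
      const double v = sumsq[i * nc + j] / reps_done - m * m;
      se(i, j) = (reps_done > 1 && v > 0.0) ? std::sqrt(v / reps_done) : 0.0;
    }
  }
  return List::create(_["mean_bl"] = mean_bl, _["se"] = se,
                      _["truncated"] = truncated);
}
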