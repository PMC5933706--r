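#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Allele-frequency trajectories
//
// Forward Wright-Fisher binomial sampling with additive selection
// (genotype fitnesses 1, 1+hs, 1+s with h = 0.5) and symmetric migration
// between an African deme (0) and a non-African deme (1) that exists for
// generations t < t_ooa (backward time; t = 0 is the present).
// ---------------------------------------------------------------------------

static inline double deme0_size(int g, const NumericVector& N0, double anc) {
  return g < (int)N0.size() ? N0[g] : anc;
}

static inline double sel_step(double p, double s) {
  if (p <= 0.0 || p >= 1.0 || s == 0.0) return p;
  const double h = 0.5;
  double wbar = p * p * (1 + s) + 2 * p * (1 - p) * (1 + h * s) +
    (1 - p) * (1 - p);
  return (p * p * (1 + s) + p * (1 - p) * (1 + h * s)) / wbar;
}

static inline double drift(double p, double twoN, bool deterministic) {
  if (deterministic) return p;
  if (p <= 0.0) return 0.0;
  if (p >= 1.0) return 1.0;
  double n = std::max(1.0, std::round(twoN));
  return R::rbinom(n, p) / n;
}

// One rejection-sampled trajectory. model: 0 = SDN/NTR-style (born as a
// single copy at generation g_start), 1 = SSV (frequency f_sel at onset
// g_start, neutral history constructed backward, conditioned on loss).
// sA, sNA apply from g_start toward the present; halt_gen most recent
// generations have s = 0. Returns x0, x1 (length g_birth + 1), g_birth,
// and the rejection counters.
// [[Rcpp::export]]
List simulate_trajectory_cpp(int model, int g_start, double sA, double sNA,
                             double f_sel, int halt_gen, NumericVector N0,
                             double anc_size, NumericVector N1,
                             NumericVector mig, int t_ooa, int max_tries,
                             bool deterministic) {
  RNGScope scope;
  const int max_walk = 200000;
  int n_lost = 0, n_fixed_back = 0;

  for (int attempt = 0; attempt < max_tries; ++attempt) {
    std::vector<double> x0, x1;  // index = generations ago
    int g_birth;

    if (model == 1) {
      // backward neutral walk from f_sel at g_start until loss
      std::vector<double> back;
      back.push_back(f_sel);
      bool ok = false, fixed = false;
      double q = f_sel;
      for (int g = g_start + 1; g <= g_start + max_walk; ++g) {
        double twoN = 2.0 * deme0_size(g, N0, anc_size);
        q = drift(q, twoN, false);
        back.push_back(q);
        if (q <= 0.0) { ok = true; g_birth = g - 1; break; }
        if (q >= 1.0) { fixed = true; break; }
      }
      if (!ok) { if (fixed) ++n_fixed_back; else ++n_lost; continue; }
      x0.assign(g_birth + 1, 0.0);
      x1.assign(g_birth + 1, 0.0);
      for (int g = g_start; g <= g_birth; ++g) {
        x0[g] = back[g - g_start];
        if (g < t_ooa) x1[g] = back[g - g_start];  // shared standing variant
      }
      x0[g_start] = f_sel;
      if (g_start < t_ooa) x1[g_start] = f_sel;
    } else {
      g_birth = g_start;
      x0.assign(g_birth + 1, 0.0);
      x1.assign(g_birth + 1, 0.0);
      x0[g_birth] = 1.0 / (2.0 * deme0_size(g_birth, N0, anc_size));
    }

    // forward phase from g_start (selection applies from here on)
    bool lost = false;
    for (int t = g_start; t >= 1; --t) {
      int tn = t - 1;
      double s0 = (model == 1) ? 0.0 : sA;
      double s1 = sNA;
      if (tn < halt_gen) { s0 = 0.0; s1 = 0.0; }
      bool d1_now = t < t_ooa;
      bool d1_next = tn < t_ooa;
      double p0 = sel_step(x0[t], s0);
      double p1 = d1_now ? sel_step(x1[t], s1) : 0.0;
      double m = (d1_now && t < (int)mig.size()) ? mig[t] : 0.0;
      double q0 = d1_now ? (1 - m) * p0 + m * p1 : p0;
      double q1 = d1_now ? (1 - m) * p1 + m * p0 : 0.0;
      x0[tn] = drift(q0, 2.0 * deme0_size(tn, N0, anc_size), deterministic);
      if (d1_next) {
        double twoN1 = 2.0 * N1[tn];
        // founder draw when the out-of-Africa deme first appears
        double src = d1_now ? q1 : q0;
        x1[tn] = drift(src, twoN1, deterministic);
      }
      if (x0[tn] <= 0.0 && (!d1_next || x1[tn] <= 0.0) && tn > 0) {
        // may still be rescued only by nothing: allele extinct
        lost = true; break;
      }
    }
    if (lost || (x0[0] <= 0.0 && x1[0] <= 0.0)) { ++n_lost; continue; }
    return List::create(_["x0"] = NumericVector(x0.begin(), x0.end()),
                        _["x1"] = NumericVector(x1.begin(), x1.end()),
                        _["g_birth"] = g_birth,
                        _["n_lost"] = n_lost,
                        _["n_fixed_back"] = n_fixed_back);
  }
  return List::create(_["failed"] = true, _["n_lost"] = n_lost,
                      _["n_fixed_back"] = n_fixed_back);
}

// ---------------------------------------------------------------------------
// Trajectory-conditioned structured coalescent with recombination
// ---------------------------------------------------------------------------

struct Seg {
  double l, r;
  std::vector<int> desc;  // sorted sample indices below this segment
};

struct Lin {
  int deme, cls;          // cls: 1 = derived focal allele, 0 = ancestral
  std::vector<Seg> segs;  // sorted, disjoint
  double lo() const { return segs.front().l; }
  double hi() const { return segs.back().r; }
  double span() const { return segs.empty() ? 0.0 : hi() - lo(); }
  double len() const {
    double s = 0; for (const auto& g : segs) s += g.r - g.l; return s;
  }
};

static std::vector<int> set_union_vec(const std::vector<int>& a,
                                      const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_union(a.begin(), a.end(), b.begin(), b.end(),
                 std::back_inserter(out));
  return out;
}

// merge two segment lists at a coalescence; segments whose descendant set
// reaches all samples (MRCA) are dropped
static std::vector<Seg> merge_segs(const std::vector<Seg>& A,
                                   const std::vector<Seg>& B, int ntot) {
  std::vector<double> bp;
  bp.reserve(2 * (A.size() + B.size()));
  for (const auto& s : A) { bp.push_back(s.l); bp.push_back(s.r); }
  for (const auto& s : B) { bp.push_back(s.l); bp.push_back(s.r); }
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());
  std::vector<Seg> out;
  size_t ia = 0, ib = 0;
  for (size_t i = 0; i + 1 < bp.size(); ++i) {
    double l = bp[i], r = bp[i + 1];
    while (ia < A.size() && A[ia].r <= l) ++ia;
    while (ib < B.size() && B[ib].r <= l) ++ib;
    const Seg* sa = (ia < A.size() && A[ia].l <= l) ? &A[ia] : nullptr;
    const Seg* sb = (ib < B.size() && B[ib].l <= l) ? &B[ib] : nullptr;
    if (!sa && !sb) continue;
    std::vector<int> d;
    if (sa && sb) d = set_union_vec(sa->desc, sb->desc);
    else d = sa ? sa->desc : sb->desc;
    if ((int)d.size() >= ntot) continue;  // segment has found its MRCA
    if (!out.empty() && out.back().r == l && out.back().desc == d)
      out.back().r = r;
    else out.push_back(Seg{l, r, std::move(d)});
  }
  return out;
}

struct SimState {
  std::vector<Lin> lins;
  std::vector<double> mpos;
  std::vector<std::vector<int>> mdesc;
  int ntot;
  double mu;  // per bp per generation

  void add_mutations(double dt) {
    for (auto& ln : lins) {
      double lam = mu * ln.len() * dt;
      if (lam <= 0) continue;
      int nm = (int)R::rpois(lam);
      for (int k = 0; k < nm; ++k) {
        double u = R::runif(0.0, ln.len());
        for (const auto& g : ln.segs) {
          double w = g.r - g.l;
          if (u < w) {
            mpos.push_back(g.l + u);
            mdesc.push_back(g.desc);
            break;
          }
          u -= w;
        }
      }
    }
  }

  void prune() {
    lins.erase(std::remove_if(lins.begin(), lins.end(),
                              [](const Lin& l) { return l.segs.empty(); }),
               lins.end());
  }

  // split lineage i at breakpoint b; the piece on the focal side keeps the
  // class, the other piece redraws its class from the current derived
  // frequency in its deme
  void recombine(size_t i, double b, double focal, double xd) {
    Lin& ln = lins[i];
    std::vector<Seg> left, right;
    for (const auto& g : ln.segs) {
      if (g.r <= b) left.push_back(g);
      else if (g.l >= b) right.push_back(g);
      else {
        left.push_back(Seg{g.l, b, g.desc});
        right.push_back(Seg{b, g.r, g.desc});
      }
    }
    if (left.empty() || right.empty()) return;
    bool focal_left = focal < b;
    Lin nw;
    nw.deme = ln.deme;
    int keep_cls = ln.cls;
    int new_cls = (R::unif_rand() < xd) ? 1 : 0;
    if (focal_left) {
      ln.segs = left; ln.cls = keep_cls;
      nw.segs = right; nw.cls = new_cls;
    } else {
      ln.segs = right; ln.cls = keep_cls;
      nw.segs = left; nw.cls = new_cls;
    }
    lins.push_back(std::move(nw));
  }
};

// continuous-time neutral single-deme phase (used once the sample is in
// one deme with no derived-class lineages left)
static void continuous_phase(SimState& st, double t_now,
                             const NumericVector& N0, double anc_size,
                             double r_bp) {
  double t = t_now;
  const double n0len = N0.size();
  while (true) {
    st.prune();
    if (st.lins.size() < 2) break;
    double N = t < n0len ? N0[(int)t] : anc_size;
    double t_next_change = t < n0len ? n0len : R_PosInf;
    // within N0 the African size is piecewise constant; find next change
    if (t < n0len) {
      int g = (int)t;
      while (g + 1 < n0len && N0[g + 1] == N0[g]) ++g;
      t_next_change = g + 1 == n0len ? n0len : (double)(g + 1);
    }
    size_t k = st.lins.size();
    double rate_coal = k * (k - 1.0) / 2.0 / (2.0 * N);
    double tot_span = 0;
    for (const auto& ln : st.lins) tot_span += ln.span();
    double rate_rec = r_bp * tot_span;
    double rate = rate_coal + rate_rec;
    double dt = R::exp_rand() / rate;
    if (t + dt > t_next_change) {
      st.add_mutations(t_next_change - t);
      t = t_next_change;
      continue;
    }
    st.add_mutations(dt);
    t += dt;
    if (R::unif_rand() < rate_coal / rate) {
      int i = (int)(R::unif_rand() * k);
      int j = (int)(R::unif_rand() * (k - 1));
      if (j >= i) ++j;
      st.lins[i].segs = merge_segs(st.lins[i].segs, st.lins[j].segs, st.ntot);
      st.lins.erase(st.lins.begin() + j);
    } else {
      double u = R::unif_rand() * tot_span;
      for (size_t i = 0; i < k; ++i) {
        double w = st.lins[i].span();
        if (u < w) {
          st.recombine(i, st.lins[i].lo() + u, /*focal=*/-1.0, /*xd=*/0.0);
          break;
        }
        u -= w;
      }
    }
  }
}

// [[Rcpp::export]]
List sim_locus_cpp(NumericVector x0, NumericVector x1, int g_birth,
                   int n0, int n1, int nder0, int nder1,
                   NumericVector N0, double anc_size, NumericVector N1,
                   NumericVector mig, int t_ooa, double L, double r_bp,
                   double mu_bp, double focal_pos, bool conditioned) {
  RNGScope scope;
  SimState st;
  st.ntot = n0 + n1;
  st.mu = mu_bp;

  // sample: deme 0 rows first; within a deme, derived-class rows first
  for (int i = 0; i < st.ntot; ++i) {
    Lin ln;
    ln.deme = i < n0 ? 0 : 1;
    ln.cls = 0;
    if (conditioned) {
      if (i < n0) ln.cls = i < nder0 ? 1 : 0;
      else ln.cls = (i - n0) < nder1 ? 1 : 0;
    }
    ln.segs.push_back(Seg{0.0, L, std::vector<int>{i}});
    st.lins.push_back(std::move(ln));
  }
  if (t_ooa <= 0) for (auto& ln : st.lins) ln.deme = 0;

  int t = 0;  // lineages currently at generation t
  const int hard_cap = 5000000;
  while (true) {
    st.prune();
    if (st.lins.size() < 2) break;
    bool anyD = false;
    for (const auto& ln : st.lins) if (ln.cls == 1) { anyD = true; break; }
    if (!anyD && t >= t_ooa) { continuous_phase(st, t, N0, anc_size, r_bp); break; }
    if (t > hard_cap) stop("coalescent failed to terminate");

    int tp = t + 1;  // parents' generation
    if (tp >= t_ooa) for (auto& ln : st.lins) ln.deme = 0;

    // class frequencies in the parents' generation
    double xd0 = (conditioned && tp <= g_birth) ? x0[tp] : 0.0;
    double xd1 = (conditioned && tp <= g_birth && tp < t_ooa) ? x1[tp] : 0.0;
    double Nn0 = tp < (int)N0.size() ? N0[tp] : anc_size;
    double Nn1 = tp < t_ooa ? N1[tp] : 0.0;
    double xd[2] = {xd0, xd1};
    double Nd[2] = {Nn0, Nn1};

    // mutations on the branch from t to t+1
    st.add_mutations(1.0);

    // recombination: per lineage, prob r_bp * span
    size_t nlin = st.lins.size();
    for (size_t i = 0; i < nlin; ++i) {
      double span = st.lins[i].span();
      if (span <= 0) continue;
      if (R::unif_rand() < r_bp * span) {
        double b = st.lins[i].lo() + R::unif_rand() * span;
        st.recombine(i, b, focal_pos, xd[st.lins[i].deme]);
      }
    }

    // migration (both demes alive)
    if (tp < t_ooa) {
      double m = tp < (int)mig.size() ? mig[tp] : 0.0;
      if (m > 0) for (auto& ln : st.lins) {
        if (R::unif_rand() < m) {
          int other = 1 - ln.deme;
          double f = ln.cls == 1 ? xd[other] : 1.0 - xd[other];
          if (f > 0 && (other == 0 || tp < t_ooa)) ln.deme = other;
        }
      }
    }

    // forced moves out of empty classes
    for (auto& ln : st.lins) {
      double f_here = ln.cls == 1 ? xd[ln.deme] : 1.0 - xd[ln.deme];
      if (f_here <= 0.0) {
        int other = 1 - ln.deme;
        bool other_alive = other == 1 ? tp < t_ooa : true;
        double f_other = other_alive ?
          (ln.cls == 1 ? xd[other] : 1.0 - xd[other]) : 0.0;
        if (other_alive && f_other > 0.0) ln.deme = other;
        // else: class locally extinct everywhere; handled at birth below
      }
    }

    // Wright-Fisher parent assignment within each deme x class
    for (int d = 0; d < 2; ++d) for (int c = 0; c < 2; ++c) {
      std::vector<size_t> ids;
      for (size_t i = 0; i < st.lins.size(); ++i)
        if (st.lins[i].deme == d && st.lins[i].cls == c) ids.push_back(i);
      if (ids.size() < 2) continue;
      double f = c == 1 ? xd[d] : 1.0 - xd[d];
      double M = std::max(1.0, std::round(2.0 * Nd[d] * f));
      std::unordered_map<long, size_t> first;
      for (size_t idx : ids) {
        long par = (long)(R::unif_rand() * M);
        auto it = first.find(par);
        if (it == first.end()) first[par] = idx;
        else {
          size_t tgt = it->second;
          st.lins[tgt].segs = merge_segs(st.lins[tgt].segs,
                                         st.lins[idx].segs, st.ntot);
          st.lins[idx].segs.clear();
        }
      }
    }

    // focal-allele birth: all remaining derived lineages coalesce into the
    // single founding copy (in the African deme) and switch to the
    // ancestral background
    if (conditioned && tp >= g_birth) {
      std::vector<size_t> ds;
      for (size_t i = 0; i < st.lins.size(); ++i)
        if (st.lins[i].cls == 1 && !st.lins[i].segs.empty()) ds.push_back(i);
      if (ds.size() > 1) {
        for (size_t k = 1; k < ds.size(); ++k) {
          st.lins[ds[0]].segs = merge_segs(st.lins[ds[0]].segs,
                                           st.lins[ds[k]].segs, st.ntot);
          st.lins[ds[k]].segs.clear();
        }
      }
      for (auto& ln : st.lins) if (ln.cls == 1) { ln.cls = 0; ln.deme = 0; }
    }
    t = tp;
  }

  // assemble output
  int S = st.mpos.size();
  NumericVector pos(S);
  IntegerMatrix geno(st.ntot, S);
  for (int j = 0; j < S; ++j) {
    pos[j] = st.mpos[j];
    for (int i : st.mdesc[j]) geno(i, j) = 1;
  }
  return List::create(_["pos"] = pos, _["geno"] = geno);
}
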