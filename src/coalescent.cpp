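// Structured-coalescent engine: backward-in-time simulation of single-locus
// genealogies under multi-deme demographies with exponential growth,
// migration and timed historical events, plus accumulation passes for the
// branch-length-ratio SFS estimator, infinite-sites mutation dropping and
// the heterozygous-individual ascertainment scheme.
//
// Conventions (documented in the R-level help):
//  * sizes are diploid; a pair of lineages in a deme of size N coalesces at
//    rate 1/(2N);
//  * migration matrix entry [from][to] is the backward per-lineage rate;
//  * growth rate r is the forward exponential rate, so backward in time the
//    deme size is N_ref * exp(-r * (t - t_ref)) until an event resets it;
//  * waiting times under growth use the exact time-change inversion
//    s = log1p(b*E/a)/b for hazard a*exp(b*s), no Euler stepping.
//
// The hot path (cpp_expected_sfs, cpp_pseudo_sfs) never materializes trees:
// every lineage carries its dense SFS entry index (which is additive under
// coalescence, since the index is a linear function of the per-deme
// descendant counts) and its count of "chosen" ascertainment leaves; a
// branch is emitted the moment it closes. Full trees are built only for the
// single-genealogy R API.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Event {
  double time;
  int source;       // -1 = none (pure size/growth/matrix change uses sink)
  int sink;
  double prop;      // probability a source lineage moves to sink
  double new_size;  // NaN = unchanged (applies to sink)
  double new_growth;// NaN = unchanged (applies to sink)
  int mig_id;       // -1 = unchanged
};

struct Model {
  int npop;
  std::vector<int> samp;
  std::vector<double> size0, growth0;
  std::vector< std::vector<double> > migs;     // row-major [from*npop+to]
  std::vector< std::vector<double> > rowsums;  // per matrix, per source deme
  std::vector<bool> has_mig;                   // per matrix
  std::vector<Event> events;
  std::vector<int> stride;                     // dense-index strides, last deme fastest
  int n, nent;
};

Model parse_model(const List& model) {
  Model M;
  M.npop = as<int>(model["npop"]);
  M.samp = as< std::vector<int> >(model["sample_sizes"]);
  M.size0 = as< std::vector<double> >(model["sizes"]);
  M.growth0 = as< std::vector<double> >(model["growth"]);
  List migs(model["migration"]);
  for (int i = 0; i < migs.size(); ++i) {
    NumericMatrix m(migs[i]);
    std::vector<double> flat(M.npop * M.npop, 0.0), rs(M.npop, 0.0);
    bool any = false;
    for (int a = 0; a < M.npop; ++a)
      for (int b = 0; b < M.npop; ++b)
        if (a != b && m(a, b) > 0.0) {
          flat[a * M.npop + b] = m(a, b);
          rs[a] += m(a, b);
          any = true;
        }
    M.migs.push_back(flat);
    M.rowsums.push_back(rs);
    M.has_mig.push_back(any);
  }
  NumericMatrix ev(as<NumericMatrix>(model["events"]));
  for (int i = 0; i < ev.nrow(); ++i) {
    Event e;
    e.time = ev(i, 0);
    e.source = ev(i, 1) >= 0 ? (int)ev(i, 1) : -1;
    e.sink = (int)ev(i, 2);
    e.prop = ev(i, 3);
    e.new_size = ev(i, 4);
    e.new_growth = ev(i, 5);
    e.mig_id = std::isnan(ev(i, 6)) ? -1 : (int)ev(i, 6);
    M.events.push_back(e);
  }
  M.stride.assign(M.npop, 1);
  for (int k = M.npop - 2; k >= 0; --k)
    M.stride[k] = M.stride[k + 1] * (M.samp[k + 1] + 1);
  M.n = 0;
  for (int k = 0; k < M.npop; ++k) M.n += M.samp[k];
  M.nent = M.stride[0] * (M.samp[0] + 1);
  return M;
}

// Draw waiting time for hazard a*exp(b*s); E std-exponential deviate.
inline double growth_wait(double a, double b, double E) {
  if (a <= 0.0) return R_PosInf;
  if (b == 0.0) return E / a;
  double x = 1.0 + b * E / a;
  if (x <= 0.0) return R_PosInf;  // declining backward rate never fires
  return std::log(x) / b;
}

// Reusable per-lineage state; compacted in place as lineages coalesce.
struct Work {
  std::vector<int> deme, idx, chosen;
  std::vector<double> birth;
  std::vector<int> cnt;
  std::vector<double> size_ref, growth, ref_time;
};

// A closed branch: dense SFS entry, length, whether it lies on the
// ascertainment subtree (exactly one chosen leaf below it).
struct Branch { int idx; double len; bool sub; };

// Simulate one genealogy, emitting every non-root branch into `out`
// (cleared first). If asc_deme >= 0, two distinct lineages of that deme are
// pre-chosen uniformly; a branch's `sub` flag marks the subtree joining them
// to their MRCA. Returns nothing; throws on stalled (non-closable) models.
void simulate_branches(const Model& M, Work& W, std::vector<Branch>& out,
                       int asc_deme, double tmax) {
  const int npop = M.npop, n = M.n;
  out.clear();
  W.deme.resize(n); W.idx.resize(n); W.chosen.resize(n); W.birth.resize(n);
  {
    int id = 0;
    for (int k = 0; k < npop; ++k)
      for (int j = 0; j < M.samp[k]; ++j) {
        W.deme[id] = k; W.idx[id] = M.stride[k]; W.chosen[id] = 0;
        W.birth[id] = 0.0; ++id;
      }
  }
  if (asc_deme >= 0) {
    int c = M.samp[asc_deme];
    int i1 = (int)(unif_rand() * c); if (i1 >= c) i1 = c - 1;
    int i2 = (int)(unif_rand() * (c - 1)); if (i2 >= c - 1) i2 = c - 2;
    if (i2 >= i1) ++i2;
    int base = 0;
    for (int k = 0; k < asc_deme; ++k) base += M.samp[k];
    W.chosen[base + i1] = 1;
    W.chosen[base + i2] = 1;
  }
  int nact = n;

  W.size_ref = M.size0; W.growth = M.growth0;
  W.ref_time.assign(npop, 0.0);
  W.cnt.assign(npop, 0);
  int mig_id = 0;
  size_t ev_idx = 0;
  double t = 0.0;
  for (int i = 0; i < nact; ++i) ++W.cnt[W.deme[i]];

  while (nact > 1) {
    while (ev_idx < M.events.size() && M.events[ev_idx].time <= t) {
      const Event& e = M.events[ev_idx];
      for (int k = 0; k < npop; ++k) {        // refresh size references
        if (W.growth[k] != 0.0)
          W.size_ref[k] *= std::exp(-W.growth[k] * (e.time - W.ref_time[k]));
        W.ref_time[k] = e.time;
      }
      if (e.source >= 0 && e.prop > 0.0) {
        for (int i = 0; i < nact; ++i)
          if (W.deme[i] == e.source &&
              (e.prop >= 1.0 || unif_rand() < e.prop)) {
            --W.cnt[e.source]; ++W.cnt[e.sink];
            W.deme[i] = e.sink;
          }
      }
      if (!std::isnan(e.new_size)) W.size_ref[e.sink] = e.new_size;
      if (!std::isnan(e.new_growth)) W.growth[e.sink] = e.new_growth;
      if (e.mig_id >= 0) mig_id = e.mig_id;
      ++ev_idx;
    }
    double next_ev = ev_idx < M.events.size() ? M.events[ev_idx].time
                                              : R_PosInf;

    double best = R_PosInf;
    int what = -1, which = -1;                // 0 = coalescence, 1 = migration
    for (int k = 0; k < npop; ++k) {
      int c = W.cnt[k];
      if (c >= 2) {
        double a, s;
        if (W.growth[k] == 0.0) {
          a = 0.25 * c * (c - 1) / W.size_ref[k];
          s = exp_rand() / a;
        } else {
          double N = W.size_ref[k] *
                     std::exp(-W.growth[k] * (t - W.ref_time[k]));
          a = 0.25 * c * (c - 1) / N;
          s = growth_wait(a, W.growth[k], exp_rand());
        }
        if (s < best) { best = s; what = 0; which = k; }
      }
    }
    const std::vector<double>& rs = M.rowsums[mig_id];
    double mrate = 0.0;
    if (M.has_mig[mig_id])
      for (int k = 0; k < npop; ++k) mrate += W.cnt[k] * rs[k];
    if (mrate > 0.0) {
      double s = exp_rand() / mrate;
      if (s < best) { best = s; what = 1; }
    }

    if (t + best >= next_ev) { t = next_ev; continue; }
    if (!std::isfinite(best))
      stop("coalescent simulation stalled at time %f: no coalescence or "
           "migration possible and no further events (model not closable)", t);
    t += best;
    if (t > tmax)
      stop("coalescent simulation exceeded the hard time cap (%g "
           "generations); check that the model is closable", tmax);

    if (what == 0) {
      int c = W.cnt[which];
      int i1 = (int)(unif_rand() * c); if (i1 >= c) i1 = c - 1;
      int i2 = (int)(unif_rand() * (c - 1)); if (i2 >= c - 1) i2 = c - 2;
      if (i2 >= i1) ++i2;
      int a = -1, b = -1, seen = 0;
      for (int i = 0; i < nact; ++i)
        if (W.deme[i] == which) {
          if (seen == i1) a = i;
          if (seen == i2) b = i;
          ++seen;
          if (seen > i1 && seen > i2) break;
        }
      // close both child branches
      out.push_back(Branch{W.idx[a], t - W.birth[a], W.chosen[a] == 1});
      out.push_back(Branch{W.idx[b], t - W.birth[b], W.chosen[b] == 1});
      // merged lineage replaces slot a; slot b filled from the back
      W.idx[a] += W.idx[b];
      W.chosen[a] += W.chosen[b];
      W.birth[a] = t;
      --nact;
      W.deme[b] = W.deme[nact]; W.idx[b] = W.idx[nact];
      W.chosen[b] = W.chosen[nact]; W.birth[b] = W.birth[nact];
      --W.cnt[which];
    } else {
      const std::vector<double>& mg = M.migs[mig_id];
      double u = unif_rand() * mrate, acc = 0.0;
      int k = npop - 1;
      for (int kk = 0; kk < npop; ++kk) {
        acc += W.cnt[kk] * rs[kk];
        if (u <= acc) { k = kk; break; }
      }
      int c = W.cnt[k];
      int pick = (int)(unif_rand() * c); if (pick >= c) pick = c - 1;
      int li = -1, seen = 0;
      for (int i = 0; i < nact; ++i)
        if (W.deme[i] == k) { if (seen == pick) { li = i; break; } ++seen; }
      double u2 = unif_rand() * rs[k], acc2 = 0.0;
      int dest = -1;
      for (int j = 0; j < npop; ++j) {
        acc2 += mg[k * npop + j];
        if (u2 <= acc2 && mg[k * npop + j] > 0.0) { dest = j; break; }
      }
      if (dest < 0)
        for (int j = npop - 1; j >= 0; --j)
          if (mg[k * npop + j] > 0) { dest = j; break; }
      --W.cnt[k]; ++W.cnt[dest];
      W.deme[li] = dest;
    }
  }
}

} // namespace

// Branch-length-ratio estimator accumulation over Z genealogies.
// Returns numerators per dense SFS entry, the denominator (sum of total or
// ascertained-subtree lengths), the sum of total lengths, and the sum of
// exp(-mu * relevant length) for the Poisson zero class when mu >= 0.
// [[Rcpp::export]]
List cpp_expected_sfs(List model, int Z, int asc_deme, double mu,
                      double tmax) {
  Model M = parse_model(model);
  std::vector<double> numer(M.nent, 0.0);
  double denom = 0.0, sum_T = 0.0, sum_exp = 0.0;
  Work W; std::vector<Branch> br;
  br.reserve(2 * M.n);

  for (int z = 0; z < Z; ++z) {
    simulate_branches(M, W, br, asc_deme, tmax);
    double T = 0.0, Tuse = 0.0;
    if (asc_deme < 0) {
      for (size_t i = 0; i < br.size(); ++i) {
        numer[br[i].idx] += br[i].len;
        T += br[i].len;
      }
      Tuse = T;
    } else {
      for (size_t i = 0; i < br.size(); ++i) {
        T += br[i].len;
        if (br[i].sub) { numer[br[i].idx] += br[i].len; Tuse += br[i].len; }
      }
    }
    denom += Tuse;
    sum_T += T;
    if (mu >= 0.0) sum_exp += std::exp(-mu * Tuse);
    if ((z & 0x3ff) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["numer"] = NumericVector(numer.begin(), numer.end()),
                      _["denom"] = denom, _["sum_T"] = sum_T,
                      _["sum_exp"] = sum_exp, _["Z"] = Z);
}

// Pseudo-observed SFS: simulate nloci independent genealogies, drop
// Poisson(mu * locus_len * T) infinite-sites mutations uniformly on
// branches, tabulate derived-allele counts. With asc_deme >= 0 only
// mutations falling on branches through which exactly one of two randomly
// chosen lineages of that deme descends (i.e. sites heterozygous between
// them) are retained -- a direct mutation-level filter, independent of the
// subtree-restricted expectation estimator.
// [[Rcpp::export]]
List cpp_pseudo_sfs(List model, int nloci, double mu, double locus_len,
                    int asc_deme, double tmax) {
  Model M = parse_model(model);
  std::vector<double> counts(M.nent, 0.0);
  double S = 0.0;
  Work W; std::vector<Branch> br;
  std::vector<double> cum;
  br.reserve(2 * M.n);
  cum.reserve(2 * M.n);

  for (int loc = 0; loc < nloci; ++loc) {
    simulate_branches(M, W, br, asc_deme, tmax);
    double T = 0.0;
    cum.resize(br.size());
    for (size_t v = 0; v < br.size(); ++v) { T += br[v].len; cum[v] = T; }
    int nmut = (int)R::rpois(mu * locus_len * T);
    for (int m = 0; m < nmut; ++m) {
      double u = unif_rand() * T;
      size_t lo = 0, hi = br.size() - 1;
      while (lo < hi) {
        size_t mid = (lo + hi) / 2;
        if (cum[mid] < u) lo = mid + 1; else hi = mid;
      }
      if (asc_deme >= 0 && !br[lo].sub) continue;
      counts[br[lo].idx] += 1.0;
      S += 1.0;
    }
    if ((loc & 0xfff) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["counts"] = NumericVector(counts.begin(),
                                                  counts.end()),
                      _["S"] = S);
}

// ---------------------------------------------------------------------------
// Single-genealogy API: materialize a full tree for the R-level container.
// Same process as simulate_branches, but keeping parent pointers and node
// times; performance is irrelevant here.
// ---------------------------------------------------------------------------

namespace {

struct Tree {
  int n;
  std::vector<int> parent;
  std::vector<double> time;
  std::vector<int> leaf_deme;
};

void simulate_tree(const Model& M, Tree& tr, double tmax) {
  // run the branch simulator while tracking node identities
  const int npop = M.npop, n = M.n;
  const int nnode = 2 * n - 1;
  tr.n = n;
  tr.parent.assign(nnode, -1);
  tr.time.assign(nnode, 0.0);
  tr.leaf_deme.resize(n);

  std::vector<int> node(n), deme(n);
  {
    int id = 0;
    for (int k = 0; k < npop; ++k)
      for (int j = 0; j < M.samp[k]; ++j) {
        node[id] = id; deme[id] = k; tr.leaf_deme[id] = k; ++id;
      }
  }
  int nact = n, next_id = n;
  std::vector<double> size_ref(M.size0), growth(M.growth0);
  std::vector<double> ref_time(npop, 0.0);
  std::vector<int> cnt(npop, 0);
  for (int i = 0; i < nact; ++i) ++cnt[deme[i]];
  int mig_id = 0;
  size_t ev_idx = 0;
  double t = 0.0;

  while (nact > 1) {
    while (ev_idx < M.events.size() && M.events[ev_idx].time <= t) {
      const Event& e = M.events[ev_idx];
      for (int k = 0; k < npop; ++k) {
        if (growth[k] != 0.0)
          size_ref[k] *= std::exp(-growth[k] * (e.time - ref_time[k]));
        ref_time[k] = e.time;
      }
      if (e.source >= 0 && e.prop > 0.0)
        for (int i = 0; i < nact; ++i)
          if (deme[i] == e.source &&
              (e.prop >= 1.0 || unif_rand() < e.prop)) {
            --cnt[e.source]; ++cnt[e.sink];
            deme[i] = e.sink;
          }
      if (!std::isnan(e.new_size)) size_ref[e.sink] = e.new_size;
      if (!std::isnan(e.new_growth)) growth[e.sink] = e.new_growth;
      if (e.mig_id >= 0) mig_id = e.mig_id;
      ++ev_idx;
    }
    double next_ev = ev_idx < M.events.size() ? M.events[ev_idx].time
                                              : R_PosInf;
    double best = R_PosInf;
    int what = -1, which = -1;
    for (int k = 0; k < npop; ++k) {
      if (cnt[k] >= 2) {
        double N = size_ref[k];
        if (growth[k] != 0.0)
          N *= std::exp(-growth[k] * (t - ref_time[k]));
        double a = 0.25 * cnt[k] * (cnt[k] - 1) / N;
        double s = growth_wait(a, growth[k], exp_rand());
        if (s < best) { best = s; what = 0; which = k; }
      }
    }
    const std::vector<double>& rs = M.rowsums[mig_id];
    double mrate = 0.0;
    if (M.has_mig[mig_id])
      for (int k = 0; k < npop; ++k) mrate += cnt[k] * rs[k];
    if (mrate > 0.0) {
      double s = exp_rand() / mrate;
      if (s < best) { best = s; what = 1; }
    }
    if (t + best >= next_ev) { t = next_ev; continue; }
    if (!std::isfinite(best))
      stop("coalescent simulation stalled at time %f: no coalescence or "
           "migration possible and no further events (model not closable)", t);
    t += best;
    if (t > tmax)
      stop("coalescent simulation exceeded the hard time cap (%g "
           "generations); check that the model is closable", tmax);

    if (what == 0) {
      int c = cnt[which];
      int i1 = (int)(unif_rand() * c); if (i1 >= c) i1 = c - 1;
      int i2 = (int)(unif_rand() * (c - 1)); if (i2 >= c - 1) i2 = c - 2;
      if (i2 >= i1) ++i2;
      int a = -1, b = -1, seen = 0;
      for (int i = 0; i < nact; ++i)
        if (deme[i] == which) {
          if (seen == i1) a = i;
          if (seen == i2) b = i;
          ++seen;
        }
      int id = next_id++;
      tr.time[id] = t;
      tr.parent[node[a]] = id;
      tr.parent[node[b]] = id;
      node[a] = id;
      --nact;
      node[b] = node[nact]; deme[b] = deme[nact];
      --cnt[which];
    } else {
      const std::vector<double>& mg = M.migs[mig_id];
      double u = unif_rand() * mrate, acc = 0.0;
      int k = npop - 1;
      for (int kk = 0; kk < npop; ++kk) {
        acc += cnt[kk] * rs[kk];
        if (u <= acc) { k = kk; break; }
      }
      int c = cnt[k];
      int pick = (int)(unif_rand() * c); if (pick >= c) pick = c - 1;
      int li = -1, seen = 0;
      for (int i = 0; i < nact; ++i)
        if (deme[i] == k) { if (seen == pick) { li = i; break; } ++seen; }
      double u2 = unif_rand() * rs[k], acc2 = 0.0;
      int dest = -1;
      for (int j = 0; j < npop; ++j) {
        acc2 += mg[k * npop + j];
        if (u2 <= acc2 && mg[k * npop + j] > 0.0) { dest = j; break; }
      }
      if (dest < 0)
        for (int j = npop - 1; j >= 0; --j)
          if (mg[k * npop + j] > 0) { dest = j; break; }
      --cnt[k]; ++cnt[dest];
      deme[li] = dest;
    }
  }
}

} // namespace

// One genealogy, fully materialized. Parent ids exceed child ids; leaves are
// nodes 0..n-1 at time 0.
// [[Rcpp::export]]
List cpp_simulate_genealogy(List model, double tmax) {
  Model M = parse_model(model);
  Tree tr;
  simulate_tree(M, tr, tmax);
  const int nnode = 2 * tr.n - 1, npop = M.npop;
  IntegerMatrix desc(nnode, npop);
  for (int i = 0; i < tr.n; ++i) desc(i, tr.leaf_deme[i]) = 1;
  NumericVector blen(nnode);
  IntegerVector entry(nnode, -1);
  for (int v = 0; v < nnode - 1; ++v) {  // parent id > child id
    int p = tr.parent[v];
    for (int k = 0; k < npop; ++k) desc(p, k) += desc(v, k);
    int idx = 0;
    for (int k = 0; k < npop; ++k) idx += desc(v, k) * M.stride[k];
    entry[v] = idx;
    blen[v] = tr.time[p] - tr.time[v];
  }
  return List::create(
      _["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
      _["node_time"] = NumericVector(tr.time.begin(), tr.time.end()),
      _["leaf_deme"] = IntegerVector(tr.leaf_deme.begin(),
                                     tr.leaf_deme.end()),
      _["branch_length"] = blen,
      _["descent"] = desc,
      _["entry"] = entry);
}

// Ascertainment subtree of a supplied genealogy (0-based parent vector,
// -1 at the root). The two lineages are chosen here so the draw shares the
// package RNG stream. Returns the chosen leaves and branch membership.
// [[Rcpp::export]]
List cpp_ascertain_subtree(IntegerVector parent, NumericVector node_time,
                           IntegerVector leaf_deme, int deme) {
  int n = leaf_deme.size();
  int nnode = 2 * n - 1;
  std::vector<int> cand;
  for (int i = 0; i < n; ++i) if (leaf_deme[i] == deme) cand.push_back(i);
  int c = (int)cand.size();
  int i1 = (int)(unif_rand() * c); if (i1 >= c) i1 = c - 1;
  int i2 = (int)(unif_rand() * (c - 1)); if (i2 >= c - 1) i2 = c - 2;
  if (i2 >= i1) ++i2;
  int l1 = cand[i1], l2 = cand[i2];
  std::vector<char> mark(nnode, 0), in_sub(nnode, 0);
  for (int v = l1; v != -1; v = parent[v]) mark[v] = 1;
  int mrca = l2;
  while (!mark[mrca]) mrca = parent[mrca];
  for (int v = l1; v != mrca; v = parent[v]) in_sub[v] = 1;
  for (int v = l2; v != mrca; v = parent[v]) in_sub[v] = 1;
  return List::create(
      _["in_subtree"] = LogicalVector(in_sub.begin(), in_sub.end()),
      _["leaves"] = IntegerVector::create(l1, l2));
}
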