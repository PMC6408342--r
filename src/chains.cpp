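#include <Rcpp.h>
using namespace Rcpp;

// Swap-chain kernels. Both chains draw with R's RNG (unif_rand), so
// set.seed() in R fully determines a run.

static inline int draw(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Fixed-fixed bipartite chain. vals is modified in place on a copy.
// rule: 0 = product acceptance (or uninformed when P is NULL),
//       1 = Metropolis ratio (created over destroyed).
// record: store the state after every trial as a column-major bit key
// (requires n*m <= 30; enforced by the R wrapper).
// [[Rcpp::export(name = ".chain_bipartite_cpp")]]
List chain_bipartite_cpp(IntegerMatrix vals_, Nullable<NumericMatrix> P_,
                         double target_accepted, double max_trials,
                         int rule, bool record) {
  IntegerMatrix vals = clone(vals_);
  int n = vals.nrow(), m = vals.ncol();
  bool informed = P_.isNotNull();
  NumericMatrix P = informed ? NumericMatrix(P_) : NumericMatrix(1, 1);

  std::vector<int> li, lj;
  for (int c = 0; c < m; ++c)
    for (int r = 0; r < n; ++r)
      if (vals(r, c) == 1) { li.push_back(r); lj.push_back(c); }
  int L = (int)li.size();

  double accepted = 0, trials = 0;
  IntegerVector keys(record ? (int)max_trials : 0);
  long key = 0;
  if (record)
    for (int c = 0; c < m; ++c)
      for (int r = 0; r < n; ++r)
        if (vals(r, c) == 1) key |= 1L << (c * n + r);

  if (L >= 2) {
    while (trials < max_trials && accepted < target_accepted) {
      int t = (int)trials;
      trials += 1;
      int a = draw(L);
      int b = draw(L - 1);
      if (b >= a) ++b;
      int i = li[a], j = lj[a], l = li[b], mm = lj[b];
      if (i != l && j != mm && vals(i, mm) == 0 && vals(l, j) == 0) {
        bool acc;
        if (!informed) {
          acc = true;
        } else if (rule == 0) {
          acc = unif_rand() < P(i, mm) * P(l, j);
        } else {
          double ratio = (P(i, mm) * P(l, j)) / (P(i, j) * P(l, mm));
          acc = unif_rand() < std::min(1.0, ratio);
        }
        if (acc) {
          vals(i, j) = 0; vals(l, mm) = 0;
          vals(i, mm) = 1; vals(l, j) = 1;
          lj[a] = mm; lj[b] = j;
          accepted += 1;
          if (record) {
            key &= ~(1L << (j * n + i));
            key &= ~(1L << (mm * n + l));
            key |= 1L << (mm * n + i);
            key |= 1L << (j * n + l);
          }
        }
      }
      if (record) keys[t] = (int)key;
    }
  }
  if (record) keys = head(keys, (int)trials);
  return List::create(_["vals"] = vals, _["accepted"] = accepted,
                      _["trials"] = trials,
                      _["cap_hit"] = trials >= max_trials && accepted < target_accepted,
                      _["keys"] = keys);
}

// Food-web chain: swaps within link classes only (singles with singles,
// doubles as unordered pairs with doubles, cannibal self-loops frozen),
// preserving in/out degrees and single/double/cannibal counts exactly.
// [[Rcpp::export(name = ".chain_foodweb_cpp")]]
List chain_foodweb_cpp(IntegerMatrix vals_, Nullable<NumericMatrix> P_,
                       double target_accepted, double max_trials, int rule) {
  IntegerMatrix vals = clone(vals_);
  int n = vals.nrow();
  bool informed = P_.isNotNull();
  NumericMatrix P = informed ? NumericMatrix(P_) : NumericMatrix(1, 1);

  std::vector<int> si, sj, di, dj;   // singles (i -> j), doubles (i < j)
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      if (vals(i, j) == 1 && vals(j, i) == 0) { si.push_back(i); sj.push_back(j); }
      if (i < j && vals(i, j) == 1 && vals(j, i) == 1) { di.push_back(i); dj.push_back(j); }
    }
  int nS = (int)si.size(), nD = (int)di.size();
  double accepted = 0, trials = 0;

  if (nS + nD >= 2) {
    while (trials < max_trials && accepted < target_accepted) {
      trials += 1;
      int a = draw(nS + nD);
      int b = draw(nS + nD - 1);
      if (b >= a) ++b;
      if (a < nS && b < nS) {
        // single-single: (i->j), (l->m)  =>  (i->m), (l->j)
        int i = si[a], j = sj[a], l = si[b], mm = sj[b];
        bool ok = i != l && j != mm && i != mm && l != j &&
          vals(i, mm) == 0 && vals(mm, i) == 0 &&
          vals(l, j) == 0 && vals(j, l) == 0;
        if (ok) {
          bool acc;
          if (!informed) acc = true;
          else if (rule == 0) acc = unif_rand() < P(i, mm) * P(l, j);
          else {
            double ratio = (P(i, mm) * P(l, j)) / (P(i, j) * P(l, mm));
            acc = unif_rand() < std::min(1.0, ratio);
          }
          if (acc) {
            vals(i, j) = 0; vals(l, mm) = 0;
            vals(i, mm) = 1; vals(l, j) = 1;
            sj[a] = mm; sj[b] = j;
            accepted += 1;
          }
        }
      } else if (a >= nS && b >= nS) {
        // double-double, node-disjoint, random pairing orientation
        int p = a - nS, q = b - nS;
        int d1a = di[p], d1b = dj[p], d2a = di[q], d2b = dj[q];
        if (d1a != d2a && d1a != d2b && d1b != d2a && d1b != d2b) {
          if (unif_rand() < 0.5) std::swap(d2a, d2b);
          // proposed new doubles {d1a, d2b} and {d1b, d2a}
          bool ok = vals(d1a, d2b) == 0 && vals(d2b, d1a) == 0 &&
            vals(d1b, d2a) == 0 && vals(d2a, d1b) == 0;
          if (ok) {
            bool acc;
            if (!informed) acc = true;
            else {
              double pc = P(d1a, d2b) * P(d2b, d1a) * P(d1b, d2a) * P(d2a, d1b);
              if (rule == 0) acc = unif_rand() < pc;
              else {
                double pd = P(d1a, d1b) * P(d1b, d1a) * P(d2a, d2b) * P(d2b, d2a);
                acc = unif_rand() < std::min(1.0, pc / pd);
              }
            }
            if (acc) {
              vals(d1a, d1b) = 0; vals(d1b, d1a) = 0;
              vals(d2a, d2b) = 0; vals(d2b, d2a) = 0;
              vals(d1a, d2b) = 1; vals(d2b, d1a) = 1;
              vals(d1b, d2a) = 1; vals(d2a, d1b) = 1;
              di[p] = std::min(d1a, d2b); dj[p] = std::max(d1a, d2b);
              di[q] = std::min(d1b, d2a); dj[q] = std::max(d1b, d2a);
              accepted += 1;
            }
          }
        }
      }
      // mixed single/double draws are invalid trials
    }
  }
  return List::create(_["vals"] = vals, _["accepted"] = accepted,
                      _["trials"] = trials,
                      _["cap_hit"] = trials >= max_trials && accepted < target_accepted);
}
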