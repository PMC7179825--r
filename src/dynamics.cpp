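#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Draw `spb` distinct unit indices in [1, upc] using R's RNG (rejection
// sampling; spb << upc in all realistic configs).
static inline void sample_distinct(int upc, int spb, int *out) {
  for (int k = 0; k < spb; ++k) {
    int v;
    bool dup;
    do {
      v = (int)(unif_rand() * upc) + 1;
      if (v > upc) v = upc;
      dup = false;
      for (int j = 0; j < k; ++j)
        if (out[j] == v) { dup = true; break; }
    } while (dup);
    out[k] = v;
  }
}

// Potential-synapse wiring for one pathway. `links` is an n_columns x
// n_linked matrix of 1-based source-column ids (one branch per linked
// column). Every unit of every column gets its own independent draw of
// `spb` distinct presynaptic units inside each linked column. Returns an
// (n_columns * upc) x (n_linked * spb) matrix of global presynaptic unit
// ids; row r is post unit r (1-based: column (r-1)/upc + 1).
// [[Rcpp::export]]
IntegerMatrix cpp_wire_branches(IntegerMatrix links, int upc, int spb) {
  const int n_cols = links.nrow(), n_linked = links.ncol();
  const int n_post = n_cols * upc;
  IntegerMatrix pre(n_post, n_linked * spb);
  RNGScope scope;
  std::vector<int> buf(spb > 0 ? spb : 1);
  for (int pc = 0; pc < n_cols; ++pc) {
    for (int u = 0; u < upc; ++u) {
      const int row = pc * upc + u;
      for (int b = 0; b < n_linked; ++b) {
        const int src = links(pc, b);
        sample_distinct(upc, spb, buf.data());
        for (int k = 0; k < spb; ++k)
          pre(row, b * spb + k) = (src - 1) * upc + buf[k];
      }
    }
  }
  return pre;
}

// Best-branch overlap per post unit. A branch spikes when it holds at least
// `branch_thr` synapses that are simultaneously established (weight >=
// est_thr) and presynaptically active. Branches are independent: counts are
// never summed across branches. Returns, per post unit, the largest
// active-established count among spiking branches (0 if no branch spikes).
// [[Rcpp::export]]
IntegerVector cpp_branch_overlap(IntegerMatrix pre, NumericMatrix w,
                                 IntegerVector active, int n_source_units,
                                 double est_thr, int branch_thr, int spb) {
  const int n_post = pre.nrow(), n_syn = pre.ncol();
  std::vector<char> mask(n_source_units + 1, 0);
  for (int i = 0; i < active.size(); ++i) mask[active[i]] = 1;
  IntegerVector best(n_post);
  if (n_syn == 0 || active.size() == 0) return best;
  for (int r = 0; r < n_post; ++r) {
    int b_best = 0;
    for (int s = 0; s < n_syn; s += spb) {
      int cnt = 0;
      for (int k = 0; k < spb; ++k) {
        const int c = s + k;
        if (w(r, c) >= est_thr && mask[pre(r, c)]) ++cnt;
      }
      if (cnt >= branch_thr && cnt > b_best) b_best = cnt;
    }
    best[r] = b_best;
  }
  return best;
}

// STDP-like update, in place, restricted to rows of currently active post
// units. Presynaptic in the past source set -> potentiate w += lr*(1-w);
// presynaptic simultaneously active only -> depress w *= (1-lr); a unit in
// both sets potentiates (past-pairing wins). All other synapses untouched.
// [[Rcpp::export]]
void cpp_plasticity(IntegerMatrix pre, NumericMatrix w,
                    IntegerVector post_active, IntegerVector past_active,
                    IntegerVector curr_active, int n_source_units, double lr) {
  const int n_syn = pre.ncol();
  if (n_syn == 0 || post_active.size() == 0) return;
  std::vector<char> past(n_source_units + 1, 0), curr(n_source_units + 1, 0);
  for (int i = 0; i < past_active.size(); ++i) past[past_active[i]] = 1;
  for (int i = 0; i < curr_active.size(); ++i) curr[curr_active[i]] = 1;
  for (int i = 0; i < post_active.size(); ++i) {
    const int r = post_active[i] - 1;
    for (int c = 0; c < n_syn; ++c) {
      const int p = pre(r, c);
      if (past[p])
        w(r, c) += lr * (1.0 - w(r, c));
      else if (curr[p])
        w(r, c) *= (1.0 - lr);
    }
  }
}

// Sequential weighted sampling without replacement (the classic scheme:
// each draw is proportional to the remaining weights), using R's RNG.
// Returns k 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_weighted_sample(NumericVector w, int k) {
  const int n = w.size();
  RNGScope scope;
  std::vector<double> ww(w.begin(), w.end());
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += ww[i];
  IntegerVector out(k);
  for (int d = 0; d < k; ++d) {
    double u = unif_rand() * total;
    double acc = 0.0;
    int pick = -1;
    for (int i = 0; i < n; ++i) {
      if (ww[i] <= 0.0) continue;
      acc += ww[i];
      if (u <= acc) { pick = i; break; }
    }
    if (pick < 0) { // numerical tail: last positive weight
      for (int i = n - 1; i >= 0; --i)
        if (ww[i] > 0.0) { pick = i; break; }
    }
    out[d] = pick + 1;
    total -= ww[pick];
    ww[pick] = 0.0;
  }
  return out;
}

// Per-column excited-cluster selection plus winner-take-all inhibition for
// one word event. exc: upc x n_cols excitations; ov: per-unit best branch
// overlap (0 = not predicted). Returns the active global unit ids and the
// per-column MFE flags. Stochastic mode draws the excited cluster with
// weights exp(beta * (e - max e) / sd(e)); deterministic mode takes the
// top-k (ties to the lowest unit index). SDR winners are the
// winners_per_cc predicted-and-excited units ranked by (overlap,
// excitation, lowest id).
// [[Rcpp::export]]
List cpp_select_active(NumericMatrix exc, IntegerVector ov, int k,
                       int winners, int sdr_min, bool stochastic,
                       double beta) {
  const int upc = exc.nrow(), n_cols = exc.ncol();
  RNGScope scope;
  std::vector<int> active;
  active.reserve(n_cols * k);
  LogicalVector mfe(n_cols);
  std::vector<int> excited(k);
  std::vector<int> idx(upc);
  std::vector<double> ww(upc);
  for (int c = 0; c < n_cols; ++c) {
    // select the excited cluster
    if (k >= upc) {
      for (int u = 0; u < upc; ++u) excited[u] = u;
    } else if (!stochastic) {
      for (int u = 0; u < upc; ++u) idx[u] = u;
      std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                        [&](int a, int b) {
                          double ea = exc(a, c), eb = exc(b, c);
                          if (ea != eb) return ea > eb;
                          return a < b;
                        });
      for (int d = 0; d < k; ++d) excited[d] = idx[d];
    } else {
      double mx = exc(0, c), mean = 0.0;
      for (int u = 0; u < upc; ++u) {
        if (exc(u, c) > mx) mx = exc(u, c);
        mean += exc(u, c);
      }
      mean /= upc;
      double var = 0.0;
      for (int u = 0; u < upc; ++u) {
        double d = exc(u, c) - mean;
        var += d * d;
      }
      double s = std::sqrt(var / (upc - 1));
      double total = 0.0;
      if (s > 0.0) {
        for (int u = 0; u < upc; ++u) {
          ww[u] = std::exp(beta * (exc(u, c) - mx) / s);
          total += ww[u];
        }
      } else {
        for (int u = 0; u < upc; ++u) { ww[u] = 1.0; total += 1.0; }
      }
      for (int d = 0; d < k; ++d) {
        double u01 = unif_rand() * total;
        double acc = 0.0;
        int pick = -1;
        for (int u = 0; u < upc; ++u) {
          if (ww[u] <= 0.0) continue;
          acc += ww[u];
          if (u01 <= acc) { pick = u; break; }
        }
        if (pick < 0)
          for (int u = upc - 1; u >= 0; --u)
            if (ww[u] > 0.0) { pick = u; break; }
        excited[d] = pick;
        total -= ww[pick];
        ww[pick] = 0.0;
      }
    }
    // predicted-and-excited
    const int base = c * upc;
    std::vector<int> P;
    P.reserve(k);
    for (int d = 0; d < k; ++d) {
      int g = base + excited[d] + 1;
      if (ov[g - 1] > 0) P.push_back(g);
    }
    if ((int)P.size() >= sdr_min) {
      std::sort(P.begin(), P.end(), [&](int a, int b) {
        if (ov[a - 1] != ov[b - 1]) return ov[a - 1] > ov[b - 1];
        double ea = exc(a - 1 - base, c), eb = exc(b - 1 - base, c);
        if (ea != eb) return ea > eb;
        return a < b;
      });
      int take = std::min((int)P.size(), winners);
      for (int d = 0; d < take; ++d) active.push_back(P[d]);
    } else {
      mfe[c] = true;
      for (int d = 0; d < k; ++d) active.push_back(base + excited[d] + 1);
    }
  }
  std::sort(active.begin(), active.end());
  return List::create(Named("active") = wrap(active),
                      Named("mfe") = mfe);
}

// In-place Kohonen update of every column's SOM towards its sampled input.
// Wt: list of n_inputs x upc matrices (mutated); X: n_inputs x n_cols;
// exc: upc x n_cols (for BMU lookup, ties to the lowest index);
// d2: upc x upc squared lattice distances.
// [[Rcpp::export]]
void cpp_som_update_all(List Wt, NumericMatrix X, NumericMatrix exc,
                        double alpha, double sigma, NumericMatrix d2) {
  if (alpha <= 0) return;
  const int n_cols = Wt.size();
  NumericMatrix W0 = Wt[0];
  const int n_in = W0.nrow(), upc = W0.ncol();
  const double denom = 2.0 * sigma * sigma;
  for (int c = 0; c < n_cols; ++c) {
    NumericMatrix W = Wt[c];
    int bmu = 0;
    double best = exc(0, c);
    for (int u = 1; u < upc; ++u)
      if (exc(u, c) > best) { best = exc(u, c); bmu = u; }
    for (int u = 0; u < upc; ++u) {
      const double ah = alpha * std::exp(-d2(u, bmu) / denom);
      if (ah <= 0.0) continue;
      for (int i = 0; i < n_in; ++i)
        W(i, u) += ah * (X(i, c) - W(i, u));
    }
  }
}

// Afferent SOM response for every column at once. Wt: list of
// n_inputs x upc weight matrices (one per column, units in columns);
// X: n_inputs x n_columns matrix of sampled input components. Returns
// upc x n_columns excitations (negated Euclidean distance).
// [[Rcpp::export]]
NumericMatrix cpp_som_response_all(List Wt, NumericMatrix X) {
  const int n_cols = Wt.size();
  NumericMatrix W0 = Wt[0];
  const int n_in = W0.nrow(), upc = W0.ncol();
  NumericMatrix exc(upc, n_cols);
  for (int c = 0; c < n_cols; ++c) {
    NumericMatrix W = Wt[c];
    for (int u = 0; u < upc; ++u) {
      double s = 0.0;
      for (int i = 0; i < n_in; ++i) {
        const double d = W(i, u) - X(i, c);
        s += d * d;
      }
      exc(u, c) = -std::sqrt(s);
    }
  }
  return exc;
}
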