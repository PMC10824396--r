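// Hot loop of the single-site annealer. The energy is fully described by
// two tables precomputed in R:
//   local(t, s)     = (1 - alpha) * (e_conf + e_pred) for epoch t, stage s
//   transE(a, b)    = alpha * e_trans(a -> b)
// Epoch energy: E(t) = transE(s[t-1], s[t]) + transE(s[t], s[t+1]) +
// local(t, s[t]), with boundary terms omitted. All randomness comes from
// R's RNG (unif_rand), so set.seed() in R makes runs bit-identical.
#include <Rcpp.h>
using namespace Rcpp;

static inline double epoch_e(const NumericMatrix& local,
                             const NumericMatrix& transE,
                             const std::vector<int>& s, int t, int T) {
  double e = local(t, s[t]);
  if (t > 0) e += transE(s[t - 1], s[t]);
  if (t < T - 1) e += transE(s[t], s[t + 1]);
  return e;
}

// [[Rcpp::export]]
List anneal_cpp(NumericMatrix local, NumericMatrix transE,
                IntegerVector init, NumericVector betas,
                bool sign_effective, bool uniform_positions,
                bool record_states) {
  const int T = init.size();
  const int K = betas.size();
  std::vector<int> s(init.begin(), init.end());
  std::vector<double> eep(T);
  for (int t = 0; t < T; ++t) eep[t] = epoch_e(local, transE, s, t, T);
  double total = 0.0;
  for (int t = 0; t < T; ++t) total += eep[t];

  std::vector<int> best(s);
  double best_total = total;
  const double init_total = total;
  NumericVector trace(K);
  IntegerVector positions(K), old_stages(K), new_stages(K);
  IntegerVector states;
  if (record_states) states = IntegerVector(K);
  int accepted = 0;
  std::vector<double> w(T);
  const double sgn = sign_effective ? 1.0 : -1.0;

  for (int k = 0; k < K; ++k) {
    const double beta = betas[k];
    // --- position selection: softmax over per-epoch energies -----------
    int pos;
    if (uniform_positions) {
      pos = (int)(unif_rand() * T);
      if (pos >= T) pos = T - 1;
    } else {
      double mx = -HUGE_VAL;
      for (int t = 0; t < T; ++t) {
        w[t] = sgn * beta * eep[t];
        if (w[t] > mx) mx = w[t];
      }
      double z = 0.0;
      for (int t = 0; t < T; ++t) { w[t] = std::exp(w[t] - mx); z += w[t]; }
      double u = unif_rand() * z, c = 0.0;
      pos = T - 1;
      for (int t = 0; t < T; ++t) { c += w[t]; if (u <= c) { pos = t; break; } }
    }
    // --- stage proposal: 5-way softmax of -beta * deltaE ----------------
    const int cur = s[pos];
    double d[5];
    double dmin = 0.0;
    for (int c5 = 0; c5 < 5; ++c5) {
      if (c5 == cur) { d[c5] = 0.0; continue; }
      double dd = local(pos, c5) - local(pos, cur);
      if (pos > 0) dd += 2.0 * (transE(s[pos - 1], c5) - transE(s[pos - 1], cur));
      if (pos < T - 1) dd += 2.0 * (transE(c5, s[pos + 1]) - transE(cur, s[pos + 1]));
      d[c5] = dd;
      if (dd < dmin) dmin = dd;
    }
    double pw[5], z5 = 0.0;
    for (int c5 = 0; c5 < 5; ++c5) { pw[c5] = std::exp(-beta * (d[c5] - dmin)); z5 += pw[c5]; }
    double u5 = unif_rand() * z5, cc = 0.0;
    int nw = 4;
    for (int c5 = 0; c5 < 5; ++c5) { cc += pw[c5]; if (u5 <= cc) { nw = c5; break; } }
    // --- apply and patch the epoch-energy cache -------------------------
    if (nw != cur) {
      s[pos] = nw;
      double delta = 0.0;
      for (int t = std::max(0, pos - 1); t <= std::min(T - 1, pos + 1); ++t) {
        double e_new = epoch_e(local, transE, s, t, T);
        delta += e_new - eep[t];
        eep[t] = e_new;
      }
      total += delta;
      ++accepted;
      if (total < best_total) { best_total = total; best = s; }
    }
    trace[k] = total;
    positions[k] = pos + 1;  // 1-based for R
    old_stages[k] = cur;
    new_stages[k] = nw;
    if (record_states) {
      int code = 0, p5 = 1;
      for (int t = 0; t < T; ++t) { code += s[t] * p5; p5 *= 5; }
      states[k] = code;
    }
  }

  return List::create(
    _["final_state"] = IntegerVector(s.begin(), s.end()),
    _["best_state"] = IntegerVector(best.begin(), best.end()),
    _["energy_trace"] = trace,
    _["positions"] = positions,
    _["old_stages"] = old_stages,
    _["new_stages"] = new_stages,
    _["best_energy"] = best_total,
    _["initial_energy"] = init_total,
    _["accepted_moves"] = accepted,
    _["state_trace"] = record_states ? (SEXP)states : R_NilValue);
}
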