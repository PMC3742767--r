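#include <Rcpp.h>
using namespace Rcpp;

// Simulated-annealing core for the minimum-set problem: single-unit
// add/remove moves, Boltzmann acceptance, geometric cooling. Objective:
// sum(cost[selected]) + sum_f spf[f] * max(0, target[f] - held[f]).
// Uses R's RNG so runs are reproducible from set.seed().

static double penalty(const NumericVector& spf, const NumericVector& target,
                      const NumericVector& held) {
  double p = 0.0;
  for (int f = 0; f < spf.size(); ++f) {
    double sh = target[f] - held[f];
    if (sh > 0) p += spf[f] * sh;
  }
  return p;
}

// [[Rcpp::export(name = ".anneal_core")]]
List anneal_core(NumericMatrix amount,   // features x units
                 NumericVector cost,     // per unit
                 NumericVector target,   // per feature (absolute amounts)
                 NumericVector spf,      // per feature
                 LogicalVector init,     // starting selection
                 int n_moves, double t0, double cooling) {
  int nf = amount.nrow(), nu = amount.ncol();
  LogicalVector sel = clone(init);
  NumericVector held(nf);
  double cost_sum = 0.0;
  for (int u = 0; u < nu; ++u) {
    if (sel[u]) {
      cost_sum += cost[u];
      for (int f = 0; f < nf; ++f) held[f] += amount(f, u);
    }
  }
  double obj = cost_sum + penalty(spf, target, held);
  LogicalVector best = clone(sel);
  double best_obj = obj;
  double temp = t0;
  NumericVector held_new(nf);
  for (int it = 0; it < n_moves; ++it) {
    int u = (int)(unif_rand() * nu);
    if (u == nu) u = nu - 1;
    double delta = sel[u] ? -cost[u] : cost[u];
    // penalty change from toggling unit u
    double dpen = 0.0;
    for (int f = 0; f < nf; ++f) {
      double a = amount(f, u);
      if (a == 0) continue;
      double h_old = held[f];
      double h_new = sel[u] ? h_old - a : h_old + a;
      double p_old = target[f] - h_old; if (p_old < 0) p_old = 0;
      double p_new = target[f] - h_new; if (p_new < 0) p_new = 0;
      dpen += spf[f] * (p_new - p_old);
    }
    delta += dpen;
    if (delta <= 0 || unif_rand() < std::exp(-delta / temp)) {
      if (sel[u]) {
        cost_sum -= cost[u];
        for (int f = 0; f < nf; ++f) held[f] -= amount(f, u);
      } else {
        cost_sum += cost[u];
        for (int f = 0; f < nf; ++f) held[f] += amount(f, u);
      }
      sel[u] = !sel[u];
      obj += delta;
      if (obj < best_obj) {
        best_obj = obj;
        best = clone(sel);
      }
    }
    temp *= cooling;
    if (temp < 1e-12) temp = 1e-12;
  }
  return List::create(_["selection"] = best, _["objective"] = best_obj,
                      _["final_selection"] = sel, _["final_objective"] = obj);
}
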