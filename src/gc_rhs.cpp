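// Mass-action + trafficking right-hand side kernel.
//
// State layout (0-based): [0, n_sp)   surface receptor species (#/cell)
//                         [n_sp,2n_sp) endosomal species (area-normalized)
//                         then endosomal free ligand (nM), then clamped
//                         extracellular ligand (nM).
// All index vectors arrive 0-based from R. Tiny negative entries produced
// by the integrator are clamped to zero before flux evaluation so the
// right-hand side stays structurally positive.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// ---- model block shared with the direct deSolve entry point --------------
// gc_set_model() copies the prepared parameter list into plain C++ storage;
// gc_derivs() is the derivs() signature deSolve calls when given
// func = "gc_derivs", dllname = "gckin" (no R callback per solver step).
namespace {
struct GcModel {
  int n_sp = 0;
  std::vector<int> bind_rec, bind_prod, bind_xlig, bind_elig;
  std::vector<int> dim_a, dim_b, dim_p, elig_idx;
  std::vector<double> krevs_b, kreve_b, krevs_d, kreve_d;
  std::vector<double> k_in, rec_rate, endo_loss, syn;
  double kbnd = 0, kfwd = 0, phi = 0.5, c2n = 0, kdeg = 0;
};
GcModel M;

inline void gc_rhs_core(const GcModel& m, const double* y, double* d) {
  const int n_sp = m.n_sp;
  std::vector<double> ys(n_sp), ye(n_sp);
  for (int i = 0; i < n_sp; ++i) {
    ys[i] = y[i] > 0 ? y[i] : 0.0;
    ye[i] = y[n_sp + i] > 0 ? y[n_sp + i] : 0.0;
  }
  const int ntot = 2 * n_sp + 2 * (int)m.elig_idx.size();
  for (int i = 0; i < ntot; ++i) d[i] = 0.0;

  for (size_t j = 0; j < m.bind_rec.size(); ++j) {
    const int r = m.bind_rec[j], p = m.bind_prod[j];
    const double Ls = y[m.bind_xlig[j]];
    const double Le = y[m.bind_elig[j]] > 0 ? y[m.bind_elig[j]] : 0.0;
    const double fs = m.kbnd * Ls * ys[r] - m.krevs_b[j] * ys[p];
    const double fe = m.kbnd * Le * ye[r] - m.kreve_b[j] * ye[p];
    d[r] -= fs;          d[p] += fs;
    d[n_sp + r] -= fe;   d[n_sp + p] += fe;
    d[m.bind_elig[j]] -= m.phi * m.c2n * fe;
  }
  for (size_t j = 0; j < m.dim_a.size(); ++j) {
    const int a = m.dim_a[j], b = m.dim_b[j], p = m.dim_p[j];
    const double fs = m.kfwd * ys[a] * ys[b] - m.krevs_d[j] * ys[p];
    const double fe = m.kfwd * ye[a] * ye[b] - m.kreve_d[j] * ye[p];
    d[a] -= fs;          d[b] -= fs;          d[p] += fs;
    d[n_sp + a] -= fe;   d[n_sp + b] -= fe;   d[n_sp + p] += fe;
  }
  for (int i = 0; i < n_sp; ++i) {
    d[i] += -m.k_in[i] * ys[i] + m.rec_rate[i] * m.phi * ye[i] + m.syn[i];
    d[n_sp + i] += m.k_in[i] / m.phi * ys[i] - m.endo_loss[i] * ye[i];
  }
  for (size_t j = 0; j < m.elig_idx.size(); ++j) {
    const int k = m.elig_idx[j];
    d[k] -= m.kdeg * (y[k] > 0 ? y[k] : 0.0);
  }
}
}  // namespace

void gc_set_model(List P) {
  M.n_sp = as<int>(P["n_sp"]);
  M.bind_rec = as<std::vector<int>>(P["bind_rec"]);
  M.bind_prod = as<std::vector<int>>(P["bind_prod"]);
  M.bind_xlig = as<std::vector<int>>(P["bind_xlig"]);
  M.bind_elig = as<std::vector<int>>(P["bind_elig"]);
  M.dim_a = as<std::vector<int>>(P["dim_a"]);
  M.dim_b = as<std::vector<int>>(P["dim_b"]);
  M.dim_p = as<std::vector<int>>(P["dim_p"]);
  M.elig_idx = as<std::vector<int>>(P["elig_idx"]);
  M.krevs_b = as<std::vector<double>>(P["krevs_b"]);
  M.kreve_b = as<std::vector<double>>(P["kreve_b"]);
  M.krevs_d = as<std::vector<double>>(P["krevs_d"]);
  M.kreve_d = as<std::vector<double>>(P["kreve_d"]);
  M.k_in = as<std::vector<double>>(P["k_in"]);
  M.rec_rate = as<std::vector<double>>(P["rec_rate"]);
  M.endo_loss = as<std::vector<double>>(P["endo_loss"]);
  M.syn = as<std::vector<double>>(P["syn"]);
  M.kbnd = as<double>(P["kbnd"]);
  M.kfwd = as<double>(P["kfwd"]);
  M.phi = as<double>(P["phi"]);
  M.c2n = as<double>(P["c2n"]);
  M.kdeg = as<double>(P["kdeg"]);
}

extern "C" void gc_derivs(int* neq, double* t, double* y, double* ydot,
                          double* yout, int* ip) {
  (void)neq; (void)t; (void)yout; (void)ip;
  gc_rhs_core(M, y, ydot);
}

NumericVector gc_deriv_cpp(NumericVector y, List P) {
  const int n_sp = as<int>(P["n_sp"]);
  const IntegerVector bind_rec = P["bind_rec"], bind_prod = P["bind_prod"],
      bind_xlig = P["bind_xlig"], bind_elig = P["bind_elig"],
      dim_a = P["dim_a"], dim_b = P["dim_b"], dim_p = P["dim_p"];
  const NumericVector krevs_b = P["krevs_b"], kreve_b = P["kreve_b"],
      krevs_d = P["krevs_d"], kreve_d = P["kreve_d"],
      k_in = P["k_in"], rec_rate = P["rec_rate"], endo_loss = P["endo_loss"],
      syn = P["syn"];
  const double kbnd = as<double>(P["kbnd"]), kfwd = as<double>(P["kfwd"]),
      phi = as<double>(P["phi"]), c2n = as<double>(P["c2n"]),
      kdeg = as<double>(P["kdeg"]);
  const IntegerVector elig_idx = P["elig_idx"];

  const int n = y.size();
  NumericVector d(n);
  std::vector<double> ys(n_sp), ye(n_sp);
  for (int i = 0; i < n_sp; ++i) {
    ys[i] = y[i] > 0 ? y[i] : 0.0;
    ye[i] = y[n_sp + i] > 0 ? y[n_sp + i] : 0.0;
  }

  // ligand association / dissociation, both compartments
  for (int j = 0; j < bind_rec.size(); ++j) {
    const int r = bind_rec[j], p = bind_prod[j];
    const double Ls = y[bind_xlig[j]];
    const double Le = y[bind_elig[j]] > 0 ? y[bind_elig[j]] : 0.0;
    const double fs = kbnd * Ls * ys[r] - krevs_b[j] * ys[p];
    const double fe = kbnd * Le * ye[r] - kreve_b[j] * ye[p];
    d[r] -= fs;          d[p] += fs;
    d[n_sp + r] -= fe;   d[n_sp + p] += fe;
    d[bind_elig[j]] -= phi * c2n * fe;  // endosomal ligand mass balance
  }

  // receptor dimerization, both compartments
  for (int j = 0; j < dim_a.size(); ++j) {
    const int a = dim_a[j], b = dim_b[j], p = dim_p[j];
    const double fs = kfwd * ys[a] * ys[b] - krevs_d[j] * ys[p];
    const double fe = kfwd * ye[a] * ye[b] - kreve_d[j] * ye[p];
    d[a] -= fs;          d[b] -= fs;          d[p] += fs;
    d[n_sp + a] -= fe;   d[n_sp + b] -= fe;   d[n_sp + p] += fe;
  }

  // trafficking: dE = -kE + k_rec(1-f) I phi ; dI = kE/phi - (rec+deg f) I
  for (int i = 0; i < n_sp; ++i) {
    d[i] += -k_in[i] * ys[i] + rec_rate[i] * phi * ye[i];
    d[n_sp + i] += k_in[i] / phi * ys[i] - endo_loss[i] * ye[i];
    d[i] += syn[i];
  }

  // endosomal free ligand degrades (lysosomal sorting fraction 1);
  // extracellular ligand rows stay clamped at derivative zero
  for (int j = 0; j < elig_idx.size(); ++j) {
    const int k = elig_idx[j];
    d[k] -= kdeg * (y[k] > 0 ? y[k] : 0.0);
  }
  return d;
}
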