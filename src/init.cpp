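// Hand-written registration: the .Call entry points used from R plus the
// plain-C derivs routine that deSolve resolves by name ("gc_derivs").

#include <Rcpp.h>
#include <R_ext/Rdynload.h>

void gc_set_model(Rcpp::List P);
Rcpp::NumericVector gc_deriv_cpp(Rcpp::NumericVector y, Rcpp::List P);
extern "C" void gc_derivs(int* neq, double* t, double* y, double* ydot,
                          double* yout, int* ip);

extern "C" SEXP _gckin_gc_set_model(SEXP PSEXP) {
BEGIN_RCPP
  gc_set_model(Rcpp::List(PSEXP));
  return R_NilValue;
END_RCPP
}

extern "C" SEXP _gckin_gc_deriv_cpp(SEXP ySEXP, SEXP PSEXP) {
BEGIN_RCPP
  return Rcpp::wrap(gc_deriv_cpp(Rcpp::NumericVector(ySEXP),
                                 Rcpp::List(PSEXP)));
END_RCPP
}

static const R_CallMethodDef CallEntries[] = {
  {"_gckin_gc_set_model", (DL_FUNC) &_gckin_gc_set_model, 1},
  {"_gckin_gc_deriv_cpp", (DL_FUNC) &_gckin_gc_deriv_cpp, 2},
  {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
  {"gc_derivs", (DL_FUNC) &gc_derivs, 6},
  {NULL, NULL, 0}
};

extern "C" void R_init_gckin(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
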