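#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct method for the 11-reaction MOR network, recorded on a
// uniform grid by last-value carry-forward. Uses R's RNG so that set.seed()
// on the R side makes trajectories bit-reproducible.
//
// stoich:    n_species x n_reactions integer matrix
// reactants: n_reactions x 2 integer matrix (1-based species index, 0 = none)
static List ssa_core(IntegerMatrix stoich, IntegerMatrix reactants,
                     NumericVector rates, IntegerVector init,
                     double t_end, double grid_dt) {
  const int ns = stoich.nrow(), nr = stoich.ncol();
  const int ng = (int)(t_end / grid_dt + 1e-9) + 1;
  IntegerMatrix states(ng, ns);
  IntegerVector firings(nr);
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> f(nr);

  double t = 0.0;
  int gi = 0;
  RNGScope scope;
  while (gi < ng) {
    double ftot = 0.0;
    for (int j = 0; j < nr; ++j) {
      double fj = rates[j] * x[reactants(j, 0) - 1];
      if (reactants(j, 1) > 0) fj *= x[reactants(j, 1) - 1];
      f[j] = fj;
      ftot += fj;
    }
    if (!(ftot > 0.0)) break;  // frozen: remaining grid filled below
    if (!R_finite(ftot)) stop("propensity overflow at t = %g", t);
    double tau = ::Rf_rexp(1.0 / ftot);
    double t_next = t + tau;
    // record grid points passed before the jump
    while (gi < ng && gi * grid_dt <= t_next) {
      for (int s = 0; s < ns; ++s) states(gi, s) = (int)x[s];
      ++gi;
    }
    // choose reaction proportional to propensity
    double u = ::unif_rand() * ftot, acc = 0.0;
    int j = nr - 1;
    for (int jj = 0; jj < nr; ++jj) {
      acc += f[jj];
      if (u <= acc) { j = jj; break; }
    }
    for (int s = 0; s < ns; ++s) x[s] += stoich(s, j);
    ++firings[j];
    t = t_next;
  }
  for (; gi < ng; ++gi)
    for (int s = 0; s < ns; ++s) states(gi, s) = (int)x[s];
  return List::create(_["states"] = states, _["firings"] = firings);
}

RcppExport SEXP mornet_ssa_core(SEXP stoichS, SEXP reactantsS, SEXP ratesS,
                                SEXP initS, SEXP t_endS, SEXP grid_dtS) {
BEGIN_RCPP
  return wrap(ssa_core(IntegerMatrix(stoichS), IntegerMatrix(reactantsS),
                       NumericVector(ratesS), IntegerVector(initS),
                       as<double>(t_endS), as<double>(grid_dtS)));
END_RCPP
}
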