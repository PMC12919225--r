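#include <Rcpp.h>
using namespace Rcpp;

// Exact-jump (Gillespie) simulation of a Markov jump process.
// K is the dense V x V rate matrix (zero diagonal); start is a 0-based
// state index; tmax the duration.  Returns transition counts N (V x V) and
// dwell times T per state with sum(T) == tmax exactly (final dwell
// truncated).  Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List ssa_counts(NumericMatrix K, int start, double tmax) {
  const int V = K.nrow();
  NumericVector rowtot(V);
  for (int i = 0; i < V; ++i) {
    double s = 0.0;
    for (int j = 0; j < V; ++j) s += K(i, j);
    rowtot[i] = s;
  }
  NumericMatrix N(V, V);
  NumericVector T(V);
  int s = start;
  double t = 0.0;
  for (;;) {
    const double R = rowtot[s];
    if (R <= 0.0) {  // absorbing (cannot happen for validated networks)
      T[s] += tmax - t;
      break;
    }
    const double dt = R::exp_rand() / R;
    if (t + dt >= tmax) {
      T[s] += tmax - t;
      break;
    }
    T[s] += dt;
    t += dt;
    const double u = unif_rand() * R;
    double acc = 0.0;
    int j = V - 1;
    for (int c = 0; c < V; ++c) {
      acc += K(s, c);
      if (u <= acc) { j = c; break; }
    }
    N(s, j) += 1.0;
    s = j;
  }
  return List::create(_["N"] = N, _["T"] = T);
}
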