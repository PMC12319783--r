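#include <Rcpp.h>
using namespace Rcpp;

//' Leaky-accumulator Euler recursion
//'
//' Integrates x <- x + (I - k * x) * dt + noise[t] with x(0) = 0 and returns
//' the state after each step. `noise` is the fully scaled per-step stochastic
//' input (the caller applies the c and sqrt(dt)/dt scaling), so the same core
//' serves both the white-noise and the pink-noise-driven accumulator.
//'
//' @param noise numeric vector of per-step noise increments (already scaled)
//' @param I drift rate
//' @param k leak rate
//' @param dt step size in seconds
//' @return numeric vector of accumulator states, one per step
//' @keywords internal
// [[Rcpp::export]]
NumericVector euler_leaky(NumericVector noise, double I, double k, double dt) {
  R_xlen_t n = noise.size();
  NumericVector out(n);
  double x = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    x = x + (I - k * x) * dt + noise[i];
    out[i] = x;
  }
  return out;
}
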