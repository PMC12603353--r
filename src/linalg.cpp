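#include <Rcpp.h>

// Row-broadcast bias addition: returns M + 1 * b^T without the temporary
// allocations of rep()/sweep() in R; hot path of the training loop.
// [[Rcpp::export(name = ".add_bias")]]
Rcpp::NumericMatrix add_bias_cpp(Rcpp::NumericMatrix M, Rcpp::NumericVector b) {
  int nr = M.nrow(), nc = M.ncol();
  if (b.size() != nc) Rcpp::stop("bias length must equal ncol(M)");
  Rcpp::NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; j++) {
    double bj = b[j];
    const double* src = &M(0, j);
    double* dst = &out(0, j);
    for (int i = 0; i < nr; i++) dst[i] = src[i] + bj;
  }
  return out;
}
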