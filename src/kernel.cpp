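#include <Rcpp.h>
using namespace Rcpp;

//' Group sums of a circularly shifted series
//'
//' For each requested circular shift, accumulates the shifted values of
//' \code{v} into groups given by \code{idx}. Used as the hot loop of the
//' surrogate machinery: the modulation-index family only needs per-bin sums
//' of the (shifted) amplitude series, so all surrogate draws can share one
//' pass over the data.
//'
//' @param v numeric series (e.g. instantaneous amplitude).
//' @param idx 1-based group index per sample (phase bin or joint bin).
//' @param ngroups number of groups.
//' @param shifts integer circular shifts in samples (0 = observed).
//' @return matrix with \code{ngroups} rows and \code{length(shifts)} columns;
//'   column s holds the per-group sums of \code{v} circularly shifted by
//'   \code{shifts[s]}.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix shift_group_sums(NumericVector v, IntegerVector idx,
                               int ngroups, IntegerVector shifts) {
  int n = v.size();
  int ns = shifts.size();
  if (idx.size() != n) stop("`v` and `idx` must have the same length");
  NumericMatrix out(ngroups, ns);
  for (int s = 0; s < ns; ++s) {
    int sh = shifts[s] % n;
    if (sh < 0) sh += n;
    double *col = &out(0, s);
    for (int t = 0; t < n; ++t) {
      int src = t + sh;
      if (src >= n) src -= n;
      int g = idx[t];
      if (g < 1 || g > ngroups) stop("`idx` out of range");
      col[g - 1] += v[src];
    }
  }
  return out;
}

//' Group counts
//'
//' Tabulates 1-based group indices; shift-invariant companion of
//' \code{shift_group_sums}.
//'
//' @param idx 1-based group index per sample.
//' @param ngroups number of groups.
//' @return integer vector of counts per group.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector group_counts(IntegerVector idx, int ngroups) {
  IntegerVector out(ngroups);
  for (int t = 0; t < idx.size(); ++t) {
    int g = idx[t];
    if (g < 1 || g > ngroups) stop("`idx` out of range");
    out[g - 1] += 1;
  }
  return out;
}
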