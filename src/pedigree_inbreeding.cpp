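#include <Rcpp.h>
using namespace Rcpp;

// Pedigree inbreeding by the Meuwissen & Luo (1992) scheme: for each
// non-founder the L-rows of sire and dam are accumulated over the ancestor
// list in one downward sweep, and F = 0.5 * sum_k L_sk * L_dk * d_k with
// d_k the Mendelian-sampling variance of ancestor k.
//
// sire/dam are 1-based ids with 0 = unknown; parents must precede offspring.
// f_known carries already-computed coefficients for the first animals so the
// simulation engine can extend F incrementally as litters are appended.
// [[Rcpp::export]]
NumericVector ped_inbreeding_cpp(IntegerVector sire, IntegerVector dam,
                                 NumericVector f_known) {
  int n = sire.size();
  int start = f_known.size();
  if (start > n) stop("more known coefficients than animals");
  NumericVector F(n);
  for (int i = 0; i < start; ++i) F[i] = f_known[i];

  std::vector<double> ws(n, 0.0), wd(n, 0.0);
  int prev_s = -1, prev_d = -1;
  double prev_f = 0.0;

  for (int i = start; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s > i || d > i) stop("parents must precede offspring (animal %d)", i + 1);
    if (s <= 0 || d <= 0) { F[i] = 0.0; prev_s = -1; continue; }
    if (s == prev_s && d == prev_d) { F[i] = prev_f; continue; }

    int top = s > d ? s : d;
    ws[s - 1] += 1.0;
    wd[d - 1] += 1.0;
    double acc = 0.0;
    for (int k = top; k >= 1; --k) {
      double as = ws[k - 1], ad = wd[k - 1];
      if (as == 0.0 && ad == 0.0) continue;
      int ks = sire[k - 1], kd = dam[k - 1];
      if (as != 0.0) {
        if (ks > 0) ws[ks - 1] += 0.5 * as;
        if (kd > 0) ws[kd - 1] += 0.5 * as;
      }
      if (ad != 0.0) {
        if (ks > 0) wd[ks - 1] += 0.5 * ad;
        if (kd > 0) wd[kd - 1] += 0.5 * ad;
      }
      if (as != 0.0 && ad != 0.0) {
        double dk;
        if (ks > 0 && kd > 0)      dk = 0.5  - 0.25 * (F[ks - 1] + F[kd - 1]);
        else if (ks > 0)           dk = 0.75 - 0.25 * F[ks - 1];
        else if (kd > 0)           dk = 0.75 - 0.25 * F[kd - 1];
        else                       dk = 1.0;
        acc += as * ad * dk;
      }
      ws[k - 1] = 0.0;
      wd[k - 1] = 0.0;
    }
    F[i] = 0.5 * acc;
    prev_s = s; prev_d = d; prev_f = F[i];
  }
  return F;
}
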