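#include <Rcpp.h>
using namespace Rcpp;

// Exact two-sided Hardy-Weinberg test on genotype counts: the p-value is
// the summed probability of all heterozygote configurations (conditional on
// the allele counts) that are no more probable than the observed one.
// Probabilities are built by the standard recurrence walked in both
// directions from a near-modal configuration, which keeps every term in
// floating range for any realistic sample size. Ties are compared with a
// 1e-12 relative tolerance so that algebraically equal configurations are
// always included.

static double hwe_one(int n_AA, int n_Aa, int n_aa) {
  if (n_AA < 0 || n_Aa < 0 || n_aa < 0) return NA_REAL;
  long n = (long)n_AA + n_Aa + n_aa;
  if (n == 0) return NA_REAL;
  long nA = 2L * n_AA + n_Aa;
  long na = 2L * n_aa + n_Aa;
  long rare = nA < na ? nA : na;
  if (rare == 0) return 1.0;              // monomorphic by convention
  int par = (int)(rare % 2);              // het count parity == rare parity
  int nhet = (int)(rare / 2) + 1;         // h = 2*i + par, i = 0..nhet-1
  std::vector<double> prob(nhet, 0.0);
  long mid = (long)std::floor((double)rare * (double)(nA + na - rare) /
                              (double)(nA + na));
  if ((mid % 2) != par) mid++;
  if (mid > rare) mid -= 2;
  int imid = (int)((mid - par) / 2);
  prob[imid] = 1.0;
  double sum = 1.0;
  for (int i = imid; i > 0; --i) {        // P(h-2) from P(h)
    double h = 2.0 * i + par;
    double hom_r = (rare - h) / 2.0;
    double hom_c = n - h - hom_r;
    prob[i - 1] = prob[i] * h * (h - 1.0) /
                  (4.0 * (hom_r + 1.0) * (hom_c + 1.0));
    sum += prob[i - 1];
  }
  for (int i = imid; i < nhet - 1; ++i) { // P(h+2) from P(h)
    double h = 2.0 * i + par;
    double hom_r = (rare - h) / 2.0;
    double hom_c = n - h - hom_r;
    prob[i + 1] = prob[i] * 4.0 * hom_r * hom_c / ((h + 2.0) * (h + 1.0));
    sum += prob[i + 1];
  }
  int iobs = (n_Aa - par) / 2;
  double pobs = prob[iobs] / sum;
  double tol = pobs * (1.0 + 1e-12);
  double pval = 0.0;
  for (int i = 0; i < nhet; ++i)
    if (prob[i] / sum <= tol) pval += prob[i] / sum;
  return pval > 1.0 ? 1.0 : pval;
}

// [[Rcpp::export(name = ".hwe_exact_cpp")]]
NumericVector hwe_exact_cpp(IntegerVector n_AA, IntegerVector n_Aa,
                            IntegerVector n_aa) {
  R_xlen_t m = n_AA.size();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i)
    out[i] = hwe_one(n_AA[i], n_Aa[i], n_aa[i]);
  return out;
}
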