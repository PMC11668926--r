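#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Nearest-taxon distance workhorse for beta-MNTD.
//
// D is the taxon-by-taxon patristic distance matrix, W the taxon-by-
// sample weight matrix (relative abundances, or 1/richness for the
// unweighted variant; zero marks absence). A null replicate is a
// permutation of taxon indices applied to D, equivalent to shuffling
// tip labels across the tree.

static void fill_presence(const NumericMatrix& W,
                          std::vector<std::vector<int> >& present) {
  int t = W.nrow(), s = W.ncol();
  present.assign(s, std::vector<int>());
  for (int j = 0; j < s; ++j)
    for (int i = 0; i < t; ++i)
      if (W(i, j) > 0) present[j].push_back(i);
}

// M(i, j) = min over taxa q present in sample j of D(perm[i], perm[q])
static void nearest_mins(const NumericMatrix& D,
                         const std::vector<std::vector<int> >& present,
                         const IntegerVector& perm, NumericMatrix& M) {
  int t = D.nrow();
  int s = (int) present.size();
  for (int j = 0; j < s; ++j) {
    const std::vector<int>& pj = present[j];
    for (int i = 0; i < t; ++i) {
      double best = R_PosInf;
      int pi = perm[i];
      for (size_t q = 0; q < pj.size(); ++q) {
        double d = D(pi, perm[pj[q]]);
        if (d < best) best = d;
      }
      M(i, j) = best;
    }
  }
}

static void bmntd_from_mins(const NumericMatrix& W,
                            const std::vector<std::vector<int> >& present,
                            const NumericMatrix& M, NumericMatrix& out) {
  int s = W.ncol();
  for (int a = 0; a < s; ++a) {
    out(a, a) = 0.0;
    for (int b = a + 1; b < s; ++b) {
      double acc = 0.0;
      const std::vector<int>& pa = present[a];
      const std::vector<int>& pb = present[b];
      for (size_t q = 0; q < pa.size(); ++q)
        acc += W(pa[q], a) * M(pa[q], b);
      for (size_t q = 0; q < pb.size(); ++q)
        acc += W(pb[q], b) * M(pb[q], a);
      out(a, b) = out(b, a) = 0.5 * acc;
    }
  }
}

// [[Rcpp::export(name = ".cpp_beta_mntd")]]
NumericMatrix cpp_beta_mntd(NumericMatrix D, NumericMatrix W) {
  int t = D.nrow(), s = W.ncol();
  if (W.nrow() != t) stop("D and W dimensions disagree");
  std::vector<std::vector<int> > present;
  fill_presence(W, present);
  IntegerVector identity(t);
  for (int i = 0; i < t; ++i) identity[i] = i;
  NumericMatrix M(t, s), out(s, s);
  nearest_mins(D, present, identity, M);
  bmntd_from_mins(W, present, M, out);
  return out;
}

// perms: n_null x t matrix of 0-based taxon permutations.
// Returns obs, null mean and null sd of beta-MNTD per sample pair.
// [[Rcpp::export(name = ".cpp_beta_nti")]]
List cpp_beta_nti(NumericMatrix D, NumericMatrix W, IntegerMatrix perms) {
  int t = D.nrow(), s = W.ncol(), n_null = perms.nrow();
  if (W.nrow() != t || perms.ncol() != t)
    stop("dimension mismatch between D, W and perms");
  std::vector<std::vector<int> > present;
  fill_presence(W, present);
  IntegerVector identity(t);
  for (int i = 0; i < t; ++i) identity[i] = i;
  NumericMatrix M(t, s), obs(s, s), nullv(s, s);
  NumericMatrix sum(s, s), sumsq(s, s);
  nearest_mins(D, present, identity, M);
  bmntd_from_mins(W, present, M, obs);
  for (int r = 0; r < n_null; ++r) {
    IntegerVector perm = perms(r, _);
    nearest_mins(D, present, perm, M);
    bmntd_from_mins(W, present, M, nullv);
    for (int a = 0; a < s; ++a)
      for (int b = 0; b < s; ++b) {
        sum(a, b) += nullv(a, b);
        sumsq(a, b) += nullv(a, b) * nullv(a, b);
      }
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix mean(s, s), sd(s, s);
  for (int a = 0; a < s; ++a)
    for (int b = 0; b < s; ++b) {
      double mu = sum(a, b) / n_null;
      mean(a, b) = mu;
      double v = (sumsq(a, b) - n_null * mu * mu) / (n_null - 1);
      sd(a, b) = v > 0 ? std::sqrt(v) : 0.0;
    }
  return List::create(_["obs"] = obs, _["mean"] = mean, _["sd"] = sd);
}
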