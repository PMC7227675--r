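#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Rule encodings share the landscape's covariate order:
//   type: 0 = range, 1 = negated range, 2 = logit, 3 = atomic
//   lo/hi: n_rules x p bound matrices, NA = covariate unconstrained
//          (atomic rules store the atom in both lo and hi)
//   coef:  n_rules x (p + 1), last column is the intercept (logit only)
//   tol:   per-covariate bin width; atomic rules match within half a bin
//
// Each rule's constrained columns are gathered once per call, so the per-cell
// loop touches only the covariates the rule actually uses.

struct CompiledRule {
  int type;
  std::vector<int> cols;      // constrained columns (range/negated/atomic)
  std::vector<double> lo, hi; // bounds (atomic: atom -/+ tol/2)
  std::vector<double> coef;   // logit coefficients for cols
  double intercept;
};

static std::vector<CompiledRule> compile_rules(const IntegerVector& type,
                                               const NumericMatrix& lo,
                                               const NumericMatrix& hi,
                                               const NumericMatrix& coef,
                                               const NumericVector& tol) {
  const int R = type.size(), p = lo.ncol();
  std::vector<CompiledRule> out(R);
  for (int r = 0; r < R; ++r) {
    CompiledRule& cr = out[r];
    cr.type = type[r];
    if (cr.type == 2) {
      cr.intercept = coef(r, p);
      for (int j = 0; j < p; ++j) {
        const double c = coef(r, j);
        if (!NumericVector::is_na(c)) {
          cr.cols.push_back(j);
          cr.coef.push_back(c);
        }
      }
    } else {
      for (int j = 0; j < p; ++j) {
        const double l = lo(r, j);
        if (NumericVector::is_na(l)) continue;
        cr.cols.push_back(j);
        if (cr.type == 3) {
          cr.lo.push_back(l - 0.5 * tol[j]);
          cr.hi.push_back(l + 0.5 * tol[j]);
        } else {
          cr.lo.push_back(l);
          cr.hi.push_back(hi(r, j));
        }
      }
    }
  }
  return out;
}

static inline bool fires_compiled(const CompiledRule& cr,
                                  const NumericMatrix& X, const int i) {
  const size_t k = cr.cols.size();
  if (cr.type == 2) {
    double eta = cr.intercept;
    for (size_t j = 0; j < k; ++j) eta += cr.coef[j] * X(i, cr.cols[j]);
    return eta > 0.0;  // logistic(eta) > 0.5
  }
  bool all_in = true;
  for (size_t j = 0; j < k; ++j) {
    const double x = X(i, cr.cols[j]);
    if (x < cr.lo[j] || x > cr.hi[j]) { all_in = false; break; }
  }
  return (cr.type == 1) ? !all_in : all_in;
}

// Evaluate every rule on every row of X: n x n_rules 0/1 matrix.
// [[Rcpp::export]]
IntegerMatrix eval_rules_cpp(const NumericMatrix& X, const IntegerVector& type,
                             const NumericMatrix& lo, const NumericMatrix& hi,
                             const NumericMatrix& coef, const NumericVector& tol) {
  const int n = X.nrow(), R = type.size();
  std::vector<CompiledRule> rules = compile_rules(type, lo, hi, coef, tol);
  IntegerMatrix out(n, R);
  for (int r = 0; r < R; ++r) {
    const CompiledRule& cr = rules[r];
    for (int i = 0; i < n; ++i) {
      out(i, r) = fires_compiled(cr, X, i) ? 1 : 0;
    }
  }
  return out;
}

// First-match-wins projection: rules are applied in row order; the first
// rule that fires decides the cell (its consequent and 1-based index are
// recorded). Cells matched by no rule are predicted absent with index -1.
// [[Rcpp::export]]
List project_rules_cpp(const NumericMatrix& X, const IntegerVector& type,
                       const NumericMatrix& lo, const NumericMatrix& hi,
                       const NumericMatrix& coef, const NumericVector& tol,
                       const IntegerVector& conseq) {
  const int n = X.nrow(), R = type.size();
  std::vector<CompiledRule> rules = compile_rules(type, lo, hi, coef, tol);
  IntegerVector pred(n), idx(n);
  for (int i = 0; i < n; ++i) {
    int p01 = 0, which = -1;
    for (int r = 0; r < R; ++r) {
      if (fires_compiled(rules[r], X, i)) {
        p01 = conseq[r];
        which = r + 1;
        break;
      }
    }
    pred[i] = p01;
    idx[i] = which;
  }
  return List::create(_["prediction"] = pred, _["rule_index"] = idx);
}
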