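#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Graphical lasso by blockwise coordinate descent (Friedman-style):
// maximize log det K - tr(S K) - lambda * sum_{i != j} |K_ij|
// with the diagonal unpenalized. W is the working covariance (dual
// variable, W ~ K^{-1}); each column block is solved as a lasso
//   min 0.5 b' W11 b - s12' b + lambda |b|_1
// by coordinate descent with exact soft-threshold zeros, so the sparsity
// pattern of K is exact (no epsilon thresholding downstream).

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One lasso solve for column j. B holds beta vectors column-wise
// (B(k, j) is the coefficient of variable k in the block for j; B(j, j)
// is unused and kept at 0). Returns max beta change.
static double solve_column(NumericMatrix W, const NumericMatrix S,
                           NumericMatrix B, int j, double lambda,
                           double inner_tol, int max_inner) {
  const int p = W.nrow();
  double total_change = 0.0;
  for (int it = 0; it < max_inner; ++it) {
    double max_delta = 0.0;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      // r = s_kj - sum_{l != k, l != j} W_kl * beta_l
      double r = S(k, j);
      for (int l = 0; l < p; ++l) {
        if (l == j || l == k) continue;
        double bl = B(l, j);
        if (bl != 0.0) r -= W(k, l) * bl;
      }
      double bnew = soft(r, lambda) / W(k, k);
      double d = std::fabs(bnew - B(k, j));
      if (d > max_delta) max_delta = d;
      B(k, j) = bnew;
    }
    if (it == 0) total_change = max_delta;
    if (max_delta < inner_tol) break;
  }
  // w12 = W11 beta
  for (int k = 0; k < p; ++k) {
    if (k == j) continue;
    double w = 0.0;
    for (int l = 0; l < p; ++l) {
      if (l == j) continue;
      double bl = B(l, j);
      if (bl != 0.0) w += W(k, l) * bl;
    }
    W(k, j) = w;
    W(j, k) = w;
  }
  return total_change;
}

// Recover K from (W, B): k_jj = 1 / (w_jj - w12' beta_j), K[-j,j] = -beta_j k_jj.
static void recover_K(const NumericMatrix W, const NumericMatrix B,
                      NumericMatrix K) {
  const int p = W.nrow();
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      dot += W(k, j) * B(k, j);
    }
    double kjj = 1.0 / (W(j, j) - dot);
    K(j, j) = kjj;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      K(k, j) = (B(k, j) == 0.0) ? 0.0 : -B(k, j) * kjj;
    }
  }
  // symmetrize zeros-preserving: average (both sides share the zero pattern
  // only at an exact solution, so keep a zero only if both halves are zero)
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j) {
      if (K(i, j) == 0.0 && K(j, i) == 0.0) continue;
      double v = 0.5 * (K(i, j) + K(j, i));
      K(i, j) = v;
      K(j, i) = v;
    }
  }
}

// [[Rcpp::export(name = ".glasso_cd")]]
List glasso_cd(NumericMatrix S, double lambda,
               Nullable<NumericMatrix> B_init = R_NilValue,
               Nullable<NumericMatrix> W_init = R_NilValue,
               double tol = 1e-6, int max_sweeps = 500,
               double inner_tol = 1e-9, int max_inner = 10000) {
  const int p = S.nrow();
  NumericMatrix W(p, p), B(p, p), K(p, p), K_prev(p, p);
  if (W_init.isNotNull()) {
    W = clone(NumericMatrix(W_init));
  } else {
    W = clone(S);
  }
  if (B_init.isNotNull()) B = clone(NumericMatrix(B_init));
  // diagonal is unpenalized: w_jj = s_jj always
  for (int j = 0; j < p; ++j) W(j, j) = S(j, j);

  recover_K(W, B, K_prev);
  bool converged = false;
  int sweeps = 0;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    sweeps = sweep + 1;
    for (int j = 0; j < p; ++j)
      solve_column(W, S, B, j, lambda, inner_tol, max_inner);
    recover_K(W, B, K);
    double max_change = 0.0;
    for (int i = 0; i < p * p; ++i) {
      double d = std::fabs(K[i] - K_prev[i]);
      if (d > max_change) max_change = d;
    }
    std::copy(K.begin(), K.end(), K_prev.begin());
    if (max_change < tol) { converged = true; break; }
  }
  return List::create(_["K"] = K, _["W"] = W, _["B"] = B,
                      _["sweeps"] = sweeps, _["converged"] = converged);
}

// Warm-started path over a decreasing lambda grid; returns one K per lambda.
// [[Rcpp::export(name = ".glasso_path_cd")]]
List glasso_path_cd(NumericMatrix S, NumericVector lambdas,
                    double tol = 1e-6, int max_sweeps = 500,
                    double inner_tol = 1e-9, int max_inner = 10000) {
  const int p = S.nrow();
  const int m = lambdas.size();
  NumericMatrix B(p, p), W = clone(S);
  List Ks(m);
  LogicalVector conv(m);
  for (int t = 0; t < m; ++t) {
    List fit = glasso_cd(S, lambdas[t], B, W, tol, max_sweeps,
                         inner_tol, max_inner);
    NumericMatrix Kt = fit["K"];
    Ks[t] = clone(Kt);
    conv[t] = as<bool>(fit["converged"]);
    NumericMatrix Bt = fit["B"], Wt = fit["W"];
    B = Bt;
    W = Wt;
  }
  return List::create(_["K"] = Ks, _["converged"] = conv);
}
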