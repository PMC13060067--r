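#include <Rcpp.h>
using namespace Rcpp;

// Weighted pool-adjacent-violators for a NON-INCREASING fit.
// Zero weights are tolerated: a pooled block whose total weight is zero
// takes the unweighted mean of its members (deterministic, never NaN).
static void pava_dec(double *y, const double *w, int n) {
  if (n <= 1) return;
  // block representation: value, weight, count (number of elements)
  std::vector<double> val(n), wt(n);
  std::vector<int> cnt(n);
  int nb = 0;
  for (int i = 0; i < n; ++i) {
    val[nb] = y[i]; wt[nb] = w[i]; cnt[nb] = 1; ++nb;
    // non-increasing: violation when previous block < current block
    while (nb > 1 && val[nb - 2] < val[nb - 1]) {
      double tw = wt[nb - 2] + wt[nb - 1];
      double tv;
      if (tw > 0.0) {
        tv = (wt[nb - 2] * val[nb - 2] + wt[nb - 1] * val[nb - 1]) / tw;
      } else {
        tv = 0.5 * (val[nb - 2] + val[nb - 1]);
      }
      int tc = cnt[nb - 2] + cnt[nb - 1];
      --nb;
      val[nb - 1] = tv; wt[nb - 1] = tw; cnt[nb - 1] = tc;
    }
  }
  int k = 0;
  for (int b = 0; b < nb; ++b)
    for (int c = 0; c < cnt[b]; ++c) y[k++] = val[b];
}

// [[Rcpp::export]]
NumericVector cpp_pava_decreasing(NumericVector y, NumericVector w) {
  int n = y.size();
  if (w.size() != n) stop("length mismatch between y and w");
  NumericVector out = clone(y);
  std::vector<double> yy(out.begin(), out.end()), ww(w.begin(), w.end());
  pava_dec(yy.data(), ww.data(), n);
  std::copy(yy.begin(), yy.end(), out.begin());
  return out;
}

static double wsse(const NumericMatrix &Z, const NumericMatrix &W,
                   const std::vector<double> &TH, int I, int J) {
  double s = 0.0;
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < I; ++i) {
      double d = Z(i, j) - TH[i + (size_t)I * j];
      s += W(i, j) * d * d;
    }
  return s;
}

// Dykstra's alternating-projection algorithm for the weighted least-squares
// projection onto the 2D monotone cone (non-increasing along every row and
// every column). The two half-cones (row-monotone, column-monotone) are each
// projected exactly by weighted PAVA in the same weighted inner product, so
// the iterates converge to the projection onto their intersection.
// [[Rcpp::export]]
List cpp_iso2d(NumericMatrix Z, NumericMatrix W, double tol = 1e-10,
               int max_iter = 20000) {
  int I = Z.nrow(), J = Z.ncol();
  if (W.nrow() != I || W.ncol() != J) stop("Z and W dimensions differ");
  size_t n = (size_t)I * J;
  std::vector<double> X(n), P(n, 0.0), Q(n, 0.0), Y(n), buf(std::max(I, J)),
      wbuf(std::max(I, J)), Xprev(n);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < I; ++i) X[i + (size_t)I * j] = Z(i, j);

  int it = 0;
  double delta = R_PosInf;
  for (it = 0; it < max_iter; ++it) {
    std::copy(X.begin(), X.end(), Xprev.begin());
    // row step: project (X + P) onto row-monotone cone
    for (int i = 0; i < I; ++i) {
      for (int j = 0; j < J; ++j) {
        buf[j] = X[i + (size_t)I * j] + P[i + (size_t)I * j];
        wbuf[j] = W(i, j);
      }
      std::vector<double> row(buf.begin(), buf.begin() + J);
      pava_dec(row.data(), wbuf.data(), J);
      for (int j = 0; j < J; ++j) {
        size_t k = i + (size_t)I * j;
        double pre = X[k] + P[k];
        Y[k] = row[j];
        P[k] = pre - row[j];
      }
    }
    // column step: project (Y + Q) onto column-monotone cone
    for (int j = 0; j < J; ++j) {
      for (int i = 0; i < I; ++i) {
        buf[i] = Y[i + (size_t)I * j] + Q[i + (size_t)I * j];
        wbuf[i] = W(i, j);
      }
      std::vector<double> col(buf.begin(), buf.begin() + I);
      pava_dec(col.data(), wbuf.data(), I);
      for (int i = 0; i < I; ++i) {
        size_t k = i + (size_t)I * j;
        double pre = Y[k] + Q[k];
        X[k] = col[i];
        Q[k] = pre - col[i];
      }
    }
    delta = 0.0;
    for (size_t k = 0; k < n; ++k)
      delta = std::max(delta, std::fabs(X[k] - Xprev[k]));
    if (delta < tol) break;
  }
  bool converged = (delta < tol);

  // worst remaining monotonicity violation (columns are exact after the
  // final column step; rows may carry the convergence gap)
  double viol = 0.0;
  for (int i = 0; i < I; ++i)
    for (int j = 0; j + 1 < J; ++j)
      viol = std::max(viol, X[i + (size_t)I * (j + 1)] - X[i + (size_t)I * j]);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i + 1 < I; ++i)
      viol = std::max(viol, X[(i + 1) + (size_t)I * j] - X[i + (size_t)I * j]);

  NumericMatrix theta(I, J);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < I; ++i) theta(i, j) = X[i + (size_t)I * j];
  return List::create(_["theta"] = theta, _["objective"] = wsse(Z, W, X, I, J),
                      _["iterations"] = it + 1, _["converged"] = converged,
                      _["max_violation"] = viol);
}

// Weighted least-squares fit of the monotone-additive surface
// theta_ij = u_i + v_j with u and v non-increasing, by block coordinate
// descent: each block update is an exact weighted PAVA projection, so the
// objective is non-increasing and converges to the global minimum of this
// convex problem. The free additive constant lives in u during iteration
// and is normalised out by the caller.
// [[Rcpp::export]]
List cpp_additive(NumericMatrix Z, NumericMatrix W, double tol = 1e-12,
                  int max_iter = 5000) {
  int I = Z.nrow(), J = Z.ncol();
  if (W.nrow() != I || W.ncol() != J) stop("Z and W dimensions differ");
  std::vector<double> u(I, 0.0), v(J, 0.0), t(std::max(I, J)),
      tw(std::max(I, J));

  // initialise u with weighted row means
  for (int i = 0; i < I; ++i) {
    double sw = 0.0, sz = 0.0;
    for (int j = 0; j < J; ++j) { sw += W(i, j); sz += W(i, j) * Z(i, j); }
    u[i] = (sw > 0.0) ? sz / sw : 0.0;
    t[i] = u[i]; tw[i] = sw;
  }
  pava_dec(t.data(), tw.data(), I);
  for (int i = 0; i < I; ++i) u[i] = t[i];

  double obj_prev = R_PosInf, obj = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // v update: weighted column means of residual Z - u, then PAVA
    for (int j = 0; j < J; ++j) {
      double sw = 0.0, sz = 0.0;
      for (int i = 0; i < I; ++i) {
        sw += W(i, j); sz += W(i, j) * (Z(i, j) - u[i]);
      }
      t[j] = (sw > 0.0) ? sz / sw : 0.0;
      tw[j] = sw;
    }
    pava_dec(t.data(), tw.data(), J);
    for (int j = 0; j < J; ++j) v[j] = t[j];
    // u update
    for (int i = 0; i < I; ++i) {
      double sw = 0.0, sz = 0.0;
      for (int j = 0; j < J; ++j) {
        sw += W(i, j); sz += W(i, j) * (Z(i, j) - v[j]);
      }
      t[i] = (sw > 0.0) ? sz / sw : 0.0;
      tw[i] = sw;
    }
    pava_dec(t.data(), tw.data(), I);
    for (int i = 0; i < I; ++i) u[i] = t[i];

    obj = 0.0;
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < I; ++i) {
        double d = Z(i, j) - u[i] - v[j];
        obj += W(i, j) * d * d;
      }
    if (obj_prev - obj < tol * (1.0 + obj)) { ++it; break; }
    obj_prev = obj;
  }
  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["objective"] = obj, _["iterations"] = it,
                      _["converged"] = (it < max_iter));
}
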