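// Recursive tvMVAR estimation cores.
//
// All cores take the observations as a cube Y with dimensions
// (channels d, samples N, trials k) and return a cube A with dimensions
// (d, d*p, N): A.slice(n) is the d x dp coefficient matrix at time n, with
// columns ordered lag-major (lag 1 channels 1..d, lag 2 channels 1..d, ...),
// i.e. A(i, (r-1)*d + j) multiplies y_j(n - r). Coefficients for n < p stay
// at their initial value (zeros). Time is 0-based here; the R layer owns all
// unit conversions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// lagged-observation row X_n = (y(n-1)', y(n-2)', ..., y(n-p)')
static inline rowvec lag_row(const cube& Y, uword n, uword p, uword trial) {
  const uword d = Y.n_rows;
  rowvec X(d * p);
  for (uword r = 1; r <= p; ++r)
    X.subvec((r - 1) * d, r * d - 1) = Y.slice(trial).col(n - r).t();
  return X;
}

// Recursive least squares with forgetting factor lambda (Eq.-2-style
// recursion).  C_n = (1-lambda) C_{n-1} + sum_k X' X is maintained through
// its inverse by rank-one (Sherman-Morrison) updates; Cinv is initialised to
// (1/delta) I with a trace-scaled delta, the regularized equivalent of the
// all-zero C initialisation.
// [[Rcpp::export(name = ".rls_core")]]
arma::cube rls_core(const arma::cube& Y, int p_, double lambda) {
  const uword d = Y.n_rows, N = Y.n_cols, k = Y.n_slices, p = (uword)p_;
  const uword dp = d * p;

  const double s2 = accu(square(Y)) / (double)Y.n_elem;
  const double delta = 1e-8 * (s2 > 0 ? s2 : 1.0);

  mat Cinv = eye(dp, dp) / delta;
  mat A(d, dp, fill::zeros);
  cube out(d, dp, N, fill::zeros);

  mat Xs(k, dp);   // per-trial lag rows at step n
  for (uword n = p; n < N; ++n) {
    // C_n = (1 - lambda) C_{n-1} + sum over trials of X'X
    Cinv /= (1.0 - lambda);
    for (uword t = 0; t < k; ++t) {
      Xs.row(t) = lag_row(Y, n, p, t);
      const vec cx = Cinv * Xs.row(t).t();
      const double denom = 1.0 + dot(Xs.row(t), cx);
      Cinv -= (cx * cx.t()) / denom;
    }
    Cinv = 0.5 * (Cinv + Cinv.t());
    // innovation-weighted update, accumulated across trials
    mat dA(d, dp, fill::zeros);
    for (uword t = 0; t < k; ++t) {
      const rowvec K = Xs.row(t) * Cinv;                    // gain
      const rowvec Z = Y.slice(t).col(n).t() - Xs.row(t) * A.t();
      dA += Z.t() * K;
    }
    A += dA;
    if (!A.is_finite())
      Rcpp::stop("RLS update diverged (non-finite coefficients) at time index %d", (int)n + 1);
    out.slice(n) = A;
  }
  return out;
}

// General linear Kalman filter on the stacked state Q = [A_1'; ...; A_p']
// (dp x d), random-walk state transition (G = I), process noise
// V = c2 I (GLKF) or V = c2^2 I (MVAAR variant), applied on the scale of the
// current state covariance (the identity is weighted by trace(P)/dp, the
// usual update-coefficient convention of adaptive AR Kalman filters, so the
// (0,1) range of the constants keeps its meaning).  The d x d observation-noise
// covariance W enters the k x k innovation covariance through its channel
// average trace(W)/d; W itself follows the recursive update
// W_n = (1-c1) W_{n-1} + c1 E'E / max(k-1, 1), with E the one-step prediction
// error of the current step (GLKF) or of the previous step (MVAAR).
// [[Rcpp::export(name = ".glkf_core")]]
arma::cube glkf_core(const arma::cube& Y, int p_, double c1, double c2,
                     bool mvaar) {
  const uword d = Y.n_rows, N = Y.n_cols, k = Y.n_slices, p = (uword)p_;
  const uword dp = d * p;
  const double v = mvaar ? c2 * c2 : c2;
  const double wdiv = k > 1 ? (double)(k - 1) : 1.0;

  mat Q(dp, d, fill::zeros);
  mat P = eye(dp, dp);
  mat W = eye(d, d);
  mat Eprev(k, d, fill::zeros);
  cube out(d, dp, N, fill::zeros);

  mat H(k, dp), E(k, d), O(k, d);
  for (uword n = p; n < N; ++n) {
    for (uword t = 0; t < k; ++t) {
      H.row(t) = lag_row(Y, n, p, t);
      O.row(t) = Y.slice(t).col(n).t();
    }
    P.diag() += v * trace(P) / (double)dp;   // predict (G = I, V relative)
    E = O - H * Q;                       // one-step prediction error
    if (!mvaar)
      W = (1.0 - c1) * W + c1 * (E.t() * E) / wdiv;
    const double wbar = trace(W) / (double)d;
    mat S = H * P * H.t();
    S.diag() += wbar + 1e-12 * (trace(S) / (double)k + 1.0);
    const mat K = P * H.t() * inv_sympd(S);
    Q += K * E;
    P -= K * (H * P);
    P = 0.5 * (P + P.t());
    if (mvaar) {
      W = (1.0 - c1) * W + c1 * (Eprev.t() * Eprev) / wdiv;
      Eprev = E;
    }
    if (!Q.is_finite())
      Rcpp::stop("Kalman update diverged (non-finite state) at time index %d", (int)n + 1);
    // Q[(r-1)d + j, i] = A_r(i, j)  ->  A(i, (r-1)d + j)
    out.slice(n) = Q.t();
  }
  return out;
}

// Dual extended Kalman filter, single trial: one linear Kalman filter on the
// signal state x = [y(n-1); ...; y(n-p)] with companion-form transition built
// from the current coefficient estimates, interleaved with one on the
// parameter vector w = (rows of A stacked), random walk with process noise
// uc * I.  y is a single trial (d x N).
// [[Rcpp::export(name = ".dekf_core")]]
arma::cube dekf_core(const arma::mat& y, int p_, double uc,
                     double state_noise, double obs_noise) {
  const uword d = y.n_rows, N = y.n_cols, p = (uword)p_;
  const uword dp = d * p, nw = d * dp;

  // state = most-recent-first stack of the last p samples
  vec x(dp, fill::zeros);
  for (uword r = 1; r <= p; ++r)
    x.subvec((r - 1) * d, r * d - 1) = y.col(p - r);
  mat Px = eye(dp, dp);
  vec w(nw, fill::zeros);
  mat Pw = eye(nw, nw);
  mat A(d, dp, fill::zeros);
  cube out(d, dp, N, fill::zeros);

  for (uword n = p; n < N; ++n) {
    for (uword i = 0; i < d; ++i)
      A.row(i) = w.subvec(i * dp, (i + 1) * dp - 1).t();
    const vec xprev = x;

    // ---- state filter (companion transition F = [A; I 0]) ----
    vec xpred(dp);
    xpred.head(d) = A * x;
    xpred.subvec(d, dp - 1) = x.subvec(0, dp - d - 1);
    mat T(dp, dp);                       // T = F Px
    T.rows(0, d - 1) = A * Px;
    T.rows(d, dp - 1) = Px.rows(0, dp - d - 1);
    const mat Tt = T.t();
    mat U(dp, dp);                       // U = F T'  =>  Px_pred = U'
    U.rows(0, d - 1) = A * Tt;
    U.rows(d, dp - 1) = Tt.rows(0, dp - d - 1);
    mat Pxp = U.t();
    Pxp.submat(0, 0, d - 1, d - 1) += state_noise * eye(d, d);

    const vec ex = y.col(n) - xpred.head(d);
    mat Sx = Pxp.submat(0, 0, d - 1, d - 1) + obs_noise * eye(d, d);
    const mat Kx = Pxp.cols(0, d - 1) * inv_sympd(Sx);
    x = xpred + Kx * ex;
    Px = Pxp - Kx * Pxp.rows(0, d - 1);
    Px = 0.5 * (Px + Px.t());

    // ---- weight filter (observation row i touches block i only) ----
    Pw.diag() += uc;
    const vec ew = y.col(n) - A * xprev;
    mat PwHt(nw, d);
    for (uword i = 0; i < d; ++i)
      PwHt.col(i) = Pw.cols(i * dp, (i + 1) * dp - 1) * xprev;
    mat Sw(d, d);
    for (uword i = 0; i < d; ++i)
      for (uword j = 0; j < d; ++j)
        Sw(i, j) = dot(PwHt.col(j).subvec(i * dp, (i + 1) * dp - 1), xprev);
    Sw = 0.5 * (Sw + Sw.t());
    Sw.diag() += 1.0;                    // weight-observation noise R_w = I
    const mat Kw = PwHt * inv_sympd(Sw);
    w += Kw * ew;
    Pw -= Kw * PwHt.t();
    Pw = 0.5 * (Pw + Pw.t());

    if (!w.is_finite() || !Px.is_finite() || !Pw.is_finite())
      Rcpp::stop("DEKF diverged (non-finite covariance or weights) at time index %d", (int)n + 1);
    for (uword i = 0; i < d; ++i)
      out.slice(n).row(i) = w.subvec(i * dp, (i + 1) * dp - 1).t();
  }
  return out;
}

// per-channel one-step squared prediction error, pooled over trials and
// time indices n = p..N-1, for GOF / consistency computations
// [[Rcpp::export(name = ".onestep_sse")]]
Rcpp::List onestep_sse(const arma::cube& A, const arma::cube& Y, int p_) {
  const uword d = Y.n_rows, N = Y.n_cols, k = Y.n_slices, p = (uword)p_;
  vec sse(d, fill::zeros);
  for (uword t = 0; t < k; ++t)
    for (uword n = p; n < N; ++n) {
      const vec err = Y.slice(t).col(n) - A.slice(n) * lag_row(Y, n, p, t).t();
      sse += square(err);
    }
  return Rcpp::List::create(Rcpp::Named("sse") = sse,
                            Rcpp::Named("n") = (double)(k * (N - p)));
}
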