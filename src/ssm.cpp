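#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact state-space form of the Matern-3/2 Gaussian process in one dimension.
// The process g(t) with unit variance and length scale ell is Markov in the
// state s(t) = (g(t), g'(t)) with
//   lambda = sqrt(3)/ell
//   A(dt)  = exp(-lambda dt) [[1+lambda dt, dt], [-lambda^2 dt, 1-lambda dt]]
//   Pinf   = diag(1, lambda^2)
//   Q(dt)  = Pinf - A Pinf A^T
// Stationary cross-covariance Cov(s(t), s(t+dt)) = Pinf A(dt)^T, whose (1,1)
// entry is exactly the Matern-3/2 kernel (1+lambda dt) exp(-lambda dt).

static inline void trans_A(double dt, double lam, double A[4]) {
  double e = std::exp(-lam * dt), ld = lam * dt;
  A[0] = e * (1.0 + ld);
  A[1] = e * dt;
  A[2] = -e * lam * lam * dt;
  A[3] = e * (1.0 - ld);
}

static inline void trans_Q(const double A[4], double lam, double Q[3]) {
  // Q = Pinf - A Pinf A^T, symmetric: store (q11, q12, q22)
  double l2 = lam * lam;
  Q[0] = 1.0 - (A[0] * A[0] + l2 * A[1] * A[1]);
  Q[1] = -(A[0] * A[2] + l2 * A[1] * A[3]);
  Q[2] = l2 - (A[2] * A[2] + l2 * A[3] * A[3]);
}

static inline void chol2(const double Q[3], double L[3]) {
  double q11 = Q[0] < 1e-300 ? 1e-300 : Q[0];
  double c11 = std::sqrt(q11);
  double c21 = Q[1] / c11;
  double r = Q[2] - c21 * c21;
  if (r < 1e-300) r = 1e-300;
  L[0] = c11;
  L[1] = c21;
  L[2] = std::sqrt(r);
}

// Precompute per-gap transition matrices and innovation Cholesky factors for
// sorted positions. Returns A (n-1 x 4, row-major [a11,a12,a21,a22]) and
// L (n-1 x 3, [l11,l21,l22]).
// [[Rcpp::export(name = ".ssm_precompute")]]
List ssm_precompute(NumericVector pos, double lengthscale) {
  int n = pos.size();
  if (n < 1) stop("need at least one position");
  if (lengthscale <= 0) stop("length scale must be positive");
  double lam = std::sqrt(3.0) / lengthscale;
  NumericMatrix A(std::max(n - 1, 0), 4), L(std::max(n - 1, 0), 3);
  for (int i = 0; i + 1 < n; ++i) {
    double dt = pos[i + 1] - pos[i];
    if (dt <= 0) stop("positions must be strictly increasing");
    double a[4], q[3], l[3];
    trans_A(dt, lam, a);
    trans_Q(a, lam, q);
    chol2(q, l);
    for (int k = 0; k < 4; ++k) A(i, k) = a[k];
    for (int k = 0; k < 3; ++k) L(i, k) = l[k];
  }
  return List::create(_["A"] = A, _["L"] = L, _["lambda"] = lam);
}

static void forward_states(const double* z, int n, const NumericMatrix& A,
                           const NumericMatrix& L, double lam, double* s) {
  // s row-major n x 2; initial state s0 = chol(Pinf) z0 = (z0, lam * z1)
  s[0] = z[0];
  s[1] = lam * z[1];
  for (int i = 1; i < n; ++i) {
    const int p = i - 1;
    double g = A(p, 0) * s[2 * p] + A(p, 1) * s[2 * p + 1] + L(p, 0) * z[2 * i];
    double d = A(p, 2) * s[2 * p] + A(p, 3) * s[2 * p + 1] + L(p, 1) * z[2 * i] +
               L(p, 2) * z[2 * i + 1];
    s[2 * i] = g;
    s[2 * i + 1] = d;
  }
}

// [[Rcpp::export(name = ".ssm_states")]]
NumericMatrix ssm_states(NumericVector z, NumericMatrix A, NumericMatrix L,
                         double lam) {
  int n = z.size() / 2;
  std::vector<double> s(2 * n);
  forward_states(z.begin(), n, A, L, lam, s.data());
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = s[2 * i];
    out(i, 1) = s[2 * i + 1];
  }
  return out;
}

static void softmax4(const double* eta, double* w) {
  // first component is the reference (logit 0)
  double e[4] = {0.0, eta[0], eta[1], eta[2]};
  double m = e[0];
  for (int k = 1; k < 4; ++k) m = std::max(m, e[k]);
  double sum = 0.0;
  for (int k = 0; k < 4; ++k) {
    w[k] = std::exp(e[k] - m);
    sum += w[k];
  }
  for (int k = 0; k < 4; ++k) w[k] /= sum;
}

// Negative log posterior (up to additive constants of the innovation prior)
// and its gradient for one deconvolution chunk, in the non-centered
// parameterization. Parameter layout:
//   par = [zPol (2n), zK27 (2n), etaPol (3), etaK27 (3)]
// uidx maps each weighted cut event to its unique-position index (0-based);
// phiPol/phiK27 hold the per-event log-normal component densities.
// [[Rcpp::export(name = ".deconv_objective")]]
List deconv_objective(NumericVector par, int n, NumericMatrix AP,
                      NumericMatrix LP, double lamP, NumericMatrix AK,
                      NumericMatrix LK, double lamK, IntegerVector uidx,
                      NumericVector wEvent, NumericMatrix phiP,
                      NumericMatrix phiK, NumericVector widths,
                      double logTotalW, double intSd, NumericVector alphaP,
                      NumericVector alphaK, bool wantGrad) {
  const int m = uidx.size();
  if ((int)par.size() != 4 * n + 6) stop("parameter length mismatch");
  const double* zP = par.begin();
  const double* zK = par.begin() + 2 * n;
  const double* etaP = par.begin() + 4 * n;
  const double* etaK = par.begin() + 4 * n + 3;

  std::vector<double> sP(2 * n), sK(2 * n);
  forward_states(zP, n, AP, LP, lamP, sP.data());
  forward_states(zK, n, AK, LK, lamK, sK.data());

  double wP[4], wK[4];
  softmax4(etaP, wP);
  softmax4(etaK, wK);

  // All density work happens on the log scale so that the objective stays
  // finite for any iterate the line search may visit.
  std::vector<double> dgP(n, 0.0), dgK(n, 0.0);

  double F = 0.0;
  double dwP[4] = {0, 0, 0, 0}, dwK[4] = {0, 0, 0, 0};

  // (a) mixture likelihood over weighted cut events (logsumexp form)
  for (int j = 0; j < m; ++j) {
    int u = uidx[j];
    double hP = wP[0] * phiP(j, 0) + wP[1] * phiP(j, 1) + wP[2] * phiP(j, 2) +
                wP[3] * phiP(j, 3);
    double hK = wK[0] * phiK(j, 0) + wK[1] * phiK(j, 1) + wK[2] * phiK(j, 2) +
                wK[3] * phiK(j, 3);
    double a = sP[2 * u] + std::log(hP);
    double b = sK[2 * u] + std::log(hK);
    double mx = std::max(a, b);
    double logD = mx + std::log1p(std::exp(std::min(a, b) - mx));
    double w = wEvent[j];
    F -= w * logD;
    if (wantGrad) {
      double rP = std::exp(a - logD);   // tP / D, in (0, 1)
      double rK = std::exp(b - logD);
      dgP[u] -= w * rP;
      dgK[u] -= w * rK;
      double cp = w * rP / hP, ck = w * rK / hK;
      for (int k = 0; k < 4; ++k) {
        dwP[k] -= cp * phiP(j, k);
        dwK[k] -= ck * phiK(j, k);
      }
    }
  }

  // (d) rectangle-rule integral: normalization of the mixture density (the
  // position factors are PDFs scaled to total weight W, so each event's
  // density is divided by I/W) plus the log-normal constraint around W
  // that fixes the remaining scale freedom. Computed on the log scale.
  double M = sP[0];
  for (int i = 0; i < n; ++i) {
    M = std::max(M, sP[2 * i]);
    M = std::max(M, sK[2 * i]);
  }
  double S = 0.0;
  for (int i = 0; i < n; ++i)
    S += widths[i] * (std::exp(sP[2 * i] - M) + std::exp(sK[2 * i] - M));
  double logI = M + std::log(S);
  double Wtot = std::exp(logTotalW);
  double dev = (logI - logTotalW) / intSd;
  F += Wtot * (logI - logTotalW);       // likelihood normalization
  F += 0.5 * dev * dev + logI;          // soft integral constraint
  double C = Wtot + dev / intSd + 1.0;  // dF / dlogI
  if (wantGrad) {
    for (int i = 0; i < n; ++i) {
      dgP[i] += C * widths[i] * std::exp(sP[2 * i] - logI);
      dgK[i] += C * widths[i] * std::exp(sK[2 * i] - logI);
    }
  }

  // (c) Dirichlet log priors (with normalizing constants). Weights are
  // floored inside the prior so that parameter vectors with alpha < 1,
  // whose density is unbounded at the simplex boundary, keep the
  // objective finite when a weight underflows.
  const double wFloor = 1e-12;
  double sAP = 0, sAK = 0, lbP = 0, lbK = 0;
  for (int k = 0; k < 4; ++k) {
    sAP += alphaP[k];
    sAK += alphaK[k];
    lbP += R::lgammafn(alphaP[k]);
    lbK += R::lgammafn(alphaK[k]);
    F -= (alphaP[k] - 1.0) * std::log(std::max(wP[k], wFloor));
    F -= (alphaK[k] - 1.0) * std::log(std::max(wK[k], wFloor));
    if (wantGrad) {
      if (wP[k] > wFloor) dwP[k] -= (alphaP[k] - 1.0) / wP[k];
      if (wK[k] > wFloor) dwK[k] -= (alphaK[k] - 1.0) / wK[k];
    }
  }
  F += (lbP - R::lgammafn(sAP)) + (lbK - R::lgammafn(sAK));

  // (b) innovation (GP) prior
  for (int i = 0; i < 4 * n; ++i) F += 0.5 * par[i] * par[i];

  if (!wantGrad)
    return List::create(_["value"] = F, _["gradient"] = R_NilValue);

  NumericVector grad(4 * n + 6);
  // backward pass per target: adjoint lam_i = (dg_i, 0) + A_i^T lam_{i+1}
  auto backward = [&](const std::vector<double>& dg, const NumericMatrix& A,
                      const NumericMatrix& L, double lam, const double* z,
                      double* gz) {
    double l0 = dg[n - 1], l1 = 0.0;
    for (int i = n - 1; i >= 1; --i) {
      const int p = i - 1;
      gz[2 * i] = L(p, 0) * l0 + L(p, 1) * l1;
      gz[2 * i + 1] = L(p, 2) * l1;
      double n0 = dg[i - 1] + A(p, 0) * l0 + A(p, 2) * l1;
      double n1 = A(p, 1) * l0 + A(p, 3) * l1;
      l0 = n0;
      l1 = n1;
    }
    gz[0] = l0;        // chol(Pinf) = diag(1, lam)
    gz[1] = lam * l1;
    for (int i = 0; i < 2 * n; ++i) gz[i] += z[i];
  };
  backward(dgP, AP, LP, lamP, zP, grad.begin());
  backward(dgK, AK, LK, lamK, zK, grad.begin() + 2 * n);

  // softmax chain rule for the three free logits per target
  double cP = 0, cK = 0;
  for (int k = 0; k < 4; ++k) {
    cP += dwP[k] * wP[k];
    cK += dwK[k] * wK[k];
  }
  for (int k = 0; k < 3; ++k) {
    grad[4 * n + k] = wP[k + 1] * (dwP[k + 1] - cP);
    grad[4 * n + 3 + k] = wK[k + 1] * (dwK[k + 1] - cK);
  }
  return List::create(_["value"] = F, _["gradient"] = grad);
}

// Conditional mean of g at arbitrary grid positions given the MAP states at
// the cut positions. Because the process is Markov, conditioning on the two
// flanking states is exact and equals the dense GP posterior-mean interpolant
// when the derivative states sit at their conditional means (true at the MAP).
// [[Rcpp::export(name = ".ssm_interpolate")]]
NumericVector ssm_interpolate(NumericMatrix states, NumericVector pos,
                              NumericVector grid, double lengthscale) {
  int n = pos.size();
  double lam = std::sqrt(3.0) / lengthscale;
  int ng = grid.size();
  NumericVector out(ng);
  int i = 0;
  for (int j = 0; j < ng; ++j) {
    double t = grid[j];
    while (i + 1 < n && pos[i + 1] <= t) ++i;
    if (t <= pos[0]) {
      // before the first site: reverse-time stationary extrapolation
      double a[4];
      trans_A(pos[0] - t, lam, a);
      // Pinf A^T Pinf^{-1}: row 1 = (a11, a21 / lam^2)
      out[j] = a[0] * states(0, 0) + (a[2] / (lam * lam)) * states(0, 1);
    } else if (t >= pos[n - 1]) {
      double a[4];
      trans_A(t - pos[n - 1], lam, a);
      out[j] = a[0] * states(n - 1, 0) + a[1] * states(n - 1, 1);
    } else if (t == pos[i]) {
      out[j] = states(i, 0);
    } else {
      double d1 = t - pos[i], d2 = pos[i + 1] - t;
      double A1[4], A2[4], AD[4], Q1[3], Q2[3];
      trans_A(d1, lam, A1);
      trans_A(d2, lam, A2);
      trans_A(pos[i + 1] - pos[i], lam, AD);
      trans_Q(A1, lam, Q1);
      trans_Q(A2, lam, Q2);
      // residual r = s_{i+1} - A(Delta) s_i
      double s0 = states(i, 0), s1 = states(i, 1);
      double t0 = states(i + 1, 0), t1 = states(i + 1, 1);
      double r0 = t0 - (AD[0] * s0 + AD[1] * s1);
      double r1 = t1 - (AD[2] * s0 + AD[3] * s1);
      // S = A2 Q1 A2^T + Q2 ; C = Q1 A2^T (first row needed)
      double q1A2t[4] = {
          Q1[0] * A2[0] + Q1[1] * A2[1], Q1[0] * A2[2] + Q1[1] * A2[3],
          Q1[1] * A2[0] + Q1[2] * A2[1], Q1[1] * A2[2] + Q1[2] * A2[3]};
      double S00 = A2[0] * q1A2t[0] + A2[1] * q1A2t[2] + Q2[0];
      double S01 = A2[0] * q1A2t[1] + A2[1] * q1A2t[3] + Q2[1];
      double S11 = A2[2] * q1A2t[1] + A2[3] * q1A2t[3] + Q2[2];
      double det = S00 * S11 - S01 * S01;
      if (det <= 1e-300) det = 1e-300;
      // x = S^{-1} r
      double x0 = (S11 * r0 - S01 * r1) / det;
      double x1 = (-S01 * r0 + S00 * r1) / det;
      double mean0 = A1[0] * s0 + A1[1] * s1 + q1A2t[0] * x0 + q1A2t[1] * x1;
      out[j] = mean0;
    }
  }
  return out;
}
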