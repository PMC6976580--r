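// Compiled cores: sequential quaternion accumulation, cone-restricted
// rotational diffusion, and the density-matrix propagation engine.
//
// The propagation engine exploits the block structure of the secular
// rotating-frame Hamiltonian H(t) = cg Sz + Sz (ax Ix + ay Iy + az Iz):
// H is block-diagonal in the electron projection with blocks
// H_± = ±(1/2) F(t), F(t) = cg 1 + ax Ix + ay Iy + az Iz on the nuclear
// space. The trajectory-ordered propagator Gamma(tau) therefore factorises
// into nuclear-space products G_± and the detected trace is
// FID(tau) = Tr{S+ Gamma^-1 Sx Gamma} = (1/2) Tr( G_-^H G_+ ),
// with G_- = G_+ evaluated with conjugated elementary propagators.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// quaternion helpers (scalar-first, double[4])
// ---------------------------------------------------------------------------

static inline void qmul(const double* a, const double* b, double* out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

static inline void qnormalize(double* q) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int i = 0; i < 4; ++i) q[i] /= n;
}

// Accumulate Q_{k+1} = Q_k * dq_k (body-frame elementary rotations).
// Returns an (n+1) x 4 matrix whose first row is q0.
// [[Rcpp::export(name = "q_accumulate_cpp")]]
NumericMatrix q_accumulate_cpp(NumericVector q0, NumericMatrix dq) {
  int n = dq.nrow();
  NumericMatrix out(n + 1, 4);
  double cur[4] = { q0[0], q0[1], q0[2], q0[3] };
  qnormalize(cur);
  for (int j = 0; j < 4; ++j) out(0, j) = cur[j];
  double step[4], nxt[4];
  for (int k = 0; k < n; ++k) {
    step[0] = dq(k, 0); step[1] = dq(k, 1);
    step[2] = dq(k, 2); step[3] = dq(k, 3);
    qmul(cur, step, nxt);
    for (int j = 0; j < 4; ++j) cur[j] = nxt[j];
    if ((k & 1023) == 1023) qnormalize(cur);
    for (int j = 0; j < 4; ++j) out(k + 1, j) = cur[j];
  }
  return out;
}

// Rotational diffusion of the body z axis restricted to a cone of half
// angle beta about the reference z axis (Metropolis rejection at the
// boundary; equilibrium uniform in solid angle inside the cone). Proposal
// rotation vectors are supplied pre-drawn (body frame).
// [[Rcpp::export(name = "cone_walk_cpp")]]
NumericMatrix cone_walk_cpp(NumericVector q0, NumericMatrix rotvec,
                            double cosBeta) {
  int n = rotvec.nrow();
  NumericMatrix out(n + 1, 4);
  double cur[4] = { q0[0], q0[1], q0[2], q0[3] };
  qnormalize(cur);
  for (int j = 0; j < 4; ++j) out(0, j) = cur[j];
  double dq[4], nxt[4];
  for (int k = 0; k < n; ++k) {
    double rx = rotvec(k, 0), ry = rotvec(k, 1), rz = rotvec(k, 2);
    double ang = std::sqrt(rx * rx + ry * ry + rz * rz);
    double s = (ang < 1e-14) ? 0.5 : std::sin(ang / 2) / ang;
    dq[0] = std::cos(ang / 2);
    dq[1] = rx * s; dq[2] = ry * s; dq[3] = rz * s;
    qmul(cur, dq, nxt);
    // R33 of the candidate: cos of the body-z tilt
    double r33 = 1.0 - 2.0 * (nxt[1] * nxt[1] + nxt[2] * nxt[2]);
    if (r33 >= cosBeta) {
      for (int j = 0; j < 4; ++j) cur[j] = nxt[j];
      if ((k & 1023) == 1023) qnormalize(cur);
    }
    for (int j = 0; j < 4; ++j) out(k + 1, j) = cur[j];
  }
  return out;
}

// Secular coupling coefficients (cg, ax, ay, az) for every frame of a
// quaternion trajectory, optionally pre-rotated by a fixed global
// quaternion (orientation-grid averaging). Single pass, no intermediates.
// gL, aL: traceless principal values (g dimensionless, a in rad/s);
// zeeman = muB B0 / hbar; aIsoRad = isotropic hyperfine in rad/s.
// [[Rcpp::export(name = "secular_coef_cpp")]]
NumericMatrix secular_coef_cpp(NumericMatrix q, NumericVector qrot,
                               NumericVector gL, NumericVector aL,
                               double zeeman, double aIsoRad) {
  int n = q.nrow();
  NumericMatrix out(n, 4);
  double r0[4] = { qrot[0], qrot[1], qrot[2], qrot[3] };
  for (int k = 0; k < n; ++k) {
    double qk[4] = { q(k, 0), q(k, 1), q(k, 2), q(k, 3) };
    double w, x, y, z;
    {
      double t[4];
      qmul(r0, qk, t);
      w = t[0]; x = t[1]; y = t[2]; z = t[3];
    }
    // rows of the rotation matrix
    double R11 = 1 - 2 * (y * y + z * z), R12 = 2 * (x * y - w * z),
           R13 = 2 * (x * z + w * y);
    double R21 = 2 * (x * y + w * z), R22 = 1 - 2 * (x * x + z * z),
           R23 = 2 * (y * z - w * x);
    double R31 = 2 * (x * z - w * y), R32 = 2 * (y * z + w * x),
           R33 = 1 - 2 * (x * x + y * y);
    double cg = zeeman * (gL[0] * R31 * R31 + gL[1] * R32 * R32 +
                          gL[2] * R33 * R33);
    double ax = aL[0] * R31 * R11 + aL[1] * R32 * R12 + aL[2] * R33 * R13;
    double ay = aL[0] * R31 * R21 + aL[1] * R32 * R22 + aL[2] * R33 * R23;
    double az = aL[0] * R31 * R31 + aL[1] * R32 * R32 + aL[2] * R33 * R33 +
      aIsoRad;
    out(k, 0) = cg; out(k, 1) = ax; out(k, 2) = ay; out(k, 3) = az;
  }
  return out;
}

// ---------------------------------------------------------------------------
// FID propagation engine
// ---------------------------------------------------------------------------

typedef std::complex<double> cplx;

// C = A * B, row-major D x D
template <int D>
static inline void mm(const cplx* A, const cplx* B, cplx* C) {
  for (int i = 0; i < D; ++i)
    for (int jj = 0; jj < D; ++jj) {
      cplx s(0, 0);
      for (int k = 0; k < D; ++k) s += A[i * D + k] * B[k * D + jj];
      C[i * D + jj] = s;
    }
}

// C = A * B^H
template <int D>
static inline void mmh(const cplx* A, const cplx* B, cplx* C) {
  for (int i = 0; i < D; ++i)
    for (int jj = 0; jj < D; ++jj) {
      cplx s(0, 0);
      for (int k = 0; k < D; ++k) s += A[i * D + k] * std::conj(B[jj * D + k]);
      C[i * D + jj] = s;
    }
}

// exp(M) for small-norm anti-Hermitian M: Horner Taylor of given order
// (order 4 suffices below |M| ~ 0.01 rad; order 8 up to ~0.3 rad).
template <int D>
static inline void expm_taylor(const cplx* M, cplx* E, int order) {
  cplx T[D * D], T2[D * D];
  for (int i = 0; i < D * D; ++i) T[i] = M[i] / (double)order;
  for (int i = 0; i < D; ++i) T[i * D + i] += 1.0;
  for (int ord = order - 1; ord >= 1; --ord) {
    mm<D>(M, T, T2);
    for (int i = 0; i < D * D; ++i) T[i] = T2[i] / (double)ord;
    for (int i = 0; i < D; ++i) T[i * D + i] += 1.0;
  }
  for (int i = 0; i < D * D; ++i) E[i] = T[i];
}

template <int D>
static List fid_engine_impl(const arma::mat& coef, double deltaS,
                            int fidLen, int decim,
                            const arma::ivec& starts, int order) {
  // nuclear operators on the D-dim space (mI descending), row-major
  cplx Ix[D * D] = {}, Iy[D * D] = {}, Iz[D * D] = {}, Id[D * D] = {};
  double j = (D - 1) / 2.0;
  for (int k = 0; k < D; ++k) { Iz[k * D + k] = j - k; Id[k * D + k] = 1.0; }
  for (int k = 0; k + 1 < D; ++k) {
    double m = j - (k + 1);
    double c = std::sqrt(j * (j + 1) - m * (m + 1));
    Ix[k * D + (k + 1)] += c / 2.0;  Ix[(k + 1) * D + k] += c / 2.0;
    Iy[k * D + (k + 1)] += cplx(0, c / 2.0);
    Iy[(k + 1) * D + k] += cplx(0, -c / 2.0);
  }

  int winLen = fidLen * decim;
  arma::cx_vec fid(fidLen, arma::fill::zeros);
  double maxUdev = 0.0;
  const cplx ihalf(0.0, 0.5 * deltaS);

  cplx Gp[D * D], Gm[D * D], M[D * D], E[D * D], tmp[D * D];
  for (arma::uword w = 0; w < starts.n_elem; ++w) {
    int s0 = starts(w);
    for (int i = 0; i < D * D; ++i) { Gp[i] = 0; Gm[i] = 0; }
    for (int i = 0; i < D; ++i) { Gp[i * D + i] = 1; Gm[i * D + i] = 1; }
    int rec = 0;
    fid(rec++) += cplx(0.5 * D, 0);
    for (int k = 0; k < winLen; ++k) {
      int t = s0 + k;
      double c0 = coef(t, 0), c1 = coef(t, 1), c2 = coef(t, 2),
             c3 = coef(t, 3);
      for (int i = 0; i < D * D; ++i)
        M[i] = ihalf * (c0 * Id[i] + c1 * Ix[i] + c2 * Iy[i] + c3 * Iz[i]);
      expm_taylor<D>(M, E, order);
      mm<D>(Gp, E, tmp);  for (int i = 0; i < D * D; ++i) Gp[i] = tmp[i];
      mmh<D>(Gm, E, tmp); for (int i = 0; i < D * D; ++i) Gm[i] = tmp[i];
      if ((k & 4095) == 4095) {
        // unitarity drift of the accumulated propagator
        cplx dev[D * D];
        mmh<D>(Gp, Gp, dev);
        double u = 0;
        for (int i = 0; i < D; ++i) dev[i * D + i] -= 1.0;
        for (int i = 0; i < D * D; ++i) u += std::norm(dev[i]);
        u = std::sqrt(u);
        if (u > maxUdev) maxUdev = u;
      }
      if ((k + 1) % decim == 0 && rec < fidLen) {
        // FID = (1/2) Tr(Gm^H Gp) = (1/2) sum conj(Gm) .* Gp
        cplx s(0, 0);
        for (int i = 0; i < D * D; ++i) s += std::conj(Gm[i]) * Gp[i];
        fid(rec++) += 0.5 * s;
      }
    }
  }
  fid /= (double)starts.n_elem;
  return List::create(_["fid"] = fid, _["maxUnitarityDev"] = maxUdev,
                      _["nWindows"] = (int)starts.n_elem);
}

// coef: N x 4 matrix (cg, ax, ay, az) in rad/s; deltaS: step in seconds;
// dimI: nuclear dimension (2 or 3); starts: 0-based window start frames.
// [[Rcpp::export(name = "fid_engine_cpp")]]
List fid_engine_cpp(arma::mat coef, double deltaS, int dimI,
                    int fidLen, int decim, arma::ivec starts) {
  double maxH = arma::abs(coef).max() * deltaS;
  if (maxH > 0.3)
    Rcpp::warning("elementary propagator argument |H*delta| = %g exceeds "
                  "0.3 rad; reduce the step", maxH);
  int order = (maxH < 0.01) ? 4 : 8;
  if (dimI == 3)
    return fid_engine_impl<3>(coef, deltaS, fidLen, decim, starts, order);
  if (dimI == 2)
    return fid_engine_impl<2>(coef, deltaS, fidLen, decim, starts, order);
  stop("unsupported nuclear dimension: %d", dimI);
  return List::create();
}
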