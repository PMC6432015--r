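// Compiled kernels: bridge integrator, crankshaft Monte Carlo,
// projection crossing extraction, exact Gauss writhe.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// helpers

// lambda / sinh(lambda * tau), stable for lambda*tau from 0 to huge.
// Computed as 2*lambda*exp(-x)/(1 - exp(-2x)); at lambda == 0 equals 1/tau.
static inline double pull_coef(double lambda, double tau) {
  if (lambda <= 0.0) return 1.0 / tau;
  double x = lambda * tau;
  return 2.0 * lambda * std::exp(-x) / (-std::expm1(-2.0 * x));
}

// lambda / (1 - exp(-2 lambda tau)) for the permutation log-weights;
// continuous limit 1/(2 tau) at lambda = 0 (pure diffusion).
static inline double weight_coef(double lambda, double tau) {
  if (lambda <= 0.0) return 0.5 / tau;
  return lambda / (-std::expm1(-2.0 * lambda * tau));
}

// draw N x 3 iid normals from the R RNG, column-major like R's matrix(rnorm())
static arma::mat rnorm_mat(int n, double sd) {
  arma::mat g(n, 3);
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < n; ++r) g(r, c) = R::rnorm(0.0, sd);
  return g;
}

// column-wise fft/ifft of a complex matrix (arma::fft is per-column already,
// but keep explicit to be safe across versions)
static arma::cx_mat fft_cols(const arma::cx_mat& x) {
  arma::cx_mat out(x.n_rows, x.n_cols);
  for (arma::uword c = 0; c < x.n_cols; ++c) out.col(c) = arma::fft(x.col(c));
  return out;
}
static arma::cx_mat ifft_cols(const arma::cx_mat& x) {
  arma::cx_mat out(x.n_rows, x.n_cols);
  for (arma::uword c = 0; c < x.n_cols; ++c) out.col(c) = arma::ifft(x.col(c));
  return out;
}

// log-weights of the circular-permutation targets given current modes.
// rho, rhof: N x 3 complex mode matrices; lambda: length-N rates; tau = tf - t.
// logw(n0) = -(N/(2 D)) * sum_{p>=1} c_p |rhof_p e^{i w_p n0} - rho_p e^{-l tau}|^2
// with c_p = lambda_p / (1 - e^{-2 lambda_p tau}).  The n0 dependence is an
// inverse DFT of c_p * rhof_p * conj(rho_p e^{-lambda_p tau}).
static arma::vec perm_log_weights_full(const arma::cx_mat& rho,
                                       const arma::cx_mat& rhof,
                                       const arma::vec& lambda,
                                       double D, double tau) {
  const int N = rho.n_rows;
  arma::vec cp(N, arma::fill::zeros);
  arma::vec decay(N, arma::fill::ones);
  for (int p = 1; p < N; ++p) {
    cp(p) = weight_coef(lambda(p), tau);
    decay(p) = std::exp(-lambda(p) * tau);
  }
  arma::cx_mat s = rho.each_col() % arma::cx_vec(decay, arma::vec(N, arma::fill::zeros));
  double A = 0.0;
  arma::cx_vec B(N, arma::fill::zeros);
  for (int p = 1; p < N; ++p) {
    double row = 0.0;
    std::complex<double> bp(0.0, 0.0);
    for (int c = 0; c < 3; ++c) {
      std::complex<double> f = rhof(p, c), ss = s(p, c);
      row += std::norm(f) + std::norm(ss);
      bp += f * std::conj(ss);
    }
    A += cp(p) * row;
    B(p) = cp(p) * bp;
  }
  arma::cx_vec ft = arma::ifft(B) * static_cast<double>(N); // sum_p B_p e^{i w_p n0}
  arma::vec logw(N);
  for (int n0 = 0; n0 < N; ++n0)
    logw(n0) = -(N / (2.0 * D)) * (A - 2.0 * std::real(ft(n0)));
  return logw;
}

// normalize log-weights over a subset of permutations by log-sum-exp
static arma::vec normalize_logw(const arma::vec& logw_sub) {
  double m = logw_sub.max();
  if (!std::isfinite(m)) stop("all permutation log-weights are -Inf; conditioning target unreachable numerically");
  arma::vec w = arma::exp(logw_sub - m);
  return w / arma::accu(w);
}

// twist modes by a circular permutation: rho_p -> rho_p * e^{i w_p n0}
static arma::cx_mat twist(const arma::cx_mat& rhof, int n0) {
  const int N = rhof.n_rows;
  arma::cx_vec ph(N);
  for (int p = 0; p < N; ++p) {
    double ang = 2.0 * M_PI * p * n0 / N;
    ph(p) = std::complex<double>(std::cos(ang), std::sin(ang));
  }
  return rhof.each_col() % ph;
}

// ---------------------------------------------------------------------------
// bridge integrator

// conditioning: 0 = free, 1 = conditioned on the permutations listed in perms
// (length 1: plain bridge; length N: full circular-permutation bridge).
// lambda must be the true relaxation rates (2 D Omega_p), lambda(0) = 0.
// [[Rcpp::export]]
List cpp_run_bridge(const arma::mat& r0, const arma::mat& rf,
                    const arma::vec& lambda, double D,
                    double dt, double tf, int conditioning,
                    const arma::ivec& perms, int frame_stride) {
  const int N = r0.n_rows;
  const int M = static_cast<int>(std::lround(tf / dt));
  if (std::abs(M * dt - tf) > 1e-9 * tf) stop("dt must divide tf to within one step");
  const bool cond = conditioning != 0;
  const int nperm = perms.n_elem;

  arma::cx_mat rho = fft_cols(arma::conv_to<arma::cx_mat>::from(r0)) / double(N);
  arma::cx_mat rhof;
  arma::cx_mat target1; // single-permutation target
  if (cond) {
    rhof = fft_cols(arma::conv_to<arma::cx_mat>::from(rf)) / double(N);
    if (nperm == 1) target1 = twist(rhof, perms(0));
  }

  std::vector<arma::mat> frames;
  std::vector<double> times, topw;
  auto record = [&](double t, double w) {
    frames.push_back(arma::real(ifft_cols(rho)) * double(N));
    times.push_back(t);
    topw.push_back(w);
  };
  record(0.0, NA_REAL);

  const double sd = std::sqrt(2.0 * D * dt);
  int landed = NA_INTEGER;
  double last_top = NA_REAL;

  for (int k = 0; k < M; ++k) {
    double t = k * dt, tau = tf - t;

    if (cond && k == M - 1) {
      // final step: place exactly on the maximal-weight permutation target
      int n0 = perms(0);
      if (nperm > 1) {
        arma::vec logw_full = perm_log_weights_full(rho, rhof, lambda, D, tau);
        arma::vec sub(nperm);
        for (int j = 0; j < nperm; ++j) sub(j) = logw_full(perms(j));
        arma::vec w = normalize_logw(sub);
        arma::uword imax = w.index_max();
        n0 = perms(imax);
        last_top = w(imax);
      } else last_top = 1.0;
      rho = (nperm == 1) ? target1 : twist(rhof, n0);
      landed = n0;
      break;
    }

    arma::cx_mat noise = fft_cols(arma::conv_to<arma::cx_mat>::from(rnorm_mat(N, sd))) / double(N);
    arma::cx_mat drift(N, 3);

    if (!cond) {
      drift = -(rho.each_col() % arma::cx_vec(lambda, arma::vec(N, arma::fill::zeros)));
    } else {
      arma::cx_mat tgt;
      if (nperm == 1) {
        tgt = target1;
        last_top = 1.0;
      } else {
        arma::vec logw_full = perm_log_weights_full(rho, rhof, lambda, D, tau);
        arma::vec sub(nperm);
        for (int j = 0; j < nperm; ++j) sub(j) = logw_full(perms(j));
        arma::vec w = normalize_logw(sub);
        last_top = w.max();
        // phi_p = sum_{n0} w_{n0} e^{i w_p n0}; weighted target = rhof_p * phi_p
        arma::cx_vec wfull(N, arma::fill::zeros);
        for (int j = 0; j < nperm; ++j) wfull(perms(j)) = w(j);
        arma::cx_vec phi = arma::ifft(wfull) * double(N);
        tgt = rhof.each_col() % phi;
      }
      for (int p = 0; p < N; ++p) {
        double lam = lambda(p);
        double coef = pull_coef(lam, tau);
        double dec = (lam > 0.0) ? std::exp(-lam * tau) : 1.0;
        for (int c = 0; c < 3; ++c)
          drift(p, c) = -lam * rho(p, c) + coef * (tgt(p, c) - rho(p, c) * dec);
      }
    }

    rho += drift * dt + noise;
    double t1 = (k + 1) * dt;
    if ((k + 1) % frame_stride == 0 && k + 1 < M)
      record(t1, cond ? last_top : NA_REAL);
  }
  record(tf, cond ? last_top : NA_REAL);

  int nf = frames.size();
  arma::cube fr(N, 3, nf);
  for (int i = 0; i < nf; ++i) fr.slice(i) = frames[i];
  return List::create(_["frames"] = fr,
                      _["times"] = arma::vec(times),
                      _["top_weight"] = arma::vec(topw),
                      _["landed_perm"] = landed);
}

// one-step diagnostics used to cross-check the R reference implementation
// [[Rcpp::export]]
List cpp_bridge_debug(const arma::cx_mat& rho, const arma::cx_mat& rhof,
                      const arma::vec& lambda, double D,
                      double t, double tf, const arma::ivec& perms) {
  double tau = tf - t;
  const int N = rho.n_rows;
  arma::vec logw_full = perm_log_weights_full(rho, rhof, lambda, D, tau);
  arma::vec sub(perms.n_elem);
  for (arma::uword j = 0; j < perms.n_elem; ++j) sub(j) = logw_full(perms(j));
  arma::vec w = normalize_logw(sub);
  arma::cx_vec wfull(N, arma::fill::zeros);
  for (arma::uword j = 0; j < perms.n_elem; ++j) wfull(perms(j)) = w(j);
  arma::cx_vec phi = arma::ifft(wfull) * double(N);
  arma::cx_mat tgt = rhof.each_col() % phi;
  arma::cx_mat drift(N, 3);
  for (int p = 0; p < N; ++p) {
    double lam = lambda(p);
    double coef = pull_coef(lam, tau);
    double dec = (lam > 0.0) ? std::exp(-lam * tau) : 1.0;
    for (int c = 0; c < 3; ++c)
      drift(p, c) = -lam * rho(p, c) + coef * (tgt(p, c) - rho(p, c) * dec);
  }
  return List::create(_["logw"] = sub, _["weights"] = w, _["drift"] = drift);
}

// ---------------------------------------------------------------------------
// exact Gauss-integral writhe of a closed polygon (Klenin & Langowski method)

static inline arma::rowvec3 unit_cross(const arma::rowvec3& x, const arma::rowvec3& y) {
  arma::rowvec3 c = arma::cross(x, y);
  double n = arma::norm(c);
  if (n < 1e-14) return arma::rowvec3(arma::fill::zeros);
  return c / n;
}
static inline double asin_clamp(double x) {
  return std::asin(std::max(-1.0, std::min(1.0, x)));
}

// [[Rcpp::export]]
double cpp_gauss_writhe(const arma::mat& r) {
  const int N = r.n_rows;
  double wr = 0.0;
  for (int i = 0; i < N; ++i) {
    arma::rowvec3 p1 = r.row(i), p2 = r.row((i + 1) % N);
    for (int j = i + 2; j < N; ++j) {
      if (i == 0 && j == N - 1) continue; // adjacent around the wrap
      arma::rowvec3 p3 = r.row(j), p4 = r.row((j + 1) % N);
      arma::rowvec3 r13 = p3 - p1, r14 = p4 - p1, r23 = p3 - p2, r24 = p4 - p2;
      arma::rowvec3 n1 = unit_cross(r13, r14);
      arma::rowvec3 n2 = unit_cross(r14, r24);
      arma::rowvec3 n3 = unit_cross(r24, r23);
      arma::rowvec3 n4 = unit_cross(r23, r13);
      double omega = asin_clamp(arma::dot(n1, n2)) + asin_clamp(arma::dot(n2, n3)) +
                     asin_clamp(arma::dot(n3, n4)) + asin_clamp(arma::dot(n4, n1));
      double sg = arma::dot(arma::cross(p4 - p3, p2 - p1), r13);
      wr += (sg >= 0 ? omega : -omega);
    }
  }
  return wr / (2.0 * M_PI);
}

// ---------------------------------------------------------------------------
// projection crossings

// orthonormal frame with third axis d (unit)
static void make_frame(const arma::rowvec3& d, arma::rowvec3& e1, arma::rowvec3& e2) {
  arma::rowvec3 ref = (std::abs(d(0)) < 0.9) ? arma::rowvec3{1, 0, 0}
                                             : arma::rowvec3{0, 1, 0};
  e1 = unit_cross(d, ref);
  e2 = unit_cross(d, e1);
}

// crossing list of the projection of ring r along direction d.
// Returns a list with matrix "crossings" (columns: seg_i, s, seg_j, t,
// over = 1 if segment i passes over, sign) and flag "degenerate".
// eps is relative to the projected extent.
// [[Rcpp::export]]
List cpp_diagram(const arma::mat& r, const arma::vec& d, double eps = 1e-9) {
  const int N = r.n_rows;
  arma::rowvec3 dd = arma::rowvec3(d.t());
  dd /= arma::norm(dd);
  arma::rowvec3 e1, e2;
  make_frame(dd, e1, e2);
  arma::vec x = r * e1.t(), y = r * e2.t(), z = r * dd.t();
  double scale = std::max(x.max() - x.min(), y.max() - y.min());
  if (scale <= 0) scale = 1.0;
  double tolp = eps * scale;
  bool degen = false;
  std::vector<std::array<double, 6>> cr;
  for (int i = 0; i < N && !degen; ++i) {
    int i1 = (i + 1) % N;
    double ux = x(i1) - x(i), uy = y(i1) - y(i);
    for (int j = i + 2; j < N; ++j) {
      if (i == 0 && j == N - 1) continue;
      int j1 = (j + 1) % N;
      double vx = x(j1) - x(j), vy = y(j1) - y(j);
      double den = ux * vy - uy * vx;
      double wx = x(j) - x(i), wy = y(j) - y(i);
      if (std::abs(den) < 1e-14 * scale * scale) {
        // parallel in projection: degenerate only if they could overlap
        double crossw = ux * wy - uy * wx;
        if (std::abs(crossw) < tolp * scale) { degen = true; break; }
        continue;
      }
      double s = (wx * vy - wy * vx) / den;
      double t = (wx * uy - wy * ux) / den;
      if (s <= -eps || s >= 1 + eps || t <= -eps || t >= 1 + eps) continue;
      if (s < eps || s > 1 - eps || t < eps || t > 1 - eps) { degen = true; break; }
      double zi = z(i) + s * (z(i1) - z(i));
      double zj = z(j) + t * (z(j1) - z(j));
      if (std::abs(zi - zj) < tolp) { degen = true; break; }
      bool i_over = zi > zj;
      // sign from the right-hand rule: d . (t_over x t_under)
      double cz = i_over ? (ux * vy - uy * vx) : (vx * uy - vy * ux);
      double sign = cz > 0 ? 1.0 : -1.0;
      cr.push_back({double(i), s, double(j), t, i_over ? 1.0 : 0.0, sign});
    }
  }
  arma::mat out(cr.size(), 6);
  for (size_t k = 0; k < cr.size(); ++k)
    for (int c = 0; c < 6; ++c) out(k, c) = cr[k][c];
  return List::create(_["crossings"] = out, _["degenerate"] = degen);
}

// signed crossing counts over many directions (rows of dirs, unit vectors).
// Returns matrix with columns n_plus, n_minus, degenerate(0/1).
// [[Rcpp::export]]
arma::mat cpp_crossing_counts(const arma::mat& r, const arma::mat& dirs,
                              double eps = 1e-9) {
  const int N = r.n_rows, M = dirs.n_rows;
  arma::mat out(M, 3, arma::fill::zeros);
  for (int m = 0; m < M; ++m) {
    arma::rowvec3 dd = dirs.row(m);
    dd /= arma::norm(dd);
    arma::rowvec3 e1, e2;
    make_frame(dd, e1, e2);
    arma::vec x = r * e1.t(), y = r * e2.t(), z = r * dd.t();
    double scale = std::max(x.max() - x.min(), y.max() - y.min());
    if (scale <= 0) scale = 1.0;
    double tolp = eps * scale;
    int np = 0, nm = 0;
    bool degen = false;
    for (int i = 0; i < N && !degen; ++i) {
      int i1 = (i + 1) % N;
      double ux = x(i1) - x(i), uy = y(i1) - y(i);
      for (int j = i + 2; j < N; ++j) {
        if (i == 0 && j == N - 1) continue;
        int j1 = (j + 1) % N;
        double vx = x(j1) - x(j), vy = y(j1) - y(j);
        double den = ux * vy - uy * vx;
        double wx = x(j) - x(i), wy = y(j) - y(i);
        if (std::abs(den) < 1e-14 * scale * scale) {
          double crossw = ux * wy - uy * wx;
          if (std::abs(crossw) < tolp * scale) { degen = true; break; }
          continue;
        }
        double s = (wx * vy - wy * vx) / den;
        double t = (wx * uy - wy * ux) / den;
        if (s <= -eps || s >= 1 + eps || t <= -eps || t >= 1 + eps) continue;
        if (s < eps || s > 1 - eps || t < eps || t > 1 - eps) { degen = true; break; }
        double zi = z(i) + s * (z(i1) - z(i));
        double zj = z(j) + t * (z(j1) - z(j));
        if (std::abs(zi - zj) < tolp) { degen = true; break; }
        bool i_over = zi > zj;
        double cz = i_over ? (ux * vy - uy * vx) : (vx * uy - vy * ux);
        if (cz > 0) ++np; else ++nm;
      }
    }
    out(m, 0) = np;
    out(m, 1) = nm;
    out(m, 2) = degen ? 1.0 : 0.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// self-avoidance and crankshaft Monte Carlo

// minimum distance between segments (p1,p2) and (p3,p4) (Lumelsky)
static double seg_dist(const arma::rowvec3& p1, const arma::rowvec3& p2,
                       const arma::rowvec3& p3, const arma::rowvec3& p4) {
  arma::rowvec3 u = p2 - p1, v = p4 - p3, w = p1 - p3;
  double a = arma::dot(u, u), b = arma::dot(u, v), c = arma::dot(v, v);
  double dd = arma::dot(u, w), e = arma::dot(v, w);
  double Dd = a * c - b * b;
  double sc, sN, sD = Dd, tc, tN, tD = Dd;
  if (Dd < 1e-12 * a * c + 1e-300) { sN = 0.0; sD = 1.0; tN = e; tD = c; }
  else {
    sN = b * e - c * dd; tN = a * e - b * dd;
    if (sN < 0) { sN = 0; tN = e; tD = c; }
    else if (sN > sD) { sN = sD; tN = e + b; tD = c; }
  }
  if (tN < 0) {
    tN = 0;
    if (-dd < 0) sN = 0; else if (-dd > a) sN = sD; else { sN = -dd; sD = a; }
  } else if (tN > tD) {
    tN = tD;
    if (-dd + b < 0) sN = 0; else if (-dd + b > a) sN = sD; else { sN = -dd + b; sD = a; }
  }
  sc = (std::abs(sN) < 1e-300) ? 0.0 : sN / sD;
  tc = (std::abs(tN) < 1e-300) ? 0.0 : tN / tD;
  arma::rowvec3 dP = w + sc * u - tc * v;
  return arma::norm(dP);
}

// true if any pair of non-adjacent cylinder segments comes closer than sigma
// [[Rcpp::export]]
bool cpp_check_overlap(const arma::mat& r, double sigma) {
  const int N = r.n_rows;
  for (int i = 0; i < N; ++i) {
    arma::rowvec3 p1 = r.row(i), p2 = r.row((i + 1) % N);
    for (int j = i + 2; j < N; ++j) {
      if (i == 0 && j == N - 1) continue;
      if (seg_dist(p1, p2, r.row(j), r.row((j + 1) % N)) < sigma) return true;
    }
  }
  return false;
}

// bending energy terms (K/2)(r_{n+1}-2r_n+r_{n-1})^2 for a window of n values
static double bend_terms(const arma::mat& r, const std::vector<int>& ns, double K) {
  const int N = r.n_rows;
  double u = 0.0;
  for (int n : ns) {
    int nm = (n - 1 + N) % N, np = (n + 1) % N;
    arma::rowvec3 d2 = r.row(np) - 2.0 * r.row(n) + r.row(nm);
    u += arma::dot(d2, d2);
  }
  return 0.5 * K * u;
}

// squared min distance lower bound via segment midpoints (prefilter)
static inline bool far_apart(const arma::mat& r, int i, int j, double cut2, int N) {
  double dx = 0.5 * (r(i, 0) + r((i + 1) % N, 0) - r(j, 0) - r((j + 1) % N, 0));
  double dy = 0.5 * (r(i, 1) + r((i + 1) % N, 1) - r(j, 1) - r((j + 1) % N, 1));
  double dz = 0.5 * (r(i, 2) + r((i + 1) % N, 2) - r(j, 2) - r((j + 1) % N, 2));
  return dx * dx + dy * dy + dz * dz > cut2;
}

// Metropolis MC of the self-avoiding semiflexible ring, mixing two
// closure-preserving local moves:
//  - crankshaft: beads h1+1 .. h1+L rotate rigidly about the chord through
//    beads h1 and h2 = h1+L+1 by a uniform angle in (-tm, tm) with
//    tm = min(max_angle, max_disp / r_max), r_max the largest distance of a
//    moved bead from the rotation axis. tm depends only on rotation
//    invariants, so forward and reverse proposals match (detailed balance).
//    Bond lengths are preserved; only the hinge bending terms change.
//  - single-bead displacement: bead i moves by a uniform vector in a cube of
//    half-width min(0.2 a, max_disp)/sqrt(3); relaxes bond lengths (which
//    crankshaft moves alone leave frozen).
// Capping every per-move displacement below the cylinder diameter prevents
// strand passage that an end-state overlap test cannot see. Moves creating
// cylinder overlaps (closest approach < sigma) are rejected.
// [[Rcpp::export]]
List cpp_mc_equilibrate(const arma::mat& r0, double a, double K, double sigma,
                        int n_sweeps, int max_arc, double max_angle,
                        double max_disp) {
  arma::mat r = r0;
  const int N = r.n_rows;
  long acc = 0, tot = 0;
  std::vector<double> energy_trace;
  // segments have length ~ a (bond scale); prefilter radius covers
  // half-lengths of both segments plus sigma, padded
  auto seg_halflen = [&](const arma::mat& rr, int i) {
    return 0.5 * arma::norm(rr.row((i + 1) % N) - rr.row(i));
  };
  double amp = std::min(0.2 * a, max_disp) / std::sqrt(3.0);
  if (amp <= 0) amp = 0.2 * a / std::sqrt(3.0);
  // window of bending terms affected by rotating beads h1+1..h1+L
  auto win = [&](int h1, int L) {
    std::vector<int> ns;
    int h2 = (h1 + L + 1) % N;
    ns.push_back(h1);
    ns.push_back((h1 + 1) % N);
    ns.push_back((h2 - 1 + N) % N);
    ns.push_back(h2);
    std::sort(ns.begin(), ns.end());
    ns.erase(std::unique(ns.begin(), ns.end()), ns.end());
    return ns;
  };
  arma::vec hl(N);
  for (int i = 0; i < N; ++i) hl(i) = seg_halflen(r, i);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int m = 0; m < N; ++m) {
      ++tot;
      if (unif_rand() < 0.5) {
        // ---- single-bead displacement ----
        int i = static_cast<int>(unif_rand() * N) % N;
        arma::rowvec3 delta;
        for (int c = 0; c < 3; ++c) delta(c) = (2.0 * unif_rand() - 1.0) * amp;
        int im = (i - 1 + N) % N, ip = (i + 1) % N;
        std::vector<int> ns = {im, i, ip};
        arma::rowvec3 b1o = r.row(i) - r.row(im), b2o = r.row(ip) - r.row(i);
        double u_old = bend_terms(r, ns, K) +
          1.5 / (a * a) * (arma::dot(b1o, b1o) + arma::dot(b2o, b2o));
        arma::mat rnew = r;
        rnew.row(i) += delta;
        arma::rowvec3 b1n = rnew.row(i) - rnew.row(im), b2n = rnew.row(ip) - rnew.row(i);
        double dU = bend_terms(rnew, ns, K) +
          1.5 / (a * a) * (arma::dot(b1n, b1n) + arma::dot(b2n, b2n)) - u_old;
        if (dU > 0 && unif_rand() > std::exp(-dU)) continue;
        if (sigma > 0) {
          bool clash = false;
          for (int q = 0; q < 2 && !clash; ++q) {
            int si = (im + q + N) % N; // segments im and i move
            double hli = seg_halflen(rnew, si);
            arma::rowvec3 p1 = rnew.row(si), p2 = rnew.row((si + 1) % N);
            for (int j = 0; j < N; ++j) {
              if (j == si || (j + 1) % N == si || (si + 1) % N == j) continue;
              if (q == 1 && j == im) continue; // pair (im, i) handled once
              double cut = hli + hl(j) + sigma + 2.0 * amp;
              if (far_apart(rnew, si, j, cut * cut, N)) continue;
              if (seg_dist(p1, p2, rnew.row(j), rnew.row((j + 1) % N)) < sigma) {
                clash = true;
                break;
              }
            }
          }
          if (clash) continue;
        }
        r = rnew;
        hl(im) = seg_halflen(r, im);
        hl(i) = seg_halflen(r, i);
        ++acc;
      } else {
        // ---- crankshaft ----
        int h1 = static_cast<int>(unif_rand() * N) % N;
        int L = 1 + static_cast<int>(unif_rand() * max_arc) % max_arc;
        if (L > N - 3) L = N - 3;
        int h2 = (h1 + L + 1) % N;
        arma::rowvec3 axis = r.row(h2) - r.row(h1);
        double an = arma::norm(axis);
        if (an < 1e-12) continue;
        axis /= an;
        double rmax = 0.0;
        for (int q = 1; q <= L; ++q) {
          arma::rowvec3 v = r.row((h1 + q) % N) - r.row(h1);
          arma::rowvec3 perp = v - axis * arma::dot(axis, v);
          rmax = std::max(rmax, arma::norm(perp));
        }
        double tm = max_angle;
        if (max_disp > 0 && rmax > 0) tm = std::min(tm, max_disp / rmax);
        double theta = (2.0 * unif_rand() - 1.0) * tm;
        // Rodrigues rotation about the line through r(h1) with direction axis
        double ct = std::cos(theta), st = std::sin(theta);
        std::vector<int> ns = win(h1, L);
        double u_old = bend_terms(r, ns, K);
        arma::mat rnew = r;
        for (int q = 1; q <= L; ++q) {
          int idx = (h1 + q) % N;
          arma::rowvec3 v = r.row(idx) - r.row(h1);
          arma::rowvec3 vrot = v * ct + arma::cross(axis, v) * st +
                               axis * (arma::dot(axis, v) * (1.0 - ct));
          rnew.row(idx) = r.row(h1) + vrot;
        }
        double dU = bend_terms(rnew, ns, K) - u_old;
        if (dU > 0 && unif_rand() > std::exp(-dU)) continue;
        if (sigma > 0) {
          // moved segments: h1 .. h1+L (segment k joins beads k and k+1).
          // Interior moved segments (h1+1 .. h1+L-1) rotate rigidly, so
          // their mutual distances are unchanged; the end segments h1 and
          // h1+L change shape and must be re-checked against everything.
          bool clash = false;
          for (int q = 0; q <= L && !clash; ++q) {
            int si = (h1 + q) % N;
            bool interior_i = (q >= 1 && q <= L - 1);
            arma::rowvec3 p1 = rnew.row(si), p2 = rnew.row((si + 1) % N);
            for (int j = 0; j < N; ++j) {
              if (j == si) continue;
              int relj = (j - h1 + N) % N;
              bool moved_j = relj <= L;
              bool interior_j = (relj >= 1 && relj <= L - 1);
              if (moved_j && interior_i && interior_j) continue; // rigid pair
              if (moved_j && relj < q) continue;                  // counted once
              // skip adjacent segments
              if ((j + 1) % N == si || (si + 1) % N == j) continue;
              double cut = hl(si) + hl(j) + sigma;
              if (far_apart(rnew, si, j, cut * cut, N)) continue;
              if (seg_dist(p1, p2, rnew.row(j), rnew.row((j + 1) % N)) < sigma) {
                clash = true;
                break;
              }
            }
          }
          if (clash) continue;
        }
        r = rnew;
        ++acc;
      }
    }
    if ((sweep + 1) % 10 == 0) {
      // cheap energy diagnostic: full bending + stretching energy
      double ub = 0.0, us = 0.0;
      for (int n = 0; n < N; ++n) {
        int np = (n + 1) % N, nm = (n - 1 + N) % N;
        arma::rowvec3 d1 = r.row(np) - r.row(n);
        arma::rowvec3 d2 = r.row(np) - 2.0 * r.row(n) + r.row(nm);
        us += arma::dot(d1, d1);
        ub += arma::dot(d2, d2);
      }
      energy_trace.push_back(1.5 / (a * a) * us + 0.5 * K * ub);
    }
  }
  return List::create(_["positions"] = r,
                      _["acceptance"] = tot > 0 ? double(acc) / double(tot) : NA_REAL,
                      _["energy_trace"] = arma::vec(energy_trace));
}
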