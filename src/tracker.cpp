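// Polynomial system evaluation and predictor-corrector path tracking.
//
// Systems arrive as lists of sparse polynomials (integer exponent matrix +
// complex coefficients) over a shared variable vector.  For homotopies the
// last variable is the path variable s, mapped to the tracking parameter t
// by one of three smooth paths (linear, monodromy circle, gamma segment).
// The predictor is RK4 on the Davidenko ODE dz/dt = -Jz^{-1} dH/dt and the
// corrector is Newton's method with adaptive step halving.

#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

struct Term {
  cplx coef;
  std::vector<int> var;  // active variable indices
  std::vector<int> exp;  // exponents (>= 1)
};

struct Poly {
  std::vector<Term> terms;
};

struct PolySys {
  int nvar;
  std::vector<Poly> polys;
};

static PolySys build_system(const List& sysR, int nvar) {
  PolySys S;
  S.nvar = nvar;
  int np = sysR.size();
  S.polys.resize(np);
  for (int i = 0; i < np; ++i) {
    List pr = sysR[i];
    IntegerMatrix E = pr["E"];
    ComplexVector cc = pr["c"];
    int nt = E.nrow();
    Poly& P = S.polys[i];
    P.terms.resize(nt);
    for (int tIdx = 0; tIdx < nt; ++tIdx) {
      Term& T = P.terms[tIdx];
      T.coef = cplx(cc[tIdx].r, cc[tIdx].i);
      for (int j = 0; j < E.ncol(); ++j) {
        if (E(tIdx, j) > 0) {
          T.var.push_back(j);
          T.exp.push_back(E(tIdx, j));
        }
      }
    }
  }
  return S;
}

static inline cplx cpow_int(cplx x, int e) {
  cplx out(1.0, 0.0);
  while (e > 0) { out *= x; --e; }
  return out;
}

// Evaluate values and (optionally) the full Jacobian at z.
static void eval_sys(const PolySys& S, const std::vector<cplx>& z,
                     std::vector<cplx>& val, std::vector<cplx>* jac) {
  int np = S.polys.size(), nv = S.nvar;
  val.assign(np, cplx(0, 0));
  if (jac) jac->assign((size_t)np * nv, cplx(0, 0));
  std::vector<cplx> pw;  // per-term powers
  for (int i = 0; i < np; ++i) {
    const Poly& P = S.polys[i];
    for (size_t tIdx = 0; tIdx < P.terms.size(); ++tIdx) {
      const Term& T = P.terms[tIdx];
      int na = T.var.size();
      pw.assign(na, cplx(1, 0));
      cplx prod = T.coef;
      for (int a = 0; a < na; ++a) {
        pw[a] = cpow_int(z[T.var[a]], T.exp[a]);
        prod *= pw[a];
      }
      val[i] += prod;
      if (jac) {
        for (int a = 0; a < na; ++a) {
          // d(term)/d var_a = coef * e_a * x_a^{e_a-1} * prod_{b!=a} x_b^{e_b}
          cplx d = T.coef * (double)T.exp[a] *
                   cpow_int(z[T.var[a]], T.exp[a] - 1);
          for (int b = 0; b < na; ++b)
            if (b != a) d *= pw[b];
          (*jac)[(size_t)i * nv + T.var[a]] += d;
        }
      }
    }
  }
}

// Solve A x = b for square complex A via Gaussian elimination with partial
// pivoting.  Returns false on (numerical) singularity.
static bool solve_lin(std::vector<cplx> A, std::vector<cplx> b, int n,
                      std::vector<cplx>& x) {
  std::vector<int> piv(n);
  for (int i = 0; i < n; ++i) piv[i] = i;
  for (int k = 0; k < n; ++k) {
    int best = k;
    double bv = std::abs(A[(size_t)k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::abs(A[(size_t)i * n + k]);
      if (v > bv) { bv = v; best = i; }
    }
    if (bv < 1e-300) return false;
    if (best != k) {
      for (int j = 0; j < n; ++j) std::swap(A[(size_t)k * n + j], A[(size_t)best * n + j]);
      std::swap(b[k], b[best]);
    }
    for (int i = k + 1; i < n; ++i) {
      cplx f = A[(size_t)i * n + k] / A[(size_t)k * n + k];
      if (f == cplx(0, 0)) continue;
      A[(size_t)i * n + k] = cplx(0, 0);
      for (int j = k + 1; j < n; ++j) A[(size_t)i * n + j] -= f * A[(size_t)k * n + j];
      b[i] -= f * b[k];
    }
  }
  x.assign(n, cplx(0, 0));
  for (int i = n - 1; i >= 0; --i) {
    cplx s = b[i];
    for (int j = i + 1; j < n; ++j) s -= A[(size_t)i * n + j] * x[j];
    x[i] = s / A[(size_t)i * n + i];
  }
  return true;
}

struct PathFun {
  int type;      // 0 linear, 1 monodromy circle, 2 gamma segment
  cplx gamma;
  cplx s(double t) const {
    switch (type) {
      case 0: return cplx(t, 0);
      case 1: {
        cplx e = std::exp(cplx(0, 2 * M_PI * (1 - t)));
        return cplx(1, 0) - e;
      }
      default: return gamma * t / (cplx(1, 0) + (gamma - cplx(1, 0)) * t);
    }
  }
  cplx sprime(double t) const {
    switch (type) {
      case 0: return cplx(1, 0);
      case 1: return cplx(0, 2 * M_PI) * std::exp(cplx(0, 2 * M_PI * (1 - t)));
      default: {
        cplx d = cplx(1, 0) + (gamma - cplx(1, 0)) * t;
        return gamma / (d * d);
      }
    }
  }
};

struct Settings {
  double init_step, min_step, newton_tol, endpoint_tol, div_bound;
  int max_newton, max_steps;
};

// Evaluate homotopy H(z, t) = S(z, s(t)) value and z-Jacobian; also ds-column.
static void eval_H(const PolySys& S, const std::vector<cplx>& z, cplx sval,
                   std::vector<cplx>& val, std::vector<cplx>* Jz,
                   std::vector<cplx>* Hs) {
  int n = S.nvar - 1;  // last variable is s
  std::vector<cplx> full(z);
  full.push_back(sval);
  std::vector<cplx> jac;
  eval_sys(S, full, val, (Jz || Hs) ? &jac : 0);
  if (Jz) {
    Jz->assign((size_t)val.size() * n, cplx(0, 0));
    for (size_t i = 0; i < val.size(); ++i)
      for (int j = 0; j < n; ++j)
        (*Jz)[i * n + j] = jac[i * S.nvar + j];
  }
  if (Hs) {
    Hs->assign(val.size(), cplx(0, 0));
    for (size_t i = 0; i < val.size(); ++i)
      (*Hs)[i] = jac[i * S.nvar + S.nvar - 1];
  }
}

static double vec_norm(const std::vector<cplx>& v) {
  double m = 0;
  for (size_t i = 0; i < v.size(); ++i) m = std::max(m, std::abs(v[i]));
  return m;
}

// Newton corrector at fixed t; returns true if converged.
static bool newton_correct(const PolySys& S, std::vector<cplx>& z, cplx sval,
                           double tol, int maxit) {
  int n = z.size();
  std::vector<cplx> val, Jz, dz;
  for (int it = 0; it < maxit; ++it) {
    eval_H(S, z, sval, val, &Jz, 0);
    if (!solve_lin(Jz, val, n, dz)) return false;
    double znorm = 1.0, dnorm = 0.0;
    for (int j = 0; j < n; ++j) {
      znorm = std::max(znorm, std::abs(z[j]));
      dnorm = std::max(dnorm, std::abs(dz[j]));
      z[j] -= dz[j];
    }
    if (dnorm <= tol * znorm) return true;
  }
  // accept if the residual is already tiny
  eval_H(S, z, sval, val, 0, 0);
  double scale = 1.0;
  for (int j = 0; j < n; ++j) scale = std::max(scale, std::abs(z[j]));
  return vec_norm(val) <= tol * scale;
}

// One Davidenko RK4 + Newton step from t to t-h; z updated in place on
// success.
static bool rk4_step(const PolySys& S, std::vector<cplx>& z, double t,
                     double h, const PathFun& path, const Settings& set) {
  int n = z.size();
  std::vector<cplx> val, Jz, Hs, k1, k2, k3, k4, ztmp(n);
  std::vector<cplx> rhs(n);
  // derivative at (z, t): dz/dt = -Jz^{-1} (Hs * s'(t))
  struct Deriv {
    const PolySys& S; const PathFun& path;
    bool operator()(const std::vector<cplx>& zz, double tt,
                    std::vector<cplx>& out) {
      std::vector<cplx> val, Jz, Hs;
      eval_H(S, zz, path.s(tt), val, &Jz, &Hs);
      cplx sp = path.sprime(tt);
      int n = zz.size();
      std::vector<cplx> b(val.size());
      for (size_t i = 0; i < Hs.size(); ++i) b[i] = Hs[i] * sp;
      std::vector<cplx> sol;
      if (!solve_lin(Jz, b, n, sol)) return false;
      out.resize(n);
      for (int j = 0; j < n; ++j) out[j] = -sol[j];
      return true;
    }
  } deriv{S, path};

  if (!deriv(z, t, k1)) return false;
  for (int j = 0; j < n; ++j) ztmp[j] = z[j] - 0.5 * h * k1[j];
  if (!deriv(ztmp, t - 0.5 * h, k2)) return false;
  for (int j = 0; j < n; ++j) ztmp[j] = z[j] - 0.5 * h * k2[j];
  if (!deriv(ztmp, t - 0.5 * h, k3)) return false;
  for (int j = 0; j < n; ++j) ztmp[j] = z[j] - h * k3[j];
  if (!deriv(ztmp, t - h, k4)) return false;
  std::vector<cplx> znew(n);
  for (int j = 0; j < n; ++j)
    znew[j] = z[j] - h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
  if (!newton_correct(S, znew, path.s(t - h), set.newton_tol, set.max_newton))
    return false;
  z = znew;
  return true;
}

// [[Rcpp::export]]
List cpp_eval_system(List sysR, int nvar, ComplexVector zR, bool jacobian) {
  PolySys S = build_system(sysR, nvar);
  std::vector<cplx> z(nvar);
  for (int j = 0; j < nvar; ++j) z[j] = cplx(zR[j].r, zR[j].i);
  std::vector<cplx> val, jac;
  eval_sys(S, z, val, jacobian ? &jac : 0);
  int np = val.size();
  ComplexVector vR(np);
  for (int i = 0; i < np; ++i) { vR[i].r = val[i].real(); vR[i].i = val[i].imag(); }
  List out = List::create(Named("value") = vR);
  if (jacobian) {
    ComplexMatrix JR(np, nvar);
    for (int i = 0; i < np; ++i)
      for (int j = 0; j < nvar; ++j) {
        JR(i, j).r = jac[(size_t)i * nvar + j].real();
        JR(i, j).i = jac[(size_t)i * nvar + j].imag();
      }
    out["jacobian"] = JR;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_track(List sysR, int nvar, List startsR, int stype,
               ComplexVector gammaR, NumericVector settingsR) {
  // nvar counts the z variables; the system has nvar+1 columns (s last).
  PolySys S = build_system(sysR, nvar + 1);
  PathFun path;
  path.type = stype;
  path.gamma = cplx(gammaR[0].r, gammaR[0].i);
  Settings set;
  set.init_step = settingsR[0];
  set.min_step = settingsR[1];
  set.newton_tol = settingsR[2];
  set.max_newton = (int)settingsR[3];
  set.endpoint_tol = settingsR[4];
  set.max_steps = (int)settingsR[5];
  set.div_bound = settingsR[6];

  int npaths = startsR.size();
  List results(npaths);
  for (int pIdx = 0; pIdx < npaths; ++pIdx) {
    ComplexVector z0R = startsR[pIdx];
    std::vector<cplx> z(nvar);
    for (int j = 0; j < nvar; ++j) z[j] = cplx(z0R[j].r, z0R[j].i);
    double t = 1.0, dt = set.init_step;
    int status = 0, steps = 0, consec = 0;
    // divergence thresholds are relative to the start-point scale (jet
    // coordinates are legitimately huge for high truncation orders)
    double zn0 = 1.0;
    for (int j = 0; j < nvar; ++j) zn0 = std::max(zn0, std::abs(z[j]));
    double divb = set.div_bound * zn0, stallb = 1e4 * zn0;
    while (t > 1e-14) {
      if (steps++ > set.max_steps) { status = 3; break; }
      double h = std::min(dt, t);
      if (rk4_step(S, z, t, h, path, set)) {
        t -= h;
        if (++consec >= 5) { dt = std::min(dt * 2.0, set.init_step * 4.0); consec = 0; }
      } else {
        dt *= 0.5;
        consec = 0;
        if (dt < set.min_step) {
          double zn = 0;
          for (int j = 0; j < nvar; ++j) zn = std::max(zn, std::abs(z[j]));
          // step underflow at large |z| is a path drifting to infinity;
          // near t = 0 the endpoint may still be recoverable by the polish
          status = (zn > stallb) ? 1 : 2;
          break;
        }
      }
      double zn = 0;
      for (int j = 0; j < nvar; ++j) zn = std::max(zn, std::abs(z[j]));
      if (zn > divb) { status = 1; break; }
    }
    double resid = NA_REAL;
    bool salvaged = false;
    if (status == 2 && t < 0.01) {
      // salvage: the path stalled very close to the target; accept it if
      // Newton converges at t = 0
      std::vector<cplx> zsave = z;
      newton_correct(S, z, path.s(0.0), set.endpoint_tol, 20);
      std::vector<cplx> val;
      eval_H(S, z, path.s(0.0), val, 0, 0);
      double scale = 1.0;
      for (int j = 0; j < nvar; ++j) scale = std::max(scale, std::abs(z[j]));
      if (vec_norm(val) / scale <= 1e-9) {
        status = 0;
        resid = vec_norm(val) / scale;
        salvaged = true;
      } else {
        z = zsave;
      }
    }
    if (status == 0 && !salvaged) {
      // endpoint polish at t = 0; convergence is judged by the relative
      // residual (the Newton step criterion can be unreachable in double
      // precision at moderately large endpoints)
      newton_correct(S, z, path.s(0.0), set.endpoint_tol, 20);
      std::vector<cplx> val;
      eval_H(S, z, path.s(0.0), val, 0, 0);
      double scale = 1.0;
      for (int j = 0; j < nvar; ++j) scale = std::max(scale, std::abs(z[j]));
      resid = vec_norm(val) / scale;
      if (resid > 1e-9) status = 2;
    }
    ComplexVector zR(nvar);
    for (int j = 0; j < nvar; ++j) { zR[j].r = z[j].real(); zR[j].i = z[j].imag(); }
    results[pIdx] = List::create(Named("z") = zR, Named("status") = status,
                                 Named("residual") = resid,
                                 Named("steps") = steps);
  }
  return results;
}

// [[Rcpp::export]]
List cpp_newton(List sysR, int nvar, ComplexVector zR, double tol, int maxit) {
  PolySys S = build_system(sysR, nvar);
  std::vector<cplx> z(nvar);
  for (int j = 0; j < nvar; ++j) z[j] = cplx(zR[j].r, zR[j].i);
  std::vector<cplx> val, Jz, dz;
  bool ok = false;
  for (int it = 0; it < maxit; ++it) {
    eval_sys(S, z, val, &Jz);
    if (!solve_lin(Jz, val, nvar, dz)) break;
    double znorm = 1.0, dnorm = 0.0;
    for (int j = 0; j < nvar; ++j) {
      znorm = std::max(znorm, std::abs(z[j]));
      dnorm = std::max(dnorm, std::abs(dz[j]));
      z[j] -= dz[j];
    }
    if (dnorm <= tol * znorm) { ok = true; break; }
  }
  eval_sys(S, z, val, 0);
  double scale = 1.0;
  for (int j = 0; j < nvar; ++j) scale = std::max(scale, std::abs(z[j]));
  ComplexVector outz(nvar);
  for (int j = 0; j < nvar; ++j) { outz[j].r = z[j].real(); outz[j].i = z[j].imag(); }
  return List::create(Named("z") = outz, Named("converged") = ok,
                      Named("residual") = vec_norm(val) / scale);
}
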