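// Compiled evaluation of the switched N-body potential and its dynamics.
//
// A system is handed over as a flat list (see compile_system() on the R
// side): harmonic constraint bonds, switched terms with their pair, pairwise
// potential (closed forms only) and encoding program, plus an optional
// flat-bottom confinement well.  Each encoding function arrives as a postfix
// program over smoothed proximity leaves; a forward pass evaluates the
// value, a reverse (adjoint) pass gives the sensitivity of the root to every
// leaf, from which the exact chain-rule forces follow.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Leaf {
  int i, j;       // zero-based particle indices
  double alpha;
  double n;
};

struct Term {
  int pi, pj;     // zero-based pair
  int kind;       // 1 morse, 2 repulsive_morse, 3 harmonic
  double par[3];
  std::vector<int> code;     // 0 const, 1 leaf, 2 not, 3 and, 4 or
  std::vector<double> arg;
  std::vector<Leaf> leaves;
};

struct Bond { int i, j; double k, r0; };

struct Engine {
  int n, d;
  std::vector<double> mass;
  std::vector<Bond> bonds;
  std::vector<Term> terms;
  bool conf_on;
  double conf_k, conf_R;
  std::vector<double> conf_c;
};

Engine build(const List& sys) {
  Engine E;
  E.n = as<int>(sys["n"]);
  E.d = as<int>(sys["d"]);
  E.mass = as<std::vector<double> >(sys["masses"]);
  NumericMatrix B = sys["bonds"];
  for (int r = 0; r < B.nrow(); ++r) {
    Bond b;
    b.i = (int)B(r, 0); b.j = (int)B(r, 1); b.k = B(r, 2); b.r0 = B(r, 3);
    E.bonds.push_back(b);
  }
  List terms = sys["terms"];
  for (int t = 0; t < terms.size(); ++t) {
    List tl = terms[t];
    Term tm;
    tm.pi = as<int>(tl["pi"]);
    tm.pj = as<int>(tl["pj"]);
    tm.kind = as<int>(tl["kind"]);
    NumericVector par = tl["par"];
    for (int k = 0; k < 3; ++k) tm.par[k] = par[k];
    tm.code = as<std::vector<int> >(tl["code"]);
    tm.arg = as<std::vector<double> >(tl["arg"]);
    NumericMatrix lv = tl["leaves"];
    for (int r = 0; r < lv.nrow(); ++r) {
      Leaf lf;
      lf.i = (int)lv(r, 0) - 1;  // R-side leaves carry 1-based ids
      lf.j = (int)lv(r, 1) - 1;
      lf.alpha = lv(r, 2);
      lf.n = lv(r, 3);
      tm.leaves.push_back(lf);
    }
    E.terms.push_back(tm);
  }
  List conf = sys["conf"];
  E.conf_on = as<bool>(conf["on"]);
  E.conf_k = as<double>(conf["k"]);
  E.conf_R = as<double>(conf["radius"]);
  E.conf_c = as<std::vector<double> >(conf["center"]);
  return E;
}

inline double dist(const std::vector<double>& x, int d, int i, int j) {
  double s = 0;
  for (int k = 0; k < d; ++k) {
    double dx = x[i * d + k] - x[j * d + k];
    s += dx * dx;
  }
  return std::sqrt(s);
}

// h_{alpha,n}(r) and dh/dr; alpha in (0, Inf) handled analytically,
// degenerate alpha (0, Inf) give constants with zero slope.
inline void h_and_grad(double r, double alpha, double n, double& h, double& dh) {
  if (alpha == 0.0) { h = 0.0; dh = 0.0; return; }
  if (!R_finite(alpha)) { h = 1.0; dh = 0.0; return; }
  double s = (r * r) / (alpha * alpha);
  double t = std::pow(s, n);
  double denom = 1.0 + t;
  h = 1.0 / denom;
  double sm1 = (n == 1.0) ? 1.0 : std::pow(s, n - 1.0);
  dh = -(2.0 * n * r / (alpha * alpha)) * sm1 / (denom * denom);
}

// pairwise potential value and -dphi/dr
inline void pot_eval(int kind, const double* p, double r,
                     double& phi, double& fmag) {
  switch (kind) {
  case 1: {  // morse: D (1 - e)^2 - D
    double e = std::exp(-p[1] * (r - p[2]));
    phi = p[0] * (1 - e) * (1 - e) - p[0];
    fmag = -2.0 * p[0] * p[1] * e * (1 - e);
    break;
  }
  case 2: {  // repulsive branch, spliced to 0 beyond r_eq
    if (r < p[2]) {
      double e = std::exp(-p[1] * (r - p[2]));
      phi = p[0] * (1 - e) * (1 - e);
      fmag = -2.0 * p[0] * p[1] * e * (1 - e);
    } else {
      phi = 0.0; fmag = 0.0;
    }
    break;
  }
  case 3:    // harmonic
    phi = 0.5 * p[0] * (r - p[1]) * (r - p[1]);
    fmag = -p[0] * (r - p[1]);
    break;
  default:
    stop("unknown potential kind in compiled system");
  }
}

// Evaluate a term's encoding program.  Returns S; if adj != nullptr it is
// filled with dS/dh_leaf for every leaf (reverse sweep over the tape).
double eval_program(const Term& tm, const std::vector<double>& hval,
                    std::vector<double>* adj) {
  const size_t m = tm.code.size();
  std::vector<double> st;  st.reserve(m);
  std::vector<double> va(m), vb(m);  // operand values per instruction
  for (size_t k = 0; k < m; ++k) {
    switch (tm.code[k]) {
    case 0: st.push_back(tm.arg[k]); break;
    case 1: st.push_back(hval[(size_t)tm.arg[k]]); break;
    case 2: {
      double a = st.back(); st.pop_back();
      va[k] = a; st.push_back(1.0 - a); break;
    }
    case 3: {
      double b = st.back(); st.pop_back();
      double a = st.back(); st.pop_back();
      va[k] = a; vb[k] = b; st.push_back(a * b); break;
    }
    case 4: {
      double b = st.back(); st.pop_back();
      double a = st.back(); st.pop_back();
      va[k] = a; vb[k] = b; st.push_back(a + b - a * b); break;
    }
    default: stop("bad opcode");
    }
  }
  if (st.size() != 1) stop("malformed encoding program");
  double S = st[0];
  if (adj) {
    std::fill(adj->begin(), adj->end(), 0.0);
    // reverse sweep: propagate d(root)/d(instruction output)
    std::vector<double> bar(m, 0.0);
    if (m) bar[m - 1] = 1.0;
    // reconstruct operand instruction indices by replaying a stack of indices
    std::vector<int> ist;
    std::vector<int> opa(m, -1), opb(m, -1);
    for (size_t k = 0; k < m; ++k) {
      switch (tm.code[k]) {
      case 0: case 1: ist.push_back((int)k); break;
      case 2: opa[k] = ist.back(); ist.pop_back(); ist.push_back((int)k); break;
      case 3: case 4: {
        opb[k] = ist.back(); ist.pop_back();
        opa[k] = ist.back(); ist.pop_back();
        ist.push_back((int)k); break;
      }
      }
    }
    for (size_t kk = m; kk-- > 0;) {
      double g = bar[kk];
      if (g == 0.0) continue;
      switch (tm.code[kk]) {
      case 0: break;
      case 1: (*adj)[(size_t)tm.arg[kk]] += g; break;
      case 2: bar[opa[kk]] += -g; break;
      case 3:
        bar[opa[kk]] += g * vb[kk];
        bar[opb[kk]] += g * va[kk];
        break;
      case 4:
        bar[opa[kk]] += g * (1.0 - vb[kk]);
        bar[opb[kk]] += g * (1.0 - va[kk]);
        break;
      }
    }
  }
  return S;
}

struct EnergyOut {
  double total, bond_e, conf_e;
  std::vector<double> S, phi, r;
};

EnergyOut energy_all(const Engine& E, const std::vector<double>& x) {
  EnergyOut out;
  out.bond_e = 0.0;
  for (size_t b = 0; b < E.bonds.size(); ++b) {
    double r = dist(x, E.d, E.bonds[b].i, E.bonds[b].j);
    double dr = r - E.bonds[b].r0;
    out.bond_e += 0.5 * E.bonds[b].k * dr * dr;
  }
  double sw = 0.0;
  out.S.resize(E.terms.size());
  out.phi.resize(E.terms.size());
  out.r.resize(E.terms.size());
  std::vector<double> hval;
  for (size_t t = 0; t < E.terms.size(); ++t) {
    const Term& tm = E.terms[t];
    hval.resize(tm.leaves.size());
    for (size_t l = 0; l < tm.leaves.size(); ++l) {
      double r = dist(x, E.d, tm.leaves[l].i, tm.leaves[l].j);
      double h, dh;
      h_and_grad(r, tm.leaves[l].alpha, tm.leaves[l].n, h, dh);
      hval[l] = h;
    }
    double S = eval_program(tm, hval, nullptr);
    double r = dist(x, E.d, tm.pi, tm.pj);
    double phi, fmag;
    pot_eval(tm.kind, tm.par, r, phi, fmag);
    out.S[t] = S; out.phi[t] = phi; out.r[t] = r;
    sw += S * phi;
  }
  out.conf_e = 0.0;
  if (E.conf_on) {
    for (int i = 0; i < E.n; ++i) {
      double s = 0;
      for (int k = 0; k < E.d; ++k) {
        double dx = x[i * E.d + k] - E.conf_c[k];
        s += dx * dx;
      }
      double rad = std::sqrt(s);
      if (rad > E.conf_R) {
        double exc = rad - E.conf_R;
        out.conf_e += 0.5 * E.conf_k * exc * exc;
      }
    }
  }
  out.total = out.bond_e + sw + out.conf_e;
  return out;
}

void forces_all(const Engine& E, const std::vector<double>& x,
                bool frozen, std::vector<double>& f) {
  std::fill(f.begin(), f.end(), 0.0);
  const int d = E.d;
  for (size_t b = 0; b < E.bonds.size(); ++b) {
    int i = E.bonds[b].i, j = E.bonds[b].j;
    double r = dist(x, d, i, j);
    if (r <= 0) continue;
    double fm = -E.bonds[b].k * (r - E.bonds[b].r0);
    for (int k = 0; k < d; ++k) {
      double u = (x[i * d + k] - x[j * d + k]) / r;
      f[i * d + k] += fm * u;
      f[j * d + k] -= fm * u;
    }
  }
  std::vector<double> hval, hgrad, adj;
  for (size_t t = 0; t < E.terms.size(); ++t) {
    const Term& tm = E.terms[t];
    size_t L = tm.leaves.size();
    hval.resize(L); hgrad.resize(L); adj.resize(L);
    for (size_t l = 0; l < L; ++l) {
      double r = dist(x, d, tm.leaves[l].i, tm.leaves[l].j);
      double h, dh;
      h_and_grad(r, tm.leaves[l].alpha, tm.leaves[l].n, h, dh);
      hval[l] = h; hgrad[l] = dh;
    }
    double S = eval_program(tm, hval, frozen ? nullptr : &adj);
    double r = dist(x, d, tm.pi, tm.pj);
    double phi, fmag;
    pot_eval(tm.kind, tm.par, r, phi, fmag);
    // -S * dphi/dr along the pair axis (fmag already is -dphi/dr)
    if (r > 0) {
      for (int k = 0; k < d; ++k) {
        double u = (x[tm.pi * d + k] - x[tm.pj * d + k]) / r;
        f[tm.pi * d + k] += S * fmag * u;
        f[tm.pj * d + k] -= S * fmag * u;
      }
    }
    if (!frozen) {
      // -phi * dS/dx through every leaf
      for (size_t l = 0; l < L; ++l) {
        double w = adj[l] * hgrad[l];
        if (w == 0.0) continue;
        int i = tm.leaves[l].i, j = tm.leaves[l].j;
        double rl = dist(x, d, i, j);
        if (rl <= 0) continue;
        for (int k = 0; k < d; ++k) {
          double u = (x[i * d + k] - x[j * d + k]) / rl;
          f[i * d + k] -= phi * w * u;
          f[j * d + k] += phi * w * u;
        }
      }
    }
  }
  if (E.conf_on) {
    for (int i = 0; i < E.n; ++i) {
      double s = 0;
      for (int k = 0; k < d; ++k) {
        double dx = x[i * d + k] - E.conf_c[k];
        s += dx * dx;
      }
      double rad = std::sqrt(s);
      if (rad > E.conf_R) {
        double pull = E.conf_k * (rad - E.conf_R) / rad;
        for (int k = 0; k < d; ++k) {
          f[i * d + k] -= pull * (x[i * d + k] - E.conf_c[k]);
        }
      }
    }
  }
}

std::vector<double> mat_to_flat(const NumericMatrix& x) {
  // row-major flatten: particle i occupies x[i*d .. i*d+d-1]
  std::vector<double> out((size_t)x.nrow() * x.ncol());
  for (int i = 0; i < x.nrow(); ++i) {
    for (int k = 0; k < x.ncol(); ++k) out[(size_t)i * x.ncol() + k] = x(i, k);
  }
  return out;
}

NumericMatrix flat_to_mat(const std::vector<double>& v, int n, int d) {
  NumericMatrix out(n, d);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < d; ++k) out(i, k) = v[(size_t)i * d + k];
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List engine_energy(List sys, NumericMatrix x) {
  Engine E = build(sys);
  std::vector<double> xf = mat_to_flat(x);
  EnergyOut out = energy_all(E, xf);
  return List::create(
    _["total"] = out.total, _["bond_energy"] = out.bond_e,
    _["confinement_energy"] = out.conf_e,
    _["S"] = wrap(out.S), _["phi"] = wrap(out.phi), _["r"] = wrap(out.r));
}

// [[Rcpp::export]]
NumericMatrix engine_forces(List sys, NumericMatrix x, bool frozen) {
  Engine E = build(sys);
  std::vector<double> xf = mat_to_flat(x);
  std::vector<double> f(xf.size());
  forces_all(E, xf, frozen, f);
  return flat_to_mat(f, E.n, E.d);
}

// BAOAB Langevin integrator; gamma = 0 and kBT = 0 reduce it exactly to
// velocity Verlet.  Noise is drawn from R's RNG (caller seeds it), so runs
// are reproducible under set.seed().
// [[Rcpp::export]]
List engine_run(List sys, NumericMatrix x0, NumericMatrix v0,
                double dt, int n_steps, double kBT, double gamma,
                bool frozen, int stride) {
  Engine E = build(sys);
  const int n = E.n, d = E.d;
  std::vector<double> x = mat_to_flat(x0);
  std::vector<double> v = mat_to_flat(v0);
  std::vector<double> f(x.size());
  const int n_frames = n_steps / stride + 1;
  const size_t nt = E.terms.size();

  NumericVector times(n_frames);
  NumericVector pos(Dimension(n_frames, n, d));
  NumericVector vel(Dimension(n_frames, n, d));
  NumericVector epot(n_frames), ekin(n_frames);
  NumericMatrix Srec(n_frames, nt), rrec(n_frames, nt), phirec(n_frames, nt);

  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;

  RNGScope scope;
  forces_all(E, x, frozen, f);

  int frame = 0;
  auto record = [&](int step) {
    EnergyOut eo = energy_all(E, x);
    double ke = 0;
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < d; ++k) {
        double vv = v[(size_t)i * d + k];
        ke += 0.5 * E.mass[i] * vv * vv;
      }
    }
    times[frame] = step * dt;
    epot[frame] = eo.total; ekin[frame] = ke;
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < d; ++k) {
        pos[frame + n_frames * (i + n * k)] = x[(size_t)i * d + k];
        vel[frame + n_frames * (i + n * k)] = v[(size_t)i * d + k];
      }
    }
    for (size_t t = 0; t < nt; ++t) {
      Srec(frame, t) = eo.S[t]; rrec(frame, t) = eo.r[t]; phirec(frame, t) = eo.phi[t];
    }
    ++frame;
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < d; ++k) {
        v[(size_t)i * d + k] += 0.5 * dt * f[(size_t)i * d + k] / E.mass[i];
      }
    }
    // A: half drift
    for (size_t q = 0; q < x.size(); ++q) x[q] += 0.5 * dt * v[q];
    // O: Ornstein-Uhlenbeck exact solve (identity when gamma == 0)
    if (gamma > 0) {
      for (int i = 0; i < n; ++i) {
        double c2 = std::sqrt(kBT / E.mass[i] * (1.0 - c1 * c1));
        for (int k = 0; k < d; ++k) {
          v[(size_t)i * d + k] = c1 * v[(size_t)i * d + k] + c2 * norm_rand();
        }
      }
    }
    // A: half drift
    for (size_t q = 0; q < x.size(); ++q) x[q] += 0.5 * dt * v[q];
    // B: half kick with fresh forces
    forces_all(E, x, frozen, f);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < d; ++k) {
        v[(size_t)i * d + k] += 0.5 * dt * f[(size_t)i * d + k] / E.mass[i];
      }
    }
    for (size_t q = 0; q < x.size(); ++q) {
      if (!R_finite(x[q])) {
        stop("integration diverged (non-finite coordinate) at step %d; "
             "reduce dt", step);
      }
    }
    if (step % stride == 0) record(step);
    if (step % 4096 == 0) checkUserInterrupt();
  }

  return List::create(
    _["times"] = times, _["positions"] = pos, _["velocities"] = vel,
    _["E_pot"] = epot, _["E_kin"] = ekin,
    _["S"] = Srec, _["r"] = rrec, _["phi"] = phirec);
}
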