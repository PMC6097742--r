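// Corotational flat triangular shell kernels.
//
// Element = constant-strain membrane + discrete-Kirchhoff (DKT) bending,
// 6 DOF/node, small local strain / moderate global rotation via an
// element-attached corotational frame.  Each element carries its own
// stress-free reference triangle and reference nodal triads, so parts
// born at different stages (artery vs patch) coexist in one model.
//
// The internal force is the exact gradient of the corotational strain
// energy (local linear element + nonlinear frame extraction, with the
// consistent spin projector).  The element tangent is obtained by forward
// finite differencing of that force, which captures all geometric
// stiffness terms; the local stiffness matrix is reference-constant, so
// a force evaluation is cheap.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void make_frame(const arma::vec& p1, const arma::vec& p2,
                       const arma::vec& p3, arma::mat& T,
                       arma::mat& loc, double& area) {
  arma::vec d12 = p2 - p1, d13 = p3 - p1;
  arma::vec nrm = arma::cross(d12, d13);
  double a2 = arma::norm(nrm);
  area = 0.5 * a2;
  arma::vec e1 = arma::normalise(d12);
  arma::vec e3 = nrm / a2;
  arma::vec e2 = arma::cross(e3, e1);
  T = arma::join_rows(e1, arma::join_rows(e2, e3));
  loc.set_size(3, 2);
  loc(0, 0) = 0.0; loc(0, 1) = 0.0;
  loc(1, 0) = arma::dot(d12, e1); loc(1, 1) = arma::dot(d12, e2);
  loc(2, 0) = arma::dot(d13, e1); loc(2, 1) = arma::dot(d13, e2);
}

// DKT curvature interpolation: beta (rotated slope) field is quadratic over
// the triangle, pinned to nodal gradients at corners and to discrete
// Kirchhoff conditions at mid-sides.  Cx, Cy map the 9 plate DOFs
// (w, w_x, w_y per node) to beta_x, beta_y at the 6 interpolation nodes.
static void dkt_maps(const arma::mat& loc, arma::mat& Cx, arma::mat& Cy) {
  Cx.zeros(6, 9); Cy.zeros(6, 9);
  for (int i = 0; i < 3; ++i) {
    Cx(i, 3 * i + 1) = 1.0;
    Cy(i, 3 * i + 2) = 1.0;
  }
  const int ei[3] = {0, 1, 2}, ej[3] = {1, 2, 0};
  for (int k = 0; k < 3; ++k) {
    int i = ei[k], j = ej[k], m = 3 + k;
    double ex = loc(j, 0) - loc(i, 0), ey = loc(j, 1) - loc(i, 1);
    double l = std::sqrt(ex * ex + ey * ey);
    double sx = ex / l, sy = ey / l;
    double nx = -sy, ny = sx;
    // beta_s(mid) from the Hermite cubic along the edge,
    // beta_n(mid) = mean of the end normal slopes
    double c = 3.0 / (2.0 * l);
    Cx(m, 3 * i + 0) = -c * sx; Cx(m, 3 * j + 0) = c * sx;
    Cy(m, 3 * i + 0) = -c * sy; Cy(m, 3 * j + 0) = c * sy;
    double gxx = -0.25 * sx * sx + 0.5 * nx * nx;
    double gyx = -0.25 * sy * sx + 0.5 * ny * nx;
    double gxy = -0.25 * sx * sy + 0.5 * nx * ny;
    double gyy = -0.25 * sy * sy + 0.5 * ny * ny;
    for (int a : {i, j}) {
      Cx(m, 3 * a + 1) += gxx; Cx(m, 3 * a + 2) += gyx;
      Cy(m, 3 * a + 1) += gxy; Cy(m, 3 * a + 2) += gyy;
    }
  }
}

// Quadratic (6-node) shape function x/y derivatives at area coords L.
static void quad_dN(const double L[3], const double b[3], const double c[3],
                    double A, double dNdx[6], double dNdy[6]) {
  double dLdx[3], dLdy[3];
  for (int a = 0; a < 3; ++a) {
    dLdx[a] = b[a] / (2.0 * A);
    dLdy[a] = c[a] / (2.0 * A);
  }
  for (int a = 0; a < 3; ++a) {
    dNdx[a] = (4.0 * L[a] - 1.0) * dLdx[a];
    dNdy[a] = (4.0 * L[a] - 1.0) * dLdy[a];
  }
  const int ei[3] = {0, 1, 2}, ej[3] = {1, 2, 0};
  for (int k = 0; k < 3; ++k) {
    int i = ei[k], j = ej[k];
    dNdx[3 + k] = 4.0 * (L[i] * dLdx[j] + L[j] * dLdx[i]);
    dNdy[3 + k] = 4.0 * (L[i] * dLdy[j] + L[j] * dLdy[i]);
  }
}

static arma::mat dkt_B(const arma::mat& Cx, const arma::mat& Cy,
                       const double L[3], const double b[3], const double c[3],
                       double A) {
  double dNdx[6], dNdy[6];
  quad_dN(L, b, c, A, dNdx, dNdy);
  arma::mat B(3, 9, arma::fill::zeros);
  for (int a = 0; a < 6; ++a) {
    B.row(0) += dNdx[a] * Cx.row(a);
    B.row(1) += dNdy[a] * Cy.row(a);
    B.row(2) += dNdy[a] * Cx.row(a) + dNdx[a] * Cy.row(a);
  }
  return B;
}

// Local plate DOF transform: (w, w_x, w_y) <- (w, th_x, th_y)
// with w_x = -th_y, w_y = th_x.
static arma::mat plate_S() {
  arma::mat S(9, 9, arma::fill::zeros);
  for (int a = 0; a < 3; ++a) {
    S(3 * a + 0, 3 * a + 0) = 1.0;
    S(3 * a + 1, 3 * a + 2) = -1.0;
    S(3 * a + 2, 3 * a + 1) = 1.0;
  }
  return S;
}

static arma::vec rot_axial(const arma::mat& Rd) {
  arma::vec s(3);
  s(0) = 0.5 * (Rd(2, 1) - Rd(1, 2));
  s(1) = 0.5 * (Rd(0, 2) - Rd(2, 0));
  s(2) = 0.5 * (Rd(1, 0) - Rd(0, 1));
  double sn = arma::norm(s);
  if (sn > 1e-14) {
    double sa = std::min(sn, 1.0);
    s *= std::asin(sa) / sn;
  }
  return s;
}

static arma::mat rodrigues(const arma::vec& w) {
  double phi = arma::norm(w);
  arma::mat R = arma::eye(3, 3);
  if (phi > 1e-14) {
    arma::mat K(3, 3, arma::fill::zeros);
    K(0, 1) = -w(2); K(0, 2) = w(1);
    K(1, 0) = w(2);  K(1, 2) = -w(0);
    K(2, 0) = -w(1); K(2, 1) = w(0);
    R += (std::sin(phi) / phi) * K +
         ((1.0 - std::cos(phi)) / (phi * phi)) * (K * K);
  }
  return R;
}

// Fixed per-element reference data.
struct ElemRef {
  arma::mat T0;
  arma::mat loc0;
  double A0;
  arma::mat Kl;       // 18x18 local stiffness (membrane + DKT + drilling)
  arma::mat Bm;       // 3x6 membrane strain-displacement
  arma::mat Dm;       // membrane constitutive (force/area)
  arma::mat Db;       // bending constitutive
  arma::mat BcS;      // centroid curvature extractor (3x9, theta DOFs)
  arma::mat R0[3];    // reference nodal triads
  arma::vec f0;       // initial (residual) stress nodal force, local frame
};

// Internal force of one element in global DOFs, plus (optionally) local
// strain measures for stress output.  xe: 3x3 current node coords (rows),
// Re: current nodal triads.
static arma::vec elem_force(const ElemRef& er, const arma::mat& xe,
                            const arma::mat Re[3], double* energy,
                            arma::vec* mem_strain, arma::vec* curvature) {
  arma::mat T, loc; double A;
  make_frame(xe.row(0).t(), xe.row(1).t(), xe.row(2).t(), T, loc, A);
  arma::vec dl(18, arma::fill::zeros);
  for (int a = 0; a < 3; ++a) {
    dl(6 * a + 0) = loc(a, 0) - er.loc0(a, 0);
    dl(6 * a + 1) = loc(a, 1) - er.loc0(a, 1);
    arma::mat Rd = T.t() * Re[a] * er.R0[a].t() * er.T0;
    arma::vec thv = rot_axial(Rd);
    dl(6 * a + 3) = thv(0); dl(6 * a + 4) = thv(1); dl(6 * a + 5) = thv(2);
  }
  arma::vec fl = er.Kl * dl + er.f0;
  if (energy) *energy += 0.5 * arma::dot(dl, fl - er.f0) + arma::dot(er.f0, dl);
  if (mem_strain) {
    arma::vec um(6);
    for (int a = 0; a < 3; ++a) {
      um(2 * a + 0) = dl(6 * a + 0); um(2 * a + 1) = dl(6 * a + 1);
    }
    *mem_strain = er.Bm * um;
    arma::vec db(9);
    for (int a = 0; a < 3; ++a) {
      db(3 * a + 0) = dl(6 * a + 2);
      db(3 * a + 1) = dl(6 * a + 3);
      db(3 * a + 2) = dl(6 * a + 4);
    }
    *curvature = er.BcS * db;
  }
  // consistent spin projector at the current configuration
  double bc_[3] = {loc(1, 1) - loc(2, 1), loc(2, 1) - loc(0, 1),
                   loc(0, 1) - loc(1, 1)};
  double cc_[3] = {loc(2, 0) - loc(1, 0), loc(0, 0) - loc(2, 0),
                   loc(1, 0) - loc(0, 0)};
  arma::rowvec wx_row(18, arma::fill::zeros), wy_row(18, arma::fill::zeros),
      wz_row(18, arma::fill::zeros);
  for (int a = 0; a < 3; ++a) {
    wx_row(6 * a + 2) = cc_[a] / (2.0 * A);
    wy_row(6 * a + 2) = -bc_[a] / (2.0 * A);
  }
  double x2c = loc(1, 0);
  wz_row(6 * 1 + 1) = 1.0 / x2c;
  wz_row(6 * 0 + 1) = -1.0 / x2c;
  arma::mat Aproj(18, 18, arma::fill::zeros);
  for (int a = 0; a < 3; ++a) {
    double xi = loc(a, 0), yi = loc(a, 1);
    Aproj(6 * a + 0, 6 * a + 0) = 1.0; Aproj(6 * a + 0, 0) -= 1.0;
    Aproj.row(6 * a + 0) += yi * wz_row;
    Aproj(6 * a + 1, 6 * a + 1) = 1.0; Aproj(6 * a + 1, 1) -= 1.0;
    Aproj.row(6 * a + 1) -= xi * wz_row;
    Aproj(6 * a + 3, 6 * a + 3) = 1.0; Aproj.row(6 * a + 3) -= wx_row;
    Aproj(6 * a + 4, 6 * a + 4) = 1.0; Aproj.row(6 * a + 4) -= wy_row;
    Aproj(6 * a + 5, 6 * a + 5) = 1.0; Aproj.row(6 * a + 5) -= wz_row;
  }
  arma::mat P(18, 18, arma::fill::zeros);
  for (int blk = 0; blk < 6; ++blk)
    P.submat(3 * blk, 3 * blk, 3 * blk + 2, 3 * blk + 2) = T.t();
  return (Aproj * P).t() * fl;
}

// Assemble tangent stiffness triplets, internal force, follower pressure
// load and (optionally) element stress resultants for the current state.
//
// elem_ref : m x 9  per-element stress-free nodal coordinates (x1 y1 z1 ...)
// elem_R0  : m x 27 per-element reference nodal triads (row-major 3x3/node)
// tri      : m x 3  0-based node indices
// xcur     : n x 3  current nodal coordinates
// Rcur     : n x 9  current nodal triads (row-major)
// [[Rcpp::export]]
List cpp_shell_assemble(const arma::mat& elem_ref, const arma::mat& elem_R0,
                        const arma::imat& tri, const arma::mat& xcur,
                        const arma::mat& Rcur, const arma::vec& Ee,
                        const arma::vec& nue, const arma::vec& th,
                        double pressure, const arma::mat& sig0,
                        bool with_stress, bool with_tangent = true,
                        double drill_scale = 1e-6) {
  const int m = tri.n_rows, n = xcur.n_rows;
  std::vector<int> ti; std::vector<int> tj; std::vector<double> tv;
  if (with_tangent) {
    ti.reserve((size_t)m * 324); tj.reserve((size_t)m * 324);
    tv.reserve((size_t)m * 324);
  }
  arma::vec f_int(6 * n, arma::fill::zeros);
  arma::vec f_pres(6 * n, arma::fill::zeros);
  double energy = 0.0;
  arma::mat stress;
  arma::vec areas(m);
  if (with_stress) stress.zeros(m, 6);
  arma::mat S = plate_S();

  for (int e = 0; e < m; ++e) {
    arma::uvec nd(3);
    for (int a = 0; a < 3; ++a) nd(a) = (arma::uword)tri(e, a);
    ElemRef er;
    {
      arma::vec p01 = elem_ref.row(e).subvec(0, 2).t();
      arma::vec p02 = elem_ref.row(e).subvec(3, 5).t();
      arma::vec p03 = elem_ref.row(e).subvec(6, 8).t();
      make_frame(p01, p02, p03, er.T0, er.loc0, er.A0);
    }
    if (er.A0 <= 0 || !std::isfinite(er.A0))
      stop("degenerate reference element");
    for (int a = 0; a < 3; ++a)
      er.R0[a] = arma::reshape(
          elem_R0.row(e).subvec(9 * a, 9 * a + 8), 3, 3).t();

    double E = Ee(e), nu = nue(e), t = th(e);
    arma::mat Dm(3, 3, arma::fill::zeros);
    double fb = E / (1.0 - nu * nu);
    Dm(0, 0) = fb; Dm(1, 1) = fb; Dm(0, 1) = fb * nu; Dm(1, 0) = fb * nu;
    Dm(2, 2) = fb * (1.0 - nu) / 2.0;
    er.Dm = Dm;
    er.Db = (t * t * t / 12.0) * Dm;

    double x2 = er.loc0(1, 0), y2 = er.loc0(1, 1),
           x3 = er.loc0(2, 0), y3 = er.loc0(2, 1);
    double b[3] = {y2 - y3, y3 - 0.0, 0.0 - y2};
    double c[3] = {x3 - x2, 0.0 - x3, x2 - 0.0};
    arma::mat Bm(3, 6, arma::fill::zeros);
    for (int a = 0; a < 3; ++a) {
      Bm(0, 2 * a + 0) = b[a]; Bm(1, 2 * a + 1) = c[a];
      Bm(2, 2 * a + 0) = c[a]; Bm(2, 2 * a + 1) = b[a];
    }
    Bm /= (2.0 * er.A0);
    er.Bm = Bm;
    arma::mat Km = (er.A0 * t) * Bm.t() * Dm * Bm;

    arma::mat Cx, Cy;
    dkt_maps(er.loc0, Cx, Cy);
    arma::mat Kb9(9, 9, arma::fill::zeros);
    const double gp[3][3] = {{0.5, 0.5, 0.0}, {0.0, 0.5, 0.5},
                             {0.5, 0.0, 0.5}};
    for (int g = 0; g < 3; ++g) {
      arma::mat B = dkt_B(Cx, Cy, gp[g], b, c, er.A0);
      Kb9 += (er.A0 / 3.0) * B.t() * er.Db * B;
    }
    arma::mat Kb = S.t() * Kb9 * S;
    const double Lc[3] = {1.0 / 3.0, 1.0 / 3.0, 1.0 / 3.0};
    er.BcS = dkt_B(Cx, Cy, Lc, b, c, er.A0) * S;

    arma::mat Kl(18, 18, arma::fill::zeros);
    const int mdof[6] = {0, 1, 6, 7, 12, 13};
    const int bdof[9] = {2, 3, 4, 8, 9, 10, 14, 15, 16};
    for (int a = 0; a < 6; ++a)
      for (int bb = 0; bb < 6; ++bb) Kl(mdof[a], mdof[bb]) += Km(a, bb);
    for (int a = 0; a < 9; ++a)
      for (int bb = 0; bb < 9; ++bb) Kl(bdof[a], bdof[bb]) += Kb(a, bb);
    double kd = drill_scale * Kl.diag().max();
    for (int a = 0; a < 3; ++a) Kl(6 * a + 5, 6 * a + 5) += kd;
    er.Kl = Kl;
    // initial (residual) membrane stress -> local nodal force
    er.f0.zeros(18);
    {
      arma::vec s0 = sig0.row(e).t();
      if (arma::any(arma::abs(s0) > 0)) {
        arma::vec f0m = (er.A0 * t) * (er.Bm.t() * s0);
        for (int a = 0; a < 6; ++a) er.f0(mdof[a]) = f0m(a);
      }
    }

    // current nodal state
    arma::mat xe(3, 3);
    arma::mat Re[3];
    for (int a = 0; a < 3; ++a) {
      xe.row(a) = xcur.row(nd(a));
      Re[a] = arma::reshape(Rcur.row(nd(a)), 3, 3).t();
    }
    {
      arma::mat Tc, locc; double Ac;
      make_frame(xe.row(0).t(), xe.row(1).t(), xe.row(2).t(), Tc, locc, Ac);
      areas(e) = Ac;
      if (pressure != 0.0) {
        arma::vec fp = (pressure * Ac / 3.0) * Tc.col(2);
        for (int a = 0; a < 3; ++a)
          for (int k = 0; k < 3; ++k) f_pres(6 * (int)nd(a) + k) += fp(k);
      }
    }

    arma::vec eps, kap;
    arma::vec fe = elem_force(er, xe, Re, &energy,
                              with_stress ? &eps : nullptr,
                              with_stress ? &kap : nullptr);
    if (with_stress) {
      arma::vec sig = Dm * eps + sig0.row(e).t();
      arma::vec M = er.Db * kap;
      stress(e, 0) = sig(0); stress(e, 1) = sig(1); stress(e, 2) = sig(2);
      stress(e, 3) = M(0); stress(e, 4) = M(1); stress(e, 5) = M(2);
    }

    int gdof[18];
    for (int a = 0; a < 3; ++a)
      for (int k = 0; k < 6; ++k) gdof[6 * a + k] = 6 * (int)nd(a) + k;
    for (int a = 0; a < 18; ++a) f_int(gdof[a]) += fe(a);

    if (with_tangent) {
      // consistent tangent by forward differencing of the exact internal
      // force; the follower-pressure load stiffness is differenced too
      double hchar = std::sqrt(er.A0);
      double eps_t = 1e-7 * hchar, eps_r = 1e-7;
      auto pres_vec = [&](const arma::mat& x) -> arma::vec {
        arma::vec fp(18, arma::fill::zeros);
        if (pressure == 0.0) return fp;
        arma::mat Tc, locc; double Ac;
        make_frame(x.row(0).t(), x.row(1).t(), x.row(2).t(), Tc, locc, Ac);
        arma::vec fn = (pressure * Ac / 3.0) * Tc.col(2);
        for (int a = 0; a < 3; ++a)
          for (int k = 0; k < 3; ++k) fp(6 * a + k) = fn(k);
        return fp;
      };
      arma::vec fp0 = pres_vec(xe);
      arma::mat Ke(18, 18);
      for (int a = 0; a < 3; ++a) {
        for (int k = 0; k < 3; ++k) {
          arma::mat xp = xe;
          xp(a, k) += eps_t;
          arma::vec fp = elem_force(er, xp, Re, nullptr, nullptr, nullptr);
          Ke.col(6 * a + k) = (fp - fe) / eps_t -
            (pres_vec(xp) - fp0) / eps_t;
        }
        for (int k = 0; k < 3; ++k) {
          arma::mat Rp[3] = {Re[0], Re[1], Re[2]};
          arma::vec dth(3, arma::fill::zeros); dth(k) = eps_r;
          Rp[a] = rodrigues(dth) * Re[a];
          arma::vec fp = elem_force(er, xe, Rp, nullptr, nullptr, nullptr);
          Ke.col(6 * a + 3 + k) = (fp - fe) / eps_r;
        }
      }
      // keep Ke unsymmetric: the follower-pressure load stiffness is not
      for (int a = 0; a < 18; ++a)
        for (int bb = 0; bb < 18; ++bb) {
          ti.push_back(gdof[a] + 1);
          tj.push_back(gdof[bb] + 1);
          tv.push_back(Ke(a, bb));
        }
    }
  }

  List out = List::create(
      _["i"] = wrap(ti), _["j"] = wrap(tj), _["v"] = wrap(tv),
      _["f_int"] = f_int, _["f_pres"] = f_pres, _["area"] = areas,
      _["energy"] = energy);
  if (with_stress) out["stress"] = stress;
  return out;
}

// Incremental triad update: R_i <- exp(skew(dtheta_i)) R_i.
// [[Rcpp::export]]
arma::mat cpp_rotate_update(const arma::mat& Rcur, const arma::mat& dtheta) {
  arma::mat out = Rcur;
  for (arma::uword i = 0; i < Rcur.n_rows; ++i) {
    arma::mat R = rodrigues(dtheta.row(i).t()) *
                  arma::reshape(Rcur.row(i), 3, 3).t();
    out.row(i) = arma::vectorise(R.t()).t();
  }
  return out;
}
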