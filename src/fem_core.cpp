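// Axisymmetric coupled displacement / pore-pressure finite-element core.
//
// Q4 elements with equal-order bilinear interpolation for u = (u_r, u_z)
// and p (CAX4P-like), 2x2 Gauss quadrature, finite-deformation kinematics
// evaluated in the current configuration (exactly equivalent to a total
// Lagrangian pull-back). Dof layout per node: (u_r, u_z, p).
//
// The solid stress is fibre (tension-only standard linear solid with
// exponential springs, backward-Euler quadratic update) plus compressible
// neo-Hookean matrix; the fluid obeys Darcy flow with permeability
// k = k0 * J^Mk (void-ratio dependence with incompressible constituents).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Pars {
  double E1, E2, k1, k2, eta, k0, Mk, Km, Gm, gw;
  int fibre_mode;  // 0 axial (z), 1 radial (r)
};

Pars make_pars(const List& params, int fibre_mode) {
  Pars P;
  P.E1 = params["E1"]; P.E2 = params["E2"];
  P.k1 = params["k1"]; P.k2 = params["k2"];
  P.eta = params["eta"]; P.k0 = params["k0"]; P.Mk = params["Mk"];
  double Em = params["Em"], num = params["num"];
  P.Km = Em / (3.0 * (1.0 - 2.0 * num));
  P.Gm = Em / (2.0 * (1.0 + num));
  P.gw = params["gamma_w"];
  P.fibre_mode = fibre_mode;
  return P;
}

// Backward-Euler update of the fibre stress; mirrors fibre_update() in R.
inline void fibre_step(double Pf_old, double P1_old, double eps_old,
                       double eps_new, double dt, const Pars& P,
                       double& Pf, double& P1, bool& fail) {
  if (eps_new <= 0.0) { Pf = 0.0; P1 = 0.0; return; }
  double x = P.k1 * eps_new;
  if (x > 200.0) x = 200.0;
  P1 = P.E1 * std::expm1(x);
  double epsdot = (eps_new - eps_old) / dt;
  double P1dot = (P1 - P1_old) / dt;
  double a = P.eta / (P.k2 * dt);
  double b = P.E2 - 2.0 * P1 - P.eta * epsdot + a;
  double c = -a * Pf_old - (P1 + P.eta * epsdot) * (P.E2 - P1) -
             (P.eta / P.k2) * P1dot;
  double disc = b * b - 4.0 * c;
  if (disc < 0.0) { fail = true; Pf = 0.0; return; }
  Pf = 0.5 * (-b + std::sqrt(disc));
  if (Pf < 0.0) Pf = 0.0;
}

// Per-Gauss-point reference data, precomputed once per mesh.
struct RefData {
  arma::umat elems;     // ne x 4, 0-based node ids
  arma::mat N;          // ngp x 4 shape values
  arma::cube dNdX;      // 4 x 2 x ngp derivatives wrt reference coords
  arma::vec detJref;    // ngp
  arma::vec Rgp;        // ngp reference radius
  int ne, nn, ngp;
};

RefData make_ref(const arma::mat& nodes, const arma::imat& elems1) {
  RefData rd;
  rd.ne = elems1.n_rows;
  rd.nn = nodes.n_rows;
  rd.ngp = 4 * rd.ne;
  rd.elems.set_size(rd.ne, 4);
  for (int e = 0; e < rd.ne; ++e)
    for (int a = 0; a < 4; ++a) rd.elems(e, a) = elems1(e, a) - 1;
  const double g = 1.0 / std::sqrt(3.0);
  const double xi[4] = {-g, g, g, -g}, et[4] = {-g, -g, g, g};
  rd.N.set_size(rd.ngp, 4);
  rd.dNdX.set_size(4, 2, rd.ngp);
  rd.detJref.set_size(rd.ngp);
  rd.Rgp.set_size(rd.ngp);
  for (int e = 0; e < rd.ne; ++e) {
    arma::mat X(4, 2);
    for (int a = 0; a < 4; ++a) X.row(a) = nodes.row(rd.elems(e, a));
    for (int q = 0; q < 4; ++q) {
      int gpi = 4 * e + q;
      double s = xi[q], t = et[q];
      arma::vec4 N = {0.25 * (1 - s) * (1 - t), 0.25 * (1 + s) * (1 - t),
                      0.25 * (1 + s) * (1 + t), 0.25 * (1 - s) * (1 + t)};
      arma::mat dNdxi(4, 2);
      dNdxi(0, 0) = -0.25 * (1 - t); dNdxi(0, 1) = -0.25 * (1 - s);
      dNdxi(1, 0) =  0.25 * (1 - t); dNdxi(1, 1) = -0.25 * (1 + s);
      dNdxi(2, 0) =  0.25 * (1 + t); dNdxi(2, 1) =  0.25 * (1 + s);
      dNdxi(3, 0) = -0.25 * (1 + t); dNdxi(3, 1) =  0.25 * (1 - s);
      arma::mat Jm = dNdxi.t() * X;  // 2x2 reference Jacobian
      double dj = Jm(0, 0) * Jm(1, 1) - Jm(0, 1) * Jm(1, 0);
      arma::mat Jinv(2, 2);
      Jinv(0, 0) = Jm(1, 1) / dj;  Jinv(0, 1) = -Jm(0, 1) / dj;
      Jinv(1, 0) = -Jm(1, 0) / dj; Jinv(1, 1) = Jm(0, 0) / dj;
      rd.N.row(gpi) = N.t();
      rd.dNdX.slice(gpi) = dNdxi * Jinv;
      rd.detJref(gpi) = dj;
      rd.Rgp(gpi) = arma::dot(N, X.col(0));
    }
  }
  return rd;
}

// Assemble the residual. If commit, also fill history/field outputs.
// Returns false on element inversion or fibre-update failure.
bool assemble(const RefData& rd, const arma::mat& nodes, const arma::vec& d,
              const arma::mat& hist, const arma::vec& Jprev, double dt,
              const Pars& P, arma::vec& res,
              bool commit, arma::mat* hist_new, arma::vec* Jnew,
              arma::mat* gp_out) {
  const double twopi = 2.0 * M_PI;
  res.zeros(3 * rd.nn);
  bool fail = false;
  for (int e = 0; e < rd.ne && !fail; ++e) {
    arma::vec4 xr, xz, pe;
    arma::uvec4 nd;
    for (int a = 0; a < 4; ++a) {
      nd(a) = rd.elems(e, a);
      xr(a) = nodes(nd(a), 0) + d(3 * nd(a));
      xz(a) = nodes(nd(a), 1) + d(3 * nd(a) + 1);
      pe(a) = d(3 * nd(a) + 2);
    }
    for (int q = 0; q < 4; ++q) {
      int gpi = 4 * e + q;
      const arma::mat& dNdX = rd.dNdX.slice(gpi);
      arma::rowvec N = rd.N.row(gpi);
      double F11 = arma::dot(xr, dNdX.col(0)), F12 = arma::dot(xr, dNdX.col(1));
      double F21 = arma::dot(xz, dNdX.col(0)), F22 = arma::dot(xz, dNdX.col(1));
      double rgp = arma::dot(N.t(), xr);
      double F33 = rgp / rd.Rgp(gpi);
      double detF2 = F11 * F22 - F12 * F21;
      double J = detF2 * F33;
      if (J <= 0.0 || rgp <= 0.0) { fail = true; break; }
      // spatial shape-function gradients dN/dx = dN/dX * inv(F2)
      double i11 = F22 / detF2, i12 = -F12 / detF2;
      double i21 = -F21 / detF2, i22 = F11 / detF2;
      arma::vec4 dNr, dNz;
      for (int a = 0; a < 4; ++a) {
        dNr(a) = dNdX(a, 0) * i11 + dNdX(a, 1) * i21;
        dNz(a) = dNdX(a, 0) * i12 + dNdX(a, 1) * i22;
      }
      // fibre kinematics and stress
      double efr, efz;
      if (P.fibre_mode == 0) { efr = F12; efz = F22; }
      else { efr = F11; efz = F21; }
      double lam = std::sqrt(efr * efr + efz * efz);
      double epsf = std::log(lam);
      double Pf, P1;
      bool ffail = false;
      fibre_step(hist(gpi, 0), hist(gpi, 1), hist(gpi, 2), epsf, dt, P,
                 Pf, P1, ffail);
      if (ffail) { fail = true; break; }
      double cf = (Pf > 0.0) ? (lam / J) * Pf / (lam * lam) : 0.0;
      double sf_rr = cf * efr * efr, sf_rz = cf * efr * efz,
             sf_zz = cf * efz * efz;
      // neo-Hookean matrix
      double Brr = F11 * F11 + F12 * F12;
      double Brz = F11 * F21 + F12 * F22;
      double Bzz = F21 * F21 + F22 * F22;
      double Bhh = F33 * F33;
      double vol = 0.5 * P.Km * (J - 1.0 / J);
      double J23 = std::cbrt(J * J);
      double GJ = P.Gm / J;
      double sm_rr = vol + GJ * (Brr - J23);
      double sm_rz = GJ * Brz;
      double sm_zz = vol + GJ * (Bzz - J23);
      double sm_hh = vol + GJ * (Bhh - J23);
      double pgp = arma::dot(N.t(), pe);
      double s_rr = sf_rr + sm_rr - pgp;
      double s_rz = sf_rz + sm_rz;
      double s_zz = sf_zz + sm_zz - pgp;
      double s_hh = sm_hh - pgp;
      double w = rd.detJref(gpi) * twopi * rd.Rgp(gpi) * J;  // current volume
      double dpdr = arma::dot(dNr, pe), dpdz = arma::dot(dNz, pe);
      double kperm = P.k0 * std::pow(J, P.Mk);
      double storage = (J - Jprev(gpi)) / (dt * J);
      double mob = kperm / P.gw;
      for (int a = 0; a < 4; ++a) {
        int base = 3 * nd(a);
        res(base) += (dNr(a) * s_rr + dNz(a) * s_rz + N(a) / rgp * s_hh) * w;
        res(base + 1) += (dNr(a) * s_rz + dNz(a) * s_zz) * w;
        res(base + 2) += (N(a) * storage + mob * (dNr(a) * dpdr + dNz(a) * dpdz)) * w;
      }
      if (commit) {
        if (epsf <= 0.0) {
          (*hist_new)(gpi, 0) = 0.0; (*hist_new)(gpi, 1) = 0.0;
          (*hist_new)(gpi, 2) = 0.0;
        } else {
          (*hist_new)(gpi, 0) = Pf; (*hist_new)(gpi, 1) = P1;
          (*hist_new)(gpi, 2) = epsf;
        }
        (*Jnew)(gpi) = J;
        double wr = -mob * dpdr, wz = -mob * dpdz;
        arma::rowvec row = {rgp, arma::dot(N.t(), xz), rd.Rgp(gpi), J, pgp,
                            wr, wz, epsf, Pf, P1, sf_rr, sf_rz, sf_zz,
                            sm_rr, sm_rz, sm_zz, sm_hh};
        gp_out->row(gpi) = row;
      }
    }
  }
  return !fail;
}

}  // namespace

// [[Rcpp::export]]
List cpp_residual(const arma::mat& nodes, const arma::imat& elems,
                  const arma::vec& d, const arma::mat& hist,
                  const arma::vec& Jprev, double dt, const List& params,
                  int fibre_mode, bool commit = false) {
  RefData rd = make_ref(nodes, elems);
  Pars P = make_pars(params, fibre_mode);
  arma::vec res;
  arma::mat hist_new(rd.ngp, 3), gp_out(rd.ngp, 17);
  arma::vec Jnew(rd.ngp);
  bool ok = assemble(rd, nodes, d, hist, Jprev, dt, P, res,
                     commit, &hist_new, &Jnew, &gp_out);
  List out = List::create(
      _["res"] = NumericVector(res.begin(), res.end()), _["ok"] = ok);
  if (commit) {
    out["hist"] = hist_new;
    out["Jgp"] = Jnew;
    out["gp"] = gp_out;
  }
  return out;
}

// One implicit time step: Newton iteration with a graph-coloured
// finite-difference Jacobian and dense solve on the free dofs.
// fixed: 0-based dof indices with prescribed values fixed_vals (already
// the values at t + dt). groups: list of 0-based dof index vectors that can
// be perturbed simultaneously; rows: per-dof affected residual rows.
// [[Rcpp::export]]
List cpp_solve_step(const arma::mat& nodes, const arma::imat& elems,
                    const arma::vec& d_prev, const arma::mat& hist,
                    const arma::vec& Jprev, double dt, const List& params,
                    int fibre_mode,
                    const arma::uvec& fixed, const arma::vec& fixed_vals,
                    const arma::vec& load_vec, double load_scale,
                    const List& groups, const List& rows,
                    const List& settings) {
  RefData rd = make_ref(nodes, elems);
  Pars P = make_pars(params, fibre_mode);
  int ndof = 3 * rd.nn;
  double rtol = settings["newton_rtol"];
  double atol_u = settings["atol_u"];
  double atol_p = settings["atol_p"];
  int maxit = settings["max_newton"];
  double fdh = settings["fd_h"];
  double incr_tol = settings["incr_tol"];

  arma::vec d = d_prev;
  for (arma::uword i = 0; i < fixed.n_elem; ++i) d(fixed(i)) = fixed_vals(i);
  // free dof mask
  arma::uvec is_fixed(ndof, arma::fill::zeros);
  for (arma::uword i = 0; i < fixed.n_elem; ++i) is_fixed(fixed(i)) = 1;
  arma::uvec free_idx = arma::find(is_fixed == 0);
  std::vector<arma::uword> fu, fp;
  for (arma::uword k = 0; k < free_idx.n_elem; ++k) {
    if (free_idx(k) % 3 == 2) fp.push_back(free_idx(k));
    else fu.push_back(free_idx(k));
  }
  arma::uvec free_u(fu), free_p(fp);

  arma::vec res(ndof);
  arma::mat hist_new(rd.ngp, 3), gp_out(rd.ngp, 17);
  arma::vec Jnew(rd.ngp);
  bool converged = false;
  int it = 0;
  double ru0 = -1.0, rp0 = -1.0;
  arma::mat K(ndof, ndof, arma::fill::none);

  auto eval = [&](const arma::vec& dd, arma::vec& rr) -> bool {
    bool ok = assemble(rd, nodes, dd, hist, Jprev, dt, P, rr,
                       false, nullptr, nullptr, nullptr);
    if (ok && load_scale != 0.0) rr -= load_scale * load_vec;
    return ok;
  };

  if (!eval(d, res))
    return List::create(_["converged"] = false, _["reason"] = "inverted");

  for (it = 0; it <= maxit; ++it) {
    double ru = arma::norm(res.elem(free_u), 2);
    double rp = free_p.n_elem ? arma::norm(res.elem(free_p), 2) : 0.0;
    if (ru0 < 0) { ru0 = ru; rp0 = rp; }
    if (ru <= std::max(atol_u, rtol * ru0) &&
        rp <= std::max(atol_p, rtol * rp0)) { converged = true; break; }
    if (it == maxit) break;
    // coloured finite-difference Jacobian
    K.zeros();
    arma::vec dp = d, rpert(ndof);
    for (int g = 0; g < groups.size(); ++g) {
      IntegerVector grp = groups[g];
      if (grp.size() == 0) continue;
      std::vector<double> hs(grp.size());
      bool any = false;
      for (int k = 0; k < grp.size(); ++k) {
        int j = grp[k];
        if (is_fixed(j)) { hs[k] = 0.0; continue; }
        hs[k] = fdh * std::max(1.0, std::abs(d(j)));
        dp(j) = d(j) + hs[k];
        any = true;
      }
      if (!any) continue;
      if (!eval(dp, rpert))
        return List::create(_["converged"] = false, _["reason"] = "inverted");
      for (int k = 0; k < grp.size(); ++k) {
        int j = grp[k];
        if (hs[k] == 0.0) continue;
        IntegerVector rws = rows[j];
        for (int m = 0; m < rws.size(); ++m) {
          int r = rws[m];
          K(r, j) = (rpert(r) - res(r)) / hs[k];
        }
        dp(j) = d(j);
      }
    }
    arma::mat Kff = K.submat(free_idx, free_idx);
    arma::vec step;
    if (!arma::solve(step, Kff, res.elem(free_idx),
                     arma::solve_opts::no_approx))
      return List::create(_["converged"] = false, _["reason"] = "singular");
    // damped update: backtrack if the residual norm grows badly
    double n0 = arma::norm(res.elem(free_idx), 2);
    double alpha = 1.0;
    arma::vec d_try, r_try(ndof);
    bool accepted = false;
    for (int ls = 0; ls < 6; ++ls) {
      d_try = d;
      d_try.elem(free_idx) = d.elem(free_idx) - alpha * step;
      if (eval(d_try, r_try)) {
        double n1 = arma::norm(r_try.elem(free_idx), 2);
        if (n1 <= (1.0 - 1e-4 * alpha) * n0 || alpha <= 1.0 / 32.0) {
          accepted = true; break;
        }
      }
      alpha *= 0.5;
    }
    if (!accepted)
      return List::create(_["converged"] = false, _["reason"] = "linesearch");
    d = d_try;
    res = r_try;
    // stationarity: a negligible Newton increment means the residual has
    // reached its discretisation/roundoff floor (relevant at very small dt)
    double ninc = alpha * arma::norm(step, "inf");
    double dref = std::max(1.0, arma::norm(d.elem(free_idx), "inf"));
    if (ninc <= incr_tol * dref) { converged = true; ++it; break; }
  }
  if (!converged)
    return List::create(_["converged"] = false, _["reason"] = "maxit",
                        _["niter"] = it);
  // committed evaluation: history update, fields, internal forces
  arma::vec res_int;
  assemble(rd, nodes, d, hist, Jprev, dt, P, res_int,
           true, &hist_new, &Jnew, &gp_out);
  return List::create(_["converged"] = true, _["d"] = d,
                      _["hist"] = hist_new, _["Jgp"] = Jnew,
                      _["gp"] = gp_out, _["res_int"] = res_int,
                      _["niter"] = it);
}
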