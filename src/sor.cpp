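#include <Rcpp.h>
using namespace Rcpp;

// Point-coupled successive over-relaxation for one linearized flow system.
//
// Solves, for the increments (du, dv) at every pixel, the Euler-Lagrange
// equations of the robustified energy linearized about the current field
// (u, v) with frozen data weights wd/wg and smoothness diffusivity psi_s:
//
//   [wd Ix^2 + g (Ixx^2+Ixy^2) + beta + a S] du + [cross] dv =
//       -wd Ix Iz - g (Ixx Ixz + Ixy Iyz) + beta (mu - u)
//       + a sum_n s_n ((u_n - u_p) + du_n)
//
// and symmetrically for dv, where S = sum of half-point diffusivities
// s_n = (psi_s[p] + psi_s[n]) / 2 over the 4-neighborhood (Neumann
// boundaries).  Sweeps are lexicographic Gauss-Seidel with relaxation
// omega; the stopping rule is the mean squared increment change
//   error = (1/N) sum_ij ((du^{k+1}-du^k)^2 + (dv^{k+1}-dv^k)^2) < eps.
//
// Each sweep ends with a constant-mode (coarse-grid) correction: the
// smoothness operator annihilates globally constant increments, so their
// convergence under point relaxation is governed only by the (often tiny)
// data terms and can stall for thousands of sweeps.  Projecting the current
// residual onto the constant subspace gives a 2x2 Galerkin system
//   [sum a11, sum a12; sum a12, sum a22] (cu, cv) = (sum r1, sum r2)
// whose solution is added uniformly to (du, dv).  This leaves the fixed
// point of the iteration (the linear system's solution) unchanged.
//
// [[Rcpp::export]]
List sor_solve(NumericMatrix wd, NumericMatrix wg,
               NumericMatrix Ix, NumericMatrix Iy, NumericMatrix Iz,
               NumericMatrix Ixx, NumericMatrix Ixy, NumericMatrix Iyy,
               NumericMatrix Ixz, NumericMatrix Iyz,
               NumericMatrix psi_s,
               NumericMatrix u, NumericMatrix v,
               NumericMatrix beta_map, NumericMatrix mu, NumericMatrix mv,
               double alpha, double gamma, double omega,
               double eps_stop, int max_sor) {
  const int h = wd.nrow(), w = wd.ncol();
  NumericMatrix du(h, w), dv(h, w);
  NumericMatrix a11(h, w), a12(h, w), a22(h, w), c1(h, w), c2(h, w);

  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double d = wd(i, j), g = gamma * wg(i, j), b = beta_map(i, j);
      a11(i, j) = d * Ix(i, j) * Ix(i, j) +
                  g * (Ixx(i, j) * Ixx(i, j) + Ixy(i, j) * Ixy(i, j)) + b;
      a22(i, j) = d * Iy(i, j) * Iy(i, j) +
                  g * (Ixy(i, j) * Ixy(i, j) + Iyy(i, j) * Iyy(i, j)) + b;
      a12(i, j) = d * Ix(i, j) * Iy(i, j) +
                  g * Ixy(i, j) * (Ixx(i, j) + Iyy(i, j));
      c1(i, j) = -d * Ix(i, j) * Iz(i, j) -
                 g * (Ixx(i, j) * Ixz(i, j) + Ixy(i, j) * Iyz(i, j)) +
                 b * (mu(i, j) - u(i, j));
      c2(i, j) = -d * Iy(i, j) * Iz(i, j) -
                 g * (Ixy(i, j) * Ixz(i, j) + Iyy(i, j) * Iyz(i, j)) +
                 b * (mv(i, j) - v(i, j));
    }
  }

  std::vector<double> errors;
  NumericMatrix du_prev(h, w), dv_prev(h, w);
  const double N = (double)h * (double)w;
  int grow = 0;
  bool diverged = false;
  int k = 0;

  for (k = 0; k < max_sor; ++k) {
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        du_prev(i, j) = du(i, j);
        dv_prev(i, j) = dv(i, j);
      }
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double sum_s = 0.0, sum_u = 0.0, sum_v = 0.0;
        const double up = u(i, j), vp = v(i, j), pp = psi_s(i, j);
        if (i > 0) {
          double s = 0.5 * (pp + psi_s(i - 1, j));
          sum_s += s;
          sum_u += s * (u(i - 1, j) - up + du(i - 1, j));
          sum_v += s * (v(i - 1, j) - vp + dv(i - 1, j));
        }
        if (i < h - 1) {
          double s = 0.5 * (pp + psi_s(i + 1, j));
          sum_s += s;
          sum_u += s * (u(i + 1, j) - up + du(i + 1, j));
          sum_v += s * (v(i + 1, j) - vp + dv(i + 1, j));
        }
        if (j > 0) {
          double s = 0.5 * (pp + psi_s(i, j - 1));
          sum_s += s;
          sum_u += s * (u(i, j - 1) - up + du(i, j - 1));
          sum_v += s * (v(i, j - 1) - vp + dv(i, j - 1));
        }
        if (j < w - 1) {
          double s = 0.5 * (pp + psi_s(i, j + 1));
          sum_s += s;
          sum_u += s * (u(i, j + 1) - up + du(i, j + 1));
          sum_v += s * (v(i, j + 1) - vp + dv(i, j + 1));
        }
        double A11 = a11(i, j) + alpha * sum_s;
        double A22 = a22(i, j) + alpha * sum_s;
        double A12 = a12(i, j);
        double b1 = c1(i, j) + alpha * sum_u;
        double b2 = c2(i, j) + alpha * sum_v;
        double det = A11 * A22 - A12 * A12;
        if (det < 1e-12) det = 1e-12;
        double du_gs = (A22 * b1 - A12 * b2) / det;
        double dv_gs = (A11 * b2 - A12 * b1) / det;
        du(i, j) = (1.0 - omega) * du(i, j) + omega * du_gs;
        dv(i, j) = (1.0 - omega) * dv(i, j) + omega * dv_gs;
      }
    }
    // constant-mode correction: Galerkin projection of the residual onto
    // globally constant (du, dv) increments
    {
      double G11 = 0.0, G12 = 0.0, G22 = 0.0, R1 = 0.0, R2 = 0.0;
      for (int j = 0; j < w; ++j) {
        for (int i = 0; i < h; ++i) {
          double sum_s = 0.0, sum_u = 0.0, sum_v = 0.0;
          const double up = u(i, j), vp = v(i, j), pp = psi_s(i, j);
          if (i > 0) {
            double s = 0.5 * (pp + psi_s(i - 1, j));
            sum_s += s;
            sum_u += s * (u(i - 1, j) - up + du(i - 1, j));
            sum_v += s * (v(i - 1, j) - vp + dv(i - 1, j));
          }
          if (i < h - 1) {
            double s = 0.5 * (pp + psi_s(i + 1, j));
            sum_s += s;
            sum_u += s * (u(i + 1, j) - up + du(i + 1, j));
            sum_v += s * (v(i + 1, j) - vp + dv(i + 1, j));
          }
          if (j > 0) {
            double s = 0.5 * (pp + psi_s(i, j - 1));
            sum_s += s;
            sum_u += s * (u(i, j - 1) - up + du(i, j - 1));
            sum_v += s * (v(i, j - 1) - vp + dv(i, j - 1));
          }
          if (j < w - 1) {
            double s = 0.5 * (pp + psi_s(i, j + 1));
            sum_s += s;
            sum_u += s * (u(i, j + 1) - up + du(i, j + 1));
            sum_v += s * (v(i, j + 1) - vp + dv(i, j + 1));
          }
          R1 += c1(i, j) + alpha * sum_u -
                (a11(i, j) + alpha * sum_s) * du(i, j) - a12(i, j) * dv(i, j);
          R2 += c2(i, j) + alpha * sum_v -
                (a22(i, j) + alpha * sum_s) * dv(i, j) - a12(i, j) * du(i, j);
          G11 += a11(i, j);
          G12 += a12(i, j);
          G22 += a22(i, j);
        }
      }
      double detG = G11 * G22 - G12 * G12;
      if (detG > 1e-10 && G11 + G22 > 1e-10) {
        double cu = (G22 * R1 - G12 * R2) / detG;
        double cv = (G11 * R2 - G12 * R1) / detG;
        for (int j = 0; j < w; ++j)
          for (int i = 0; i < h; ++i) {
            du(i, j) += cu;
            dv(i, j) += cv;
          }
      }
    }
    double err = 0.0;
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double a = du(i, j) - du_prev(i, j);
        double b = dv(i, j) - dv_prev(i, j);
        err += a * a + b * b;
      }
    err /= N;
    errors.push_back(err);
    if (err < eps_stop) { ++k; break; }
    if (errors.size() >= 2 && err > errors[errors.size() - 2]) {
      if (++grow >= 10) { diverged = true; ++k; break; }
    } else {
      grow = 0;
    }
  }

  return List::create(_["du"] = du, _["dv"] = dv,
                      _["errors"] = NumericVector(errors.begin(), errors.end()),
                      _["n_sweeps"] = (int)errors.size(),
                      _["final_error"] = errors.empty() ? NA_REAL : errors.back(),
                      _["diverged"] = diverged);
}

// Backward bilinear warp: out(i,j) = img(i + v(i,j), j + u(i,j)) with
// nearest-edge extension for out-of-frame samples.
// [[Rcpp::export]]
NumericMatrix warp_bilinear(NumericMatrix img, NumericMatrix u,
                            NumericMatrix v) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double x = j + u(i, j), y = i + v(i, j);
      if (x < 0) x = 0; if (x > w - 1) x = w - 1;
      if (y < 0) y = 0; if (y > h - 1) y = h - 1;
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
      int x1 = x0 + 1 < w ? x0 + 1 : w - 1;
      int y1 = y0 + 1 < h ? y0 + 1 : h - 1;
      double fx = x - x0, fy = y - y0;
      out(i, j) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}
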