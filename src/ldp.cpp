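// Local-density-potential Monte Carlo core.
//
// Units: k_B = 1, energies in kelvin, lengths in nm.  The excess free energy
// a^ex(rho) enters as a cubic-Hermite lookup table on a uniform density grid
// (value + derivative per node); densities beyond the table fall back to a
// user-supplied R function (counted, rare by construction).
//
// Potential:  U = sum_i a^ex(rho_bar_i) + (kappa/2) sum_i |grad rho_bar_i|^2
// with rho_bar_i = sum_{j != i} w(r_ij), w the normalized Lucy kernel.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Box {
  double L[3];
  double volume() const { return L[0] * L[1] * L[2]; }
};

// minimum-image displacement a - b
inline void min_image(const double* a, const double* b, const Box& box,
                      double* d) {
  for (int k = 0; k < 3; ++k) {
    d[k] = a[k] - b[k];
    d[k] -= box.L[k] * std::nearbyint(d[k] / box.L[k]);
  }
}

// Lucy kernel, normalized to unit 3-D integral, and its radial derivative
inline double lucy_w(double r, double rc) {
  if (r >= rc) return 0.0;
  const double u = r / rc;
  const double m = 1.0 - u;
  return 105.0 / (16.0 * M_PI * rc * rc * rc) * (1.0 + 3.0 * u) * m * m * m;
}

inline double lucy_dw(double r, double rc) {
  if (r >= rc) return 0.0;
  const double u = r / rc;
  const double m = 1.0 - u;
  return 105.0 / (16.0 * M_PI * rc * rc * rc) * (-12.0) * u * m * m / rc;
}

// cubic Hermite lookup of a^ex(rho) on a uniform grid
struct AexTable {
  double x0, dx;
  int n;
  const double* y;
  const double* dy;
  Function* fallback;   // may be null
  mutable long n_fallback;

  double eval(double x) const {
    const double xmax = x0 + dx * (n - 1);
    // roundoff in incremental updates can leave rho at -1e-20 when the last
    // neighbour leaves the cutoff; clamp instead of treating as out-of-range
    if (x < x0 && x > x0 - 1e-9) x = x0;
    if (x > xmax || x < x0) {
      if (fallback == nullptr)
        stop("local density %g outside lookup range [%g, %g] and no fallback",
             x, x0, xmax);
      ++n_fallback;
      return as<double>((*fallback)(x));
    }
    int i = static_cast<int>((x - x0) / dx);
    if (i >= n - 1) i = n - 2;
    const double t = (x - x0 - i * dx) / dx;
    const double t2 = t * t, t3 = t2 * t;
    const double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + t;
    const double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
    return h00 * y[i] + h10 * dx * dy[i] + h01 * y[i + 1] + h11 * dx * dy[i + 1];
  }
};

// full O(N^2) local-density field
void field_from_scratch(const NumericMatrix& pos, const Box& box, double rc,
                        std::vector<double>& rho,
                        std::vector<double>& grad) {
  const int n = pos.nrow();
  rho.assign(n, 0.0);
  grad.assign(3 * n, 0.0);
  double d[3];
  for (int i = 0; i < n; ++i) {
    const double pi_[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    for (int j = i + 1; j < n; ++j) {
      // early exit on the z separation: boxes are often elongated in z
      double dz = pi_[2] - pos(j, 2);
      dz -= box.L[2] * std::nearbyint(dz / box.L[2]);
      if (std::fabs(dz) >= rc) continue;
      const double pj[3] = {pos(j, 0), pos(j, 1), pos(j, 2)};
      min_image(pi_, pj, box, d);
      const double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 >= rc * rc) continue;
      const double r = std::sqrt(r2);
      const double w = lucy_w(r, rc);
      rho[i] += w;
      rho[j] += w;
      if (r > 0) {
        const double dw = lucy_dw(r, rc);
        for (int k = 0; k < 3; ++k) {
          const double g = dw * d[k] / r;   // unit vector from j to i
          grad[3 * i + k] += g;             // contribution to grad rho_i
          grad[3 * j + k] -= g;             // opposite sign for j
        }
      }
    }
  }
}

double energy_from_field(const std::vector<double>& rho,
                         const std::vector<double>& grad,
                         const AexTable& tab, double kappa,
                         std::vector<double>* e = nullptr,
                         std::vector<double>* s = nullptr) {
  const int n = static_cast<int>(rho.size());
  double U = 0.0;
  for (int i = 0; i < n; ++i) {
    const double ei = tab.eval(rho[i]);
    const double g2 = grad[3 * i] * grad[3 * i] +
      grad[3 * i + 1] * grad[3 * i + 1] + grad[3 * i + 2] * grad[3 * i + 2];
    const double si = 0.5 * kappa * g2;
    if (e) (*e)[i] = ei;
    if (s) (*s)[i] = si;
    U += ei + si;
  }
  return U;
}

AexTable make_table(const NumericVector& grid, const NumericVector& val,
                    const NumericVector& dval, Function* fb) {
  AexTable tab;
  tab.x0 = grid[0];
  tab.dx = grid[1] - grid[0];
  tab.n = grid.size();
  tab.y = REAL(val);
  tab.dy = REAL(dval);
  tab.fallback = fb;
  tab.n_fallback = 0;
  return tab;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_local_density")]]
List cpp_local_density(NumericMatrix pos, NumericVector box_len, double rc) {
  Box box = {{box_len[0], box_len[1], box_len[2]}};
  std::vector<double> rho, grad;
  field_from_scratch(pos, box, rc, rho, grad);
  const int n = pos.nrow();
  NumericVector rho_out(n);
  NumericMatrix grad_out(n, 3);
  for (int i = 0; i < n; ++i) {
    rho_out[i] = rho[i];
    for (int k = 0; k < 3; ++k) grad_out(i, k) = grad[3 * i + k];
  }
  return List::create(_["rho_bar"] = rho_out, _["grad_rho"] = grad_out);
}

// [[Rcpp::export(name = ".cpp_total_energy")]]
List cpp_total_energy(NumericMatrix pos, NumericVector box_len, double rc,
                      double kappa, NumericVector grid, NumericVector val,
                      NumericVector dval, Nullable<Function> fallback) {
  Box box = {{box_len[0], box_len[1], box_len[2]}};
  Function fb_fun = fallback.isNotNull() ? Function(fallback.get()) : Function("identity");
  Function* fb = fallback.isNotNull() ? &fb_fun : nullptr;
  AexTable tab = make_table(grid, val, dval, fb);
  std::vector<double> rho, grad;
  field_from_scratch(pos, box, rc, rho, grad);
  double U = energy_from_field(rho, grad, tab, kappa);
  return List::create(_["U"] = U, _["n_fallback"] = (double)tab.n_fallback);
}

// Metropolis MC in NVT or NpT.  A cycle is N displacement attempts; in NpT
// one volume move (random walk in ln V, isotropic rescale) is attempted per
// cycle at a random point within the cycle.
// [[Rcpp::export(name = ".cpp_run_mc")]]
List cpp_run_mc(NumericMatrix pos_in, NumericVector box_len, double rc,
                double kappa, NumericVector grid, NumericVector val,
                NumericVector dval, Nullable<Function> fallback,
                double T, bool npt, double pressure,
                int n_equil, int n_prod, double max_disp, double max_lnv,
                int adapt_every, double target_acc,
                int sample_every, int n_bins_profile) {
  const int n = pos_in.nrow();
  NumericMatrix pos = clone(pos_in);
  Box box = {{box_len[0], box_len[1], box_len[2]}};
  Function fb_fun = fallback.isNotNull() ? Function(fallback.get()) : Function("identity");
  Function* fb = fallback.isNotNull() ? &fb_fun : nullptr;
  AexTable tab = make_table(grid, val, dval, fb);

  std::vector<double> rho, grad, e(n), s(n);
  field_from_scratch(pos, box, rc, rho, grad);
  double U = energy_from_field(rho, grad, tab, kappa, &e, &s);

  const double rc2 = rc * rc;
  long acc_disp = 0, try_disp = 0, acc_vol = 0, try_vol = 0, rej_small = 0;
  long acc_win = 0, try_win = 0;

  std::vector<double> u_series, v_series, rhoavg_series;
  std::vector<NumericMatrix> frames;
  std::vector<NumericVector> frame_boxes;

  std::vector<int> touched(n);
  std::vector<double> drho(n, 0.0), dg(3 * n, 0.0);

  const long total_cycles = (long)n_equil + n_prod;
  for (long cyc = 0; cyc < total_cycles; ++cyc) {
    const bool prod = cyc >= n_equil;
    const int vol_at = npt ? (int)(R::unif_rand() * n) : -1;
    for (int step = 0; step < n; ++step) {
      if (step == vol_at) {
        // ---- volume move ----
        ++try_vol;
        const double V0 = box.volume();
        const double lnv1 = std::log(V0) + (2.0 * R::unif_rand() - 1.0) * max_lnv;
        const double V1 = std::exp(lnv1);
        const double sc = std::cbrt(V1 / V0);
        Box nbox = {{box.L[0] * sc, box.L[1] * sc, box.L[2] * sc}};
        if (nbox.L[0] < 2 * rc || nbox.L[1] < 2 * rc || nbox.L[2] < 2 * rc) {
          ++rej_small;
          continue;
        }
        NumericMatrix npos(n, 3);
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < 3; ++k) npos(i, k) = pos(i, k) * sc;
        std::vector<double> nrho, ngrad, ne(n), ns(n);
        field_from_scratch(npos, nbox, rc, nrho, ngrad);
        const double U1 = energy_from_field(nrho, ngrad, tab, kappa, &ne, &ns);
        const double arg = -(U1 - U + pressure * (V1 - V0) -
                             (n + 1) * T * std::log(V1 / V0)) / T;
        if (arg >= 0 || R::unif_rand() < std::exp(arg)) {
          ++acc_vol;
          pos = npos;
          box = nbox;
          rho.swap(nrho);
          grad.swap(ngrad);
          e.swap(ne);
          s.swap(ns);
          U = U1;
        }
        continue;
      }
      // ---- displacement move ----
      ++try_disp; ++try_win;
      const int i = (int)(R::unif_rand() * n);
      double oldp[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
      double newp[3];
      for (int k = 0; k < 3; ++k) {
        newp[k] = oldp[k] + (2.0 * R::unif_rand() - 1.0) * max_disp;
        newp[k] -= box.L[k] * std::floor(newp[k] / box.L[k]);  // wrap [0, L)
      }
      int n_touched = 0;
      double rho_i_new = 0.0, gi_new[3] = {0, 0, 0};
      double dU = 0.0;
      double d[3];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        // early exit when j is beyond the cutoff in z of both endpoints
        {
          double dzo = oldp[2] - pos(j, 2);
          dzo -= box.L[2] * std::nearbyint(dzo / box.L[2]);
          if (std::fabs(dzo) >= rc) {
            double dzn = newp[2] - pos(j, 2);
            dzn -= box.L[2] * std::nearbyint(dzn / box.L[2]);
            if (std::fabs(dzn) >= rc) continue;
          }
        }
        const double pj[3] = {pos(j, 0), pos(j, 1), pos(j, 2)};
        double w_old = 0, dw_old = 0, uo[3] = {0, 0, 0};
        min_image(oldp, pj, box, d);
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        bool in_old = r2 < rc2;
        if (in_old) {
          const double r = std::sqrt(r2);
          w_old = lucy_w(r, rc);
          dw_old = lucy_dw(r, rc);
          if (r > 0) for (int k = 0; k < 3; ++k) uo[k] = d[k] / r;
        }
        double w_new = 0, dw_new = 0, un[3] = {0, 0, 0};
        min_image(newp, pj, box, d);
        r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        bool in_new = r2 < rc2;
        if (in_new) {
          const double r = std::sqrt(r2);
          w_new = lucy_w(r, rc);
          dw_new = lucy_dw(r, rc);
          if (r > 0) for (int k = 0; k < 3; ++k) un[k] = d[k] / r;
        }
        if (in_new) {
          rho_i_new += w_new;
          for (int k = 0; k < 3; ++k) gi_new[k] += dw_new * un[k];
        }
        if (!in_old && !in_new) continue;
        touched[n_touched] = j;
        drho[j] = w_new - w_old;
        // grad_j contribution from i has opposite unit vector
        for (int k = 0; k < 3; ++k)
          dg[3 * j + k] = -(dw_new * un[k] - dw_old * uo[k]);
        ++n_touched;
        const double rj = rho[j] + drho[j];
        const double gj0 = grad[3 * j] + dg[3 * j];
        const double gj1 = grad[3 * j + 1] + dg[3 * j + 1];
        const double gj2 = grad[3 * j + 2] + dg[3 * j + 2];
        const double ej = tab.eval(rj);
        const double sj = 0.5 * kappa * (gj0 * gj0 + gj1 * gj1 + gj2 * gj2);
        dU += ej + sj - e[j] - s[j];
      }
      const double ei_new = tab.eval(rho_i_new);
      const double si_new = 0.5 * kappa *
        (gi_new[0] * gi_new[0] + gi_new[1] * gi_new[1] + gi_new[2] * gi_new[2]);
      dU += ei_new + si_new - e[i] - s[i];

      if (dU <= 0 || R::unif_rand() < std::exp(-dU / T)) {
        ++acc_disp; ++acc_win;
        for (int k = 0; k < 3; ++k) pos(i, k) = newp[k];
        rho[i] = rho_i_new;
        for (int k = 0; k < 3; ++k) grad[3 * i + k] = gi_new[k];
        e[i] = ei_new;
        s[i] = si_new;
        for (int t = 0; t < n_touched; ++t) {
          const int j = touched[t];
          rho[j] += drho[j];
          for (int k = 0; k < 3; ++k) grad[3 * j + k] += dg[3 * j + k];
          const double g0 = grad[3 * j], g1 = grad[3 * j + 1], g2 = grad[3 * j + 2];
          e[j] = tab.eval(rho[j]);
          s[j] = 0.5 * kappa * (g0 * g0 + g1 * g1 + g2 * g2);
        }
        U += dU;
      }
    }
    // step-size adaptation, equilibration only
    if (!prod && adapt_every > 0 && (cyc + 1) % adapt_every == 0 && try_win > 0) {
      const double acc = (double)acc_win / try_win;
      double f = acc / target_acc;
      if (f < 0.5) f = 0.5;
      if (f > 1.5) f = 1.5;
      max_disp *= f;
      const double cap = 0.25 * std::min(box.L[0], std::min(box.L[1], box.L[2]));
      if (max_disp > cap) max_disp = cap;
      acc_win = try_win = 0;
    }
    if (prod) {
      u_series.push_back(U);
      v_series.push_back(box.volume());
      const long pc = cyc - n_equil;
      if (sample_every > 0 && pc % sample_every == 0) {
        frames.push_back(clone(pos));
        frame_boxes.push_back(
          NumericVector::create(box.L[0], box.L[1], box.L[2]));
      }
    }
    if ((cyc + 1) % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // exact bookkeeping check: recompute field and energy from scratch
  std::vector<double> rho2, grad2;
  field_from_scratch(pos, box, rc, rho2, grad2);
  const double U_recomputed = energy_from_field(rho2, grad2, tab, kappa);
  double max_rho_dev = 0.0, max_grad_dev = 0.0;
  for (int i = 0; i < n; ++i) {
    max_rho_dev = std::max(max_rho_dev, std::fabs(rho[i] - rho2[i]));
    for (int k = 0; k < 3; ++k)
      max_grad_dev = std::max(max_grad_dev,
                              std::fabs(grad[3 * i + k] - grad2[3 * i + k]));
  }

  List frames_out(frames.size());
  List boxes_out(frames.size());
  for (size_t k = 0; k < frames.size(); ++k) {
    frames_out[k] = frames[k];
    boxes_out[k] = frame_boxes[k];
  }
  return List::create(
    _["positions"] = pos,
    _["box"] = NumericVector::create(box.L[0], box.L[1], box.L[2]),
    _["U"] = U,
    _["U_recomputed"] = U_recomputed,
    _["u_series"] = wrap(u_series),
    _["v_series"] = wrap(v_series),
    _["frames"] = frames_out,
    _["frame_boxes"] = boxes_out,
    _["acc_disp"] = (double)acc_disp / std::max(try_disp, 1L),
    _["acc_vol"] = try_vol > 0 ? (double)acc_vol / try_vol : NA_REAL,
    _["n_rejected_small_box"] = (double)rej_small,
    _["max_disp_final"] = max_disp,
    _["max_rho_dev"] = max_rho_dev,
    _["max_grad_dev"] = max_grad_dev,
    _["n_fallback"] = (double)tab.n_fallback);
}
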