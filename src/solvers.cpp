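#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Voxel (i,j,k) -> flat index, column-major like R arrays.
static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

static inline int wrap(int i, int n) {
  if (i < 0) return i + n;
  if (i >= n) return i - n;
  return i;
}

// Pseudo-steady diffusion-reaction solve by Picard-linearized Gauss-Seidel.
//
// Discretizes D*lap(S) + r(S) = 0 on a regular voxel grid with spacing h.
// Boundaries: periodic in x and y; zero flux at the substratum (k = 0) and
// at the top face (voxels flagged in bulk_mask are Dirichlet-clamped to
// bulk_conc, which normally includes the whole top region).
//
// Reaction: r(S) = sum_g vmax[v,g] * S/(Ks[g] + S)  (vmax <= 0 for sinks)
//           + crate[v]                               (constant part, optional)
// Monod sinks are rewritten as -(|vmax|/(Ks+S_old)) * S each update so the
// iteration stays non-negative; constant-rate solutions are floored at 0.
//
static double steady_residual(const NumericVector &S, int nx, int ny, int nz,
                              const NumericMatrix &vmax,
                              const NumericVector &Ks,
                              const NumericVector &crate,
                              const LogicalVector &bulk_mask,
                              double a, double scale) {
  const int ng = Ks.size();
  const bool has_crate = crate.size() == nx * ny * nz;
  double resid = 0.0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int v = idx3(i, j, k, nx, ny);
        if (bulk_mask[v]) continue;
        double nb = 0.0; int ncount = 0;
        nb += S[idx3(wrap(i - 1, nx), j, k, nx, ny)]; ++ncount;
        nb += S[idx3(wrap(i + 1, nx), j, k, nx, ny)]; ++ncount;
        nb += S[idx3(i, wrap(j - 1, ny), k, nx, ny)]; ++ncount;
        nb += S[idx3(i, wrap(j + 1, ny), k, nx, ny)]; ++ncount;
        if (k > 0)      { nb += S[idx3(i, j, k - 1, nx, ny)]; ++ncount; }
        if (k < nz - 1) { nb += S[idx3(i, j, k + 1, nx, ny)]; ++ncount; }
        double r = a * (nb - ncount * S[v]);
        if (has_crate) r += crate[v];
        for (int g = 0; g < ng; ++g)
          r += vmax(v, g) * S[v] / (Ks[g] + S[v]);
        // skip floored voxels where a constant sink cannot be satisfied
        if (S[v] == 0.0 && r < 0) continue;
        const double rn = std::fabs(r) / (a * scale);
        if (rn > resid) resid = rn;
      }
    }
  }
  return resid;
}

// [[Rcpp::export]]
List solve_steady_cpp(NumericVector conc0, IntegerVector dims,
                      NumericMatrix vmax, NumericVector Ks,
                      NumericVector crate,
                      LogicalVector bulk_mask, double bulk_conc,
                      double D, double h, double tol, int maxit,
                      double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  const int ng = Ks.size();
  const bool has_crate = crate.size() == nvox;
  NumericVector S = clone(conc0);
  const double a = D / (h * h);

  for (int v = 0; v < nvox; ++v) if (bulk_mask[v]) S[v] = bulk_conc;

  double scale = bulk_conc;
  for (int v = 0; v < nvox; ++v) if (S[v] > scale) scale = S[v];
  if (scale <= 0) scale = 1.0;

  int iter = 0;
  double resid = R_PosInf;
  for (iter = 0; iter < maxit; ++iter) {
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int v = idx3(i, j, k, nx, ny);
          if (bulk_mask[v]) continue;
          double nb = 0.0;
          int ncount = 0;
          nb += S[idx3(wrap(i - 1, nx), j, k, nx, ny)]; ++ncount;
          nb += S[idx3(wrap(i + 1, nx), j, k, nx, ny)]; ++ncount;
          nb += S[idx3(i, wrap(j - 1, ny), k, nx, ny)]; ++ncount;
          nb += S[idx3(i, wrap(j + 1, ny), k, nx, ny)]; ++ncount;
          if (k > 0)      { nb += S[idx3(i, j, k - 1, nx, ny)]; ++ncount; }
          if (k < nz - 1) { nb += S[idx3(i, j, k + 1, nx, ny)]; ++ncount; }
          double numer = a * nb;
          double denom = a * ncount;
          if (has_crate) numer += crate[v];
          for (int g = 0; g < ng; ++g) {
            const double vm = vmax(v, g);
            if (vm == 0.0) continue;
            const double lin = std::fabs(vm) / (Ks[g] + S[v]);
            if (vm < 0) denom += lin; else numer += vm * S[v] / (Ks[g] + S[v]);
          }
          // successive over-relaxation on the Picard-linearized update
          double Snew = S[v] + omega * (numer / denom - S[v]);
          if (Snew < 0) Snew = 0;
          S[v] = Snew;
        }
      }
    }
    if ((iter + 1) % 5 == 0 || iter == maxit - 1) {
      resid = steady_residual(S, nx, ny, nz, vmax, Ks, crate, bulk_mask,
                              a, scale);
      if (resid <= tol) { ++iter; break; }
    }
  }

  return List::create(_["conc"] = S, _["iterations"] = iter,
                      _["residual"] = resid,
                      _["converged"] = resid <= tol);
}

// One transient diffusion step with volumetric sources, explicit FTCS with
// internal sub-stepping for stability. Zero flux top and bottom, periodic
// laterally, so total mass changes exactly by sum(source)*dt per voxel.
// [[Rcpp::export]]
NumericVector step_transient_cpp(NumericVector conc0, IntegerVector dims,
                                 NumericVector source, double D, double h,
                                 double dt, double safety) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  NumericVector S = clone(conc0);
  const double dt_stab = safety * h * h / (6.0 * D);
  const int nsub = std::max(1, (int)std::ceil(dt / dt_stab));
  const double dts = dt / nsub;
  const double lam = D * dts / (h * h);
  std::vector<double> Snew(nvox);
  const bool has_src = source.size() == nvox;

  for (int s = 0; s < nsub; ++s) {
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int v = idx3(i, j, k, nx, ny);
          double nb = 0.0; int ncount = 0;
          nb += S[idx3(wrap(i - 1, nx), j, k, nx, ny)]; ++ncount;
          nb += S[idx3(wrap(i + 1, nx), j, k, nx, ny)]; ++ncount;
          nb += S[idx3(i, wrap(j - 1, ny), k, nx, ny)]; ++ncount;
          nb += S[idx3(i, wrap(j + 1, ny), k, nx, ny)]; ++ncount;
          if (k > 0)      { nb += S[idx3(i, j, k - 1, nx, ny)]; ++ncount; }
          if (k < nz - 1) { nb += S[idx3(i, j, k + 1, nx, ny)]; ++ncount; }
          double val = S[v] + lam * (nb - ncount * S[v]);
          if (has_src) val += source[v] * dts;
          Snew[v] = val;
        }
      }
    }
    for (int v = 0; v < nvox; ++v) S[v] = Snew[v];
  }
  return S;
}

// Pairwise shoving relaxation with a uniform cell list. Agents are hard
// spheres; each overlapping pair is moved apart along the center line, half
// the overlap each, Gauss-Seidel style in ascending index order (callers
// sort by agent id so relaxation is deterministic). Periodic in x,y; z is
// clamped to [radius, Lz - radius].
// [[Rcpp::export]]
List shove_cpp(NumericMatrix pos0, NumericVector radius,
               double Lx, double Ly, double Lz,
               double tol, double mult, int max_sweeps) {
  const int n = pos0.nrow();
  NumericMatrix pos = clone(pos0);
  if (n < 2)
    return List::create(_["pos"] = pos, _["sweeps"] = 0,
                        _["max_overlap"] = 0.0, _["converged"] = true);

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) if (radius[i] > rmax) rmax = radius[i];
  const double cell = std::max(2.0 * rmax + tol, 1e-6);
  const int ncx = std::max(1, (int)std::floor(Lx / cell));
  const int ncy = std::max(1, (int)std::floor(Ly / cell));
  const int ncz = std::max(1, (int)std::floor(Lz / cell));
  const double hx = Lx / ncx, hy = Ly / ncy, hz = Lz / ncz;

  std::vector<int> head(ncx * ncy * ncz), nxt(n);
  int sweeps = 0;
  double maxov = 0.0;
  bool converged = false;

  for (sweeps = 0; sweeps < max_sweeps; ++sweeps) {
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < n; ++i) {
      int ci = std::min(ncx - 1, std::max(0, (int)(pos(i, 0) / hx)));
      int cj = std::min(ncy - 1, std::max(0, (int)(pos(i, 1) / hy)));
      int ck = std::min(ncz - 1, std::max(0, (int)(pos(i, 2) / hz)));
      int c = ci + ncx * (cj + ncy * ck);
      nxt[i] = head[c];
      head[c] = i;
    }
    maxov = 0.0;
    for (int i = 0; i < n; ++i) {
      int ci = std::min(ncx - 1, std::max(0, (int)(pos(i, 0) / hx)));
      int cj = std::min(ncy - 1, std::max(0, (int)(pos(i, 1) / hy)));
      int ck = std::min(ncz - 1, std::max(0, (int)(pos(i, 2) / hz)));
      for (int dk = -1; dk <= 1; ++dk) {
        int k2 = ck + dk;
        if (k2 < 0 || k2 >= ncz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int j2 = (ncy > 1) ? wrap(cj + dj, ncy) : 0;
          if (ncy == 1 && dj != 0) continue;
          for (int di = -1; di <= 1; ++di) {
            int i2 = (ncx > 1) ? wrap(ci + di, ncx) : 0;
            if (ncx == 1 && di != 0) continue;
            for (int j = head[i2 + ncx * (j2 + ncy * k2)]; j != -1; j = nxt[j]) {
              if (j <= i) continue;
              double dx = pos(i, 0) - pos(j, 0);
              double dy = pos(i, 1) - pos(j, 1);
              double dz = pos(i, 2) - pos(j, 2);
              dx -= Lx * std::round(dx / Lx);
              dy -= Ly * std::round(dy / Ly);
              const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
              const double ov = radius[i] + radius[j] - d;
              if (ov <= tol) continue;
              if (ov > maxov) maxov = ov;
              double ux, uy, uz;
              if (d > 1e-12) { ux = dx / d; uy = dy / d; uz = dz / d; }
              else { ux = 0; uy = 0; uz = 1; }  // coincident: split vertically
              const double push = 0.5 * ov * mult;
              pos(i, 0) += push * ux; pos(i, 1) += push * uy; pos(i, 2) += push * uz;
              pos(j, 0) -= push * ux; pos(j, 1) -= push * uy; pos(j, 2) -= push * uz;
              for (int a : {i, j}) {
                pos(a, 0) -= Lx * std::floor(pos(a, 0) / Lx);
                pos(a, 1) -= Ly * std::floor(pos(a, 1) / Ly);
                if (pos(a, 2) < radius[a]) pos(a, 2) = radius[a];
                if (pos(a, 2) > Lz - radius[a]) pos(a, 2) = Lz - radius[a];
              }
            }
          }
        }
      }
    }
    if (maxov <= tol) { converged = true; ++sweeps; break; }
  }
  return List::create(_["pos"] = pos, _["sweeps"] = sweeps,
                      _["max_overlap"] = maxov, _["converged"] = converged);
}
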