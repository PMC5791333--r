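#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Lattice layout shared with the R side: site (x, y) -> linear index
// (y-1)*nx + (x-1) (0-based here). All kernels use a 5-point Laplacian with
// zero-flux (Neumann) domain boundaries unless stated otherwise.

// Steady-state linear reaction-diffusion solve by red-black Gauss-Seidel:
//   0 = D * lap(C) + S(x) - k(x) * C
// with S >= 0, k >= 0. Returns the field, iteration count and final residual.
// Missing neighbours at the domain boundary are dropped from the stencil
// (zero-flux). Diagonal dominance (k >= 0) guarantees convergence.
// [[Rcpp::export]]
List rd_gs_solve_cpp(int nx, int ny, double h, double D,
                     NumericVector S, NumericVector k,
                     NumericVector init, double tol, int max_iter,
                     double omega = 1.0) {
  const int n = nx * ny;
  std::vector<double> C(init.begin(), init.end());
  const double ih2 = D / (h * h);
  double resid = R_PosInf;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    for (int color = 0; color < 2; ++color) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          if (((x + y) & 1) != color) continue;
          int i = y * nx + x;
          double nb = 0.0; int nnb = 0;
          if (x > 0)      { nb += C[i - 1];  ++nnb; }
          if (x < nx - 1) { nb += C[i + 1];  ++nnb; }
          if (y > 0)      { nb += C[i - nx]; ++nnb; }
          if (y < ny - 1) { nb += C[i + nx]; ++nnb; }
          double gs = (ih2 * nb + S[i]) / (ih2 * nnb + k[i]);
          C[i] = (1.0 - omega) * C[i] + omega * gs;
        }
      }
    }
    if (it % 4 == 0 || it == max_iter) {
      resid = 0.0;
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          int i = y * nx + x;
          double nb = 0.0; int nnb = 0;
          if (x > 0)      { nb += C[i - 1];  ++nnb; }
          if (x < nx - 1) { nb += C[i + 1];  ++nnb; }
          if (y > 0)      { nb += C[i - nx]; ++nnb; }
          if (y < ny - 1) { nb += C[i + nx]; ++nnb; }
          double r = ih2 * (nb - nnb * C[i]) + S[i] - k[i] * C[i];
          if (std::fabs(r) > resid) resid = std::fabs(r);
        }
      }
      if (resid <= tol) break;
    }
  }
  return List::create(_["values"] = NumericVector(C.begin(), C.end()),
                      _["iterations"] = it,
                      _["residual"] = resid,
                      _["converged"] = (resid <= tol));
}

// Poisson solve for tumor oncotic pressure:  lap(P) = rhs on mask sites,
// Dirichlet P = 0 on off-mask sites (host tissue); off-domain neighbours
// dropped (zero-flux at the outer boundary).
// [[Rcpp::export]]
List poisson_mask_solve_cpp(int nx, int ny, double h,
                            LogicalVector mask, NumericVector rhs,
                            double tol, int max_iter,
                            double omega = 1.0) {
  const int n = nx * ny;
  std::vector<double> P(n, 0.0);
  const double h2 = h * h;
  double resid = R_PosInf;
  int it = 0;
  bool any = false;
  for (int i = 0; i < n; ++i) if (mask[i]) { any = true; break; }
  if (!any)
    return List::create(_["values"] = NumericVector(n),
                        _["iterations"] = 0, _["residual"] = 0.0,
                        _["converged"] = true);
  for (it = 1; it <= max_iter; ++it) {
    for (int color = 0; color < 2; ++color) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          if (((x + y) & 1) != color) continue;
          int i = y * nx + x;
          if (!mask[i]) continue;
          double nb = 0.0; int nnb = 0;
          if (x > 0)      { nb += P[i - 1];  ++nnb; }
          if (x < nx - 1) { nb += P[i + 1];  ++nnb; }
          if (y > 0)      { nb += P[i - nx]; ++nnb; }
          if (y < ny - 1) { nb += P[i + nx]; ++nnb; }
          double gs = (nb - h2 * rhs[i]) / nnb;
          P[i] = (1.0 - omega) * P[i] + omega * gs;
        }
      }
    }
    if (it % 4 == 0 || it == max_iter) {
      resid = 0.0;
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          int i = y * nx + x;
          if (!mask[i]) continue;
          double nb = 0.0; int nnb = 0;
          if (x > 0)      { nb += P[i - 1];  ++nnb; }
          if (x < nx - 1) { nb += P[i + 1];  ++nnb; }
          if (y > 0)      { nb += P[i - nx]; ++nnb; }
          if (y < ny - 1) { nb += P[i + nx]; ++nnb; }
          double r = (nb - nnb * P[i]) / h2 - rhs[i];
          if (std::fabs(r) > resid) resid = std::fabs(r);
        }
      }
      if (resid <= tol) break;
    }
  }
  return List::create(_["values"] = NumericVector(P.begin(), P.end()),
                      _["iterations"] = it,
                      _["residual"] = resid,
                      _["converged"] = (resid <= tol));
}

// One conservative upwind advection step of the tumor volume fraction phi
// under the Darcy velocity v = -mu * grad(P), plus local source src
// (already includes phi weighting):  phi' = phi + dt * (-div(v phi) + src),
// then clamped to [0, 1]. Face velocities at the outer boundary are zero, so
// the scheme conserves sum(phi) + dt*sum(src) exactly up to the clamp.
// [[Rcpp::export]]
NumericVector advect_phi_cpp(int nx, int ny, double h, double mu,
                             NumericVector phi, NumericVector P,
                             NumericVector src, double dt) {
  NumericVector out(nx * ny);
  std::vector<double> fx((nx + 1) * ny, 0.0), fy(nx * (ny + 1), 0.0);
  // x faces: fx[y*(nx+1) + x] is the face between (x-1,y) and (x,y)
  for (int y = 0; y < ny; ++y) {
    for (int x = 1; x < nx; ++x) {
      int i = y * nx + x;
      double u = -mu * (P[i] - P[i - 1]) / h;
      fx[y * (nx + 1) + x] = (u > 0) ? u * phi[i - 1] : u * phi[i];
    }
  }
  for (int y = 1; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      int i = y * nx + x;
      double v = -mu * (P[i] - P[i - nx]) / h;
      fy[y * nx + x] = (v > 0) ? v * phi[i - nx] : v * phi[i];
    }
  }
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      int i = y * nx + x;
      double div = (fx[y * (nx + 1) + x + 1] - fx[y * (nx + 1) + x]) / h +
                   (fy[(y + 1) * nx + x]     - fy[y * nx + x]) / h;
      double v = phi[i] + dt * (-div + src[i]);
      out[i] = (v < 0.0) ? 0.0 : (v > 1.0 ? 1.0 : v);
    }
  }
  return out;
}

// Breadth-first search over vessel segments: which lattice sites are
// connected to a seed site through traversable segments. i1/i2 are 0-based
// site indices of segment endpoints, open marks traversable segments.
// [[Rcpp::export]]
LogicalVector segment_bfs_cpp(int n_sites, IntegerVector i1, IntegerVector i2,
                              LogicalVector open, LogicalVector seed) {
  std::vector<std::vector<int>> adj(n_sites);
  const int m = i1.size();
  for (int s = 0; s < m; ++s) {
    if (!open[s]) continue;
    adj[i1[s]].push_back(i2[s]);
    adj[i2[s]].push_back(i1[s]);
  }
  LogicalVector vis(n_sites, false);
  std::queue<int> q;
  for (int i = 0; i < n_sites; ++i) {
    if (seed[i] && !adj[i].empty()) { vis[i] = true; q.push(i); }
  }
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int v : adj[u]) if (!vis[v]) { vis[v] = true; q.push(v); }
  }
  return vis;
}
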