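#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum-image displacement on an orthorhombic box.
static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

struct CellGrid {
  int nx, ny, nz;
  double Lx, Ly, Lz;
  std::vector<int> head;   // first bead index per cell, -1 terminated
  std::vector<int> next;

  CellGrid(double Lx_, double Ly_, double Lz_, double cell_min, int nbead)
      : Lx(Lx_), Ly(Ly_), Lz(Lz_) {
    nx = std::max(1, (int)std::floor(Lx / cell_min));
    ny = std::max(1, (int)std::floor(Ly / cell_min));
    nz = std::max(1, (int)std::floor(Lz / cell_min));
    head.assign((size_t)nx * ny * nz, -1);
    next.assign(nbead, -1);
  }
  bool usable() const { return nx >= 3 && ny >= 3 && nz >= 3; }
  static inline double wrap(double x, double L) {
    double w = x - L * std::floor(x / L);
    if (w >= L) w -= L;
    return w;
  }
  inline int cell_of(double x, double y, double z) const {
    int cx = (int)(wrap(x, Lx) / Lx * nx); if (cx >= nx) cx = nx - 1;
    int cy = (int)(wrap(y, Ly) / Ly * ny); if (cy >= ny) cy = ny - 1;
    int cz = (int)(wrap(z, Lz) / Lz * nz); if (cz >= nz) cz = nz - 1;
    return cx + nx * (cy + ny * cz);
  }
  inline void insert(int bead, double x, double y, double z) {
    int c = cell_of(x, y, z);
    next[bead] = head[c];
    head[c] = bead;
  }
};

// All (i, j) pairs between point sets a and b with minimum-image distance
// strictly below cutoff. Contractually identical to the O(na*nb) scan; a
// cell grid is used when the box admits >= 3 cells per dimension.
// [[Rcpp::export]]
IntegerMatrix cpp_find_pairs(NumericMatrix a, NumericMatrix b,
                             NumericVector box, double cutoff) {
  const int na = a.nrow(), nb = b.nrow();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double c2 = cutoff * cutoff;
  std::vector<int> pi, pj;
  CellGrid grid(Lx, Ly, Lz, cutoff, nb);
  if (grid.usable()) {
    for (int j = 0; j < nb; ++j) grid.insert(j, b(j, 0), b(j, 1), b(j, 2));
    for (int i = 0; i < na; ++i) {
      const double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
      int cx = (int)(CellGrid::wrap(xi, Lx) / Lx * grid.nx); if (cx >= grid.nx) cx = grid.nx - 1;
      int cy = (int)(CellGrid::wrap(yi, Ly) / Ly * grid.ny); if (cy >= grid.ny) cy = grid.ny - 1;
      int cz = (int)(CellGrid::wrap(zi, Lz) / Lz * grid.nz); if (cz >= grid.nz) cz = grid.nz - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ux = (cx + dx + grid.nx) % grid.nx;
            int uy = (cy + dy + grid.ny) % grid.ny;
            int uz = (cz + dz + grid.nz) % grid.nz;
            for (int j = grid.head[ux + grid.nx * (uy + grid.ny * uz)];
                 j != -1; j = grid.next[j]) {
              double ddx = min_image(xi - b(j, 0), Lx);
              double ddy = min_image(yi - b(j, 1), Ly);
              double ddz = min_image(zi - b(j, 2), Lz);
              if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
                pi.push_back(i + 1);
                pj.push_back(j + 1);
              }
            }
          }
    }
  } else {
    for (int i = 0; i < na; ++i)
      for (int j = 0; j < nb; ++j) {
        double ddx = min_image(a(i, 0) - b(j, 0), Lx);
        double ddy = min_image(a(i, 1) - b(j, 1), Ly);
        double ddz = min_image(a(i, 2) - b(j, 2), Lz);
        if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
          pi.push_back(i + 1);
          pj.push_back(j + 1);
        }
      }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k];
    out(k, 1) = pj[k];
  }
  return out;
}

// Single pass over a trajectory: per-(residue, lipid-bead-key) contact
// counts, per-frame any-contact events per lipid, and per-frame helix-set
// bitmasks per lipid. coords has dim (n_beads, 3, n_frames); indices are
// 0-based on entry.
// [[Rcpp::export]]
List cpp_traj_contacts(NumericVector coords, IntegerVector dims,
                       NumericMatrix box,
                       IntegerVector pidx, IntegerVector pres_row,
                       IntegerVector phelix,
                       IntegerVector lidx, IntegerVector lkey,
                       IntegerVector llip,
                       double cutoff, int nres, int nkey, int nlip) {
  const int nbead = dims[0], nframe = dims[2];
  const int np = pidx.size(), nl = lidx.size();
  const double c2 = cutoff * cutoff;
  NumericMatrix counts(nres, nkey);
  LogicalMatrix events(nframe, nlip);
  IntegerMatrix sites(nframe, nlip);
  const double *xyz = REAL(coords);
  std::vector<double> lx(nl), ly(nl), lz(nl);

  for (int f = 0; f < nframe; ++f) {
    const double Lx = box(f, 0), Ly = box(f, 1), Lz = box(f, 2);
    const double *fr = xyz + (size_t)f * nbead * 3;
    for (int j = 0; j < nl; ++j) {
      int bj = lidx[j];
      lx[j] = fr[bj];
      ly[j] = fr[bj + nbead];
      lz[j] = fr[bj + 2 * nbead];
    }
    CellGrid grid(Lx, Ly, Lz, cutoff, nl);
    bool use_grid = grid.usable();
    if (use_grid)
      for (int j = 0; j < nl; ++j) grid.insert(j, lx[j], ly[j], lz[j]);
    for (int i = 0; i < np; ++i) {
      int bi = pidx[i];
      const double xi = fr[bi], yi = fr[bi + nbead], zi = fr[bi + 2 * nbead];
      const int row = pres_row[i], hel = phelix[i];
      if (use_grid) {
        int cx = (int)(CellGrid::wrap(xi, Lx) / Lx * grid.nx); if (cx >= grid.nx) cx = grid.nx - 1;
        int cy = (int)(CellGrid::wrap(yi, Ly) / Ly * grid.ny); if (cy >= grid.ny) cy = grid.ny - 1;
        int cz = (int)(CellGrid::wrap(zi, Lz) / Lz * grid.nz); if (cz >= grid.nz) cz = grid.nz - 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ux = (cx + dx + grid.nx) % grid.nx;
              int uy = (cy + dy + grid.ny) % grid.ny;
              int uz = (cz + dz + grid.nz) % grid.nz;
              for (int j = grid.head[ux + grid.nx * (uy + grid.ny * uz)];
                   j != -1; j = grid.next[j]) {
                double ddx = min_image(xi - lx[j], Lx);
                double ddy = min_image(yi - ly[j], Ly);
                double ddz = min_image(zi - lz[j], Lz);
                if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
                  counts(row, lkey[j]) += 1.0;
                  events(f, llip[j]) = true;
                  if (hel >= 0) sites(f, llip[j]) |= (1 << hel);
                }
              }
            }
      } else {
        for (int j = 0; j < nl; ++j) {
          double ddx = min_image(xi - lx[j], Lx);
          double ddy = min_image(yi - ly[j], Ly);
          double ddz = min_image(zi - lz[j], Lz);
          if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
            counts(row, lkey[j]) += 1.0;
            events(f, llip[j]) = true;
            if (hel >= 0) sites(f, llip[j]) |= (1 << hel);
          }
        }
      }
    }
    if (f % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["counts"] = counts, _["events"] = events,
                      _["sites"] = sites);
}

// Lateral 2D Gaussian random walk for lipid centres with periodic wrapping,
// rejection from exclusion disks (protein core/helices) and slowed stepping
// (step_sd / multiplier) inside planted residence-site disks. Uses R's RNG,
// so set.seed() governs reproducibility. Returns (n_frames x n_lipids)
// matrices of x and y; frame 1 holds the initial positions.
// [[Rcpp::export]]
List cpp_lipid_walk(NumericVector x0, NumericVector y0, int n_frames,
                    double step_sd,
                    NumericMatrix site_xy, NumericVector site_r,
                    NumericVector site_mult,
                    NumericMatrix excl_xy, NumericVector excl_r,
                    double Lx, double Ly) {
  const int nlip = x0.size(), nsite = site_xy.nrow(), nexcl = excl_xy.nrow();
  NumericMatrix X(n_frames, nlip), Y(n_frames, nlip);
  if (n_frames == 0) return List::create(_["x"] = X, _["y"] = Y);
  for (int l = 0; l < nlip; ++l) {
    X(0, l) = CellGrid::wrap(x0[l], Lx);
    Y(0, l) = CellGrid::wrap(y0[l], Ly);
  }
  for (int f = 1; f < n_frames; ++f) {
    for (int l = 0; l < nlip; ++l) {
      double x = X(f - 1, l), y = Y(f - 1, l);
      double sd = step_sd;
      for (int s = 0; s < nsite; ++s) {
        double dx = min_image(x - site_xy(s, 0), Lx);
        double dy = min_image(y - site_xy(s, 1), Ly);
        if (dx * dx + dy * dy < site_r[s] * site_r[s] && site_mult[s] > 1.0)
          sd = std::min(sd, step_sd / site_mult[s]);
      }
      double nx = x + norm_rand() * sd;
      double ny = y + norm_rand() * sd;
      bool blocked = false;
      for (int e = 0; e < nexcl; ++e) {
        double dx = min_image(nx - excl_xy(e, 0), Lx);
        double dy = min_image(ny - excl_xy(e, 1), Ly);
        if (dx * dx + dy * dy < excl_r[e] * excl_r[e]) { blocked = true; break; }
      }
      if (blocked) { nx = x; ny = y; }
      X(f, l) = CellGrid::wrap(nx, Lx);
      Y(f, l) = CellGrid::wrap(ny, Ly);
    }
    if (f % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["x"] = X, _["y"] = Y);
}
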