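// Core numerical kernels: DuFort-Frankel diffusion, agent sensing/steering,
// Michaelis-Menten degradation, mitosis, and the coupled tick loop.
//
// Conventions:
//   - Lattice is an R matrix (nr x nc), column-major. Node (i, j) (0-based)
//     sits at physical position x = j*dx, y = i*dx (origin lower-left, um).
//   - Concentrations in nM; field "mass" = concentration * dx^2 (nM um^2).
//   - All randomness goes through R's RNG (unif_rand / norm_rand), so R-level
//     set.seed() controls every draw and runs are bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

inline double wrap_angle(double a) {
  // wrap to (-pi, pi]
  a -= TWO_PI * std::floor((a + M_PI) / TWO_PI);
  if (a <= -M_PI || a > M_PI) a = M_PI;
  return a;
}

// ---------------------------------------------------------------------------
// Diffusion
// ---------------------------------------------------------------------------

// One leapfrog sweep over the lattice (raw pointers; column-major, stride nr).
// Out-of-domain neighbours take the centre value (finite-volume zero-flux
// ghost), which conserves total mass exactly in exact arithmetic. Negative
// undershoots (possible near discontinuities at a > 1/4) are clamped to zero;
// returns the clamped amount in concentration units.
//
// A Robert-Asselin-Williams (RAW) time filter is applied after each sweep:
// leapfrog schemes carry a neutral computational mode that decouples the
// space-time-parity sublattices (visible as a persistent checkerboard when
// rough data - a point load, or a cell-shaped sink - is introduced). The RAW
// filter damps that mode at every wavenumber while keeping the scheme
// unconditionally stable (the plain Robert-Asselin form does not: it pushes
// the checkerboard eigenvalue outside the unit circle for D dt/dx^2 > ~1/4).
// Both corrections are proportional to the same curvature d, whose lattice
// sum vanishes, so the filter conserves mass exactly.
static const double RAW_NU = 0.1;
static const double RAW_ALPHA = 0.53;

static double df_sweep(double* cur, const double* prv, double* out,
                       int nr, int nc, double w0, double w1) {
  double clamped = 0.0;
  // the filter mutates cur, so a column may only be filtered once the sweep
  // front is two columns past it (the stencil reads cur at j-1, j, j+1)
  auto filter_col = [&](int jf) {
    double* cc = cur + (R_xlen_t)jf * nr;
    const double* pp = prv + (R_xlen_t)jf * nr;
    double* oo = out + (R_xlen_t)jf * nr;
    for (int i = 0; i < nr; ++i) {
      double d = RAW_NU * (oo[i] - 2.0 * cc[i] + pp[i]);
      double fm = cc[i] + RAW_ALPHA * d;
      double fn = oo[i] + (RAW_ALPHA - 1.0) * d;
      if (fm < 0) { clamped -= fm; fm = 0.0; }
      if (fn < 0) { clamped -= fn; fn = 0.0; }
      cc[i] = fm;
      oo[i] = fn;
    }
  };
  for (int j = 0; j < nc; ++j) {
    double* cc = cur + (R_xlen_t)j * nr;
    const double* pp = prv + (R_xlen_t)j * nr;
    double* oo = out + (R_xlen_t)j * nr;
    int offL = (j > 0) ? -nr : 0;
    int offR = (j + 1 < nc) ? nr : 0;
    for (int i = 0; i < nr; ++i) {
      double c = cc[i];
      double up    = (i + 1 < nr) ? cc[i + 1] : c;
      double down  = (i > 0)      ? cc[i - 1] : c;
      double v = w0 * pp[i] + w1 * (up + down + cc[i + offL] + cc[i + offR]);
      if (v < 0) { clamped -= v; v = 0.0; }
      oo[i] = v;
    }
    if (j >= 2) filter_col(j - 2);
  }
  if (nc >= 2) filter_col(nc - 2);
  filter_col(nc - 1);
  return clamped;
}

// One DuFort-Frankel leapfrog step for du/dt = D lap(u), no-flux borders.
//   u_new = [(1-4a) u_prev + 2a (N+S+E+W)] / (1+4a),  a = D dt / dx^2
// [[Rcpp::export]]
List cpp_df_step(NumericMatrix conc, NumericMatrix prev,
                 double D, double dx, double dt,
                 IntegerVector fixed_idx, NumericVector fixed_vals) {
  int nr = conc.nrow(), nc = conc.ncol();
  if (prev.nrow() != nr || prev.ncol() != nc)
    stop("lattice shape mismatch between the two time levels");
  if (dt <= 0) stop("dt must be positive");
  double a = D * dt / (dx * dx);
  double w0 = (1.0 - 4.0 * a) / (1.0 + 4.0 * a);
  double w1 = 2.0 * a / (1.0 + 4.0 * a);
  conc = clone(conc);  // the filter mutates the middle level
  NumericMatrix out(nr, nc);
  double clamped = df_sweep(conc.begin(), prev.begin(), out.begin(),
                            nr, nc, w0, w1);
  // re-pin reservoir/sink points on both levels
  int nf = fixed_idx.size();
  for (int k = 0; k < nf; ++k) {
    out[fixed_idx[k]] = fixed_vals[k];
    conc[fixed_idx[k]] = fixed_vals[k];
  }
  return List::create(_["conc"] = out, _["prev"] = conc,
                      _["clamped_mass"] = clamped * dx * dx);
}

// Forward-Euler (FTCS) step used to bootstrap the two-level scheme.
// [[Rcpp::export]]
NumericMatrix cpp_ftcs_step(NumericMatrix conc, double D, double dx, double dt,
                            IntegerVector fixed_idx, NumericVector fixed_vals) {
  int nr = conc.nrow(), nc = conc.ncol();
  if (dt <= 0) stop("dt must be positive");
  double a = D * dt / (dx * dx);
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double c = conc(i, j);
      double up    = (i + 1 < nr) ? conc(i + 1, j) : c;
      double down  = (i - 1 >= 0) ? conc(i - 1, j) : c;
      double right = (j + 1 < nc) ? conc(i, j + 1) : c;
      double left  = (j - 1 >= 0) ? conc(i, j - 1) : c;
      out(i, j) = c + a * (up + down + left + right - 4.0 * c);
    }
  }
  for (int k = 0; k < fixed_idx.size(); ++k) out[fixed_idx[k]] = fixed_vals[k];
  return out;
}

// ---------------------------------------------------------------------------
// Sensing helpers
// ---------------------------------------------------------------------------

// Grid nodes whose centres lie within `radius` (Euclidean, <=) of (x, y).
// Never empty: falls back to the nearest node. Returns 0-based (row, col).
static void overlap_nodes(double x, double y, double radius, double dx,
                          int nr, int nc,
                          std::vector<int>& rows, std::vector<int>& cols) {
  rows.clear(); cols.clear();
  int jc = (int)std::lround(x / dx), ic = (int)std::lround(y / dx);
  int span = (int)std::floor(radius / dx) + 1;
  double r2 = radius * radius;
  for (int di = -span; di <= span; ++di) {
    int i = ic + di;
    if (i < 0 || i >= nr) continue;
    for (int dj = -span; dj <= span; ++dj) {
      int j = jc + dj;
      if (j < 0 || j >= nc) continue;
      double ddx = j * dx - x, ddy = i * dx - y;
      if (ddx * ddx + ddy * ddy <= r2) { rows.push_back(i); cols.push_back(j); }
    }
  }
  if (rows.empty()) {
    rows.push_back(std::min(std::max(ic, 0), nr - 1));
    cols.push_back(std::min(std::max(jc, 0), nc - 1));
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_overlap_nodes(double x, double y, double radius, double dx,
                                int nr, int nc) {
  std::vector<int> rows, cols;
  overlap_nodes(x, y, radius, dx, nr, nc, rows, cols);
  IntegerMatrix out(rows.size(), 2);
  for (size_t k = 0; k < rows.size(); ++k) {
    out(k, 0) = rows[k] + 1;  // 1-based for R
    out(k, 1) = cols[k] + 1;
  }
  return out;
}

// Least-squares plane fit v = a + gx*x + gy*y over scattered points;
// returns (gx, gy); zero vector for degenerate point sets.
static void plane_gradient(const std::vector<double>& xs,
                           const std::vector<double>& ys,
                           const std::vector<double>& vs,
                           double& gx, double& gy) {
  gx = 0.0; gy = 0.0;
  size_t n = xs.size();
  if (n < 3) return;
  double mx = 0, my = 0, mv = 0;
  for (size_t k = 0; k < n; ++k) { mx += xs[k]; my += ys[k]; mv += vs[k]; }
  mx /= n; my /= n; mv /= n;
  double sxx = 0, sxy = 0, syy = 0, sxv = 0, syv = 0;
  for (size_t k = 0; k < n; ++k) {
    double ax = xs[k] - mx, ay = ys[k] - my, av = vs[k] - mv;
    sxx += ax * ax; sxy += ax * ay; syy += ay * ay;
    sxv += ax * av; syv += ay * av;
  }
  double det = sxx * syy - sxy * sxy;
  double scale = sxx + syy;
  if (det <= 1e-12 * scale * scale) return;  // collinear / degenerate
  gx = (syy * sxv - sxy * syv) / det;
  gy = (sxx * syv - sxy * sxv) / det;
}

// [[Rcpp::export]]
NumericVector cpp_plane_gradient(NumericVector x, NumericVector y,
                                 NumericVector v) {
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end()),
      vs(v.begin(), v.end());
  double gx, gy;
  plane_gradient(xs, ys, vs, gx, gy);
  return NumericVector::create(gx, gy);
}

// Biased-persistent heading proposal: wrapped-normal persistence draw plus a
// bias vector of length `bias` along the unit gradient direction.
// [[Rcpp::export]]
NumericVector cpp_propose_heading(int n, double heading, double sigma,
                                  double bias, double gx, double gy) {
  NumericVector out(n);
  double gn = std::sqrt(gx * gx + gy * gy);
  double ux = 0, uy = 0;
  bool biased = (gn > 0.0 && bias > 0.0);
  if (biased) { ux = gx / gn; uy = gy / gn; }
  for (int k = 0; k < n; ++k) {
    double th = wrap_angle(heading + sigma * norm_rand());
    if (biased) {
      double vx = std::cos(th) + bias * ux;
      double vy = std::sin(th) + bias * uy;
      if (vx != 0.0 || vy != 0.0) th = std::atan2(vy, vx);
    }
    out[k] = th;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Coupled simulation loop
// ---------------------------------------------------------------------------

struct CellBuf {
  std::vector<double> buf;
  int pos;
  bool primed;  // false until first sense (or after mitotic reset)
  // the window mean is recomputed from the buffer at every use: an
  // incremental running sum would make results depend on where the caller
  // chunks the run (different rounding), breaking bit-reproducibility
  double mean() const {
    double s = 0.0;
    for (size_t w = 0; w < buf.size(); ++w) s += buf[w];
    s /= buf.size();
    if (s < 0) s = 0;
    if (s > 1) s = 1;
    return s;
  }
};

static double occupancy(double c, double kd) { return c / (c + kd); }

static double hill_induction(double y, double vb, double ki, double h) {
  double yh = std::pow(y, h), kh = std::pow(ki, h);
  return vb + (1.0 - vb) * yh / (kh + yh);
}

// Advance the coupled state by n_ticks agent ticks. `state` is modified via
// copies and a fresh list is returned; all randomness uses the R RNG.
// [[Rcpp::export]]
List cpp_run(List state, List params, int n_ticks) {
  // --- unpack field ---
  NumericMatrix conc = clone(as<NumericMatrix>(state["conc"]));
  NumericMatrix prev = clone(as<NumericMatrix>(state["prev"]));
  int nr = conc.nrow(), nc = conc.ncol();
  double dx = as<double>(state["dx"]);
  double D = as<double>(state["D"]);
  IntegerVector fixed_idx = state["fixed_idx"];      // 0-based linear
  NumericVector fixed_vals = state["fixed_vals"];
  double cumdeg = as<double>(state["cumulative_degraded"]);
  double clamped_mass = as<double>(state["clamped_mass"]);
  double t = as<double>(state["time"]);
  int tick0 = as<int>(state["tick"]);
  int next_id = as<int>(state["next_id"]);
  double Lx = (nc - 1) * dx, Ly = (nr - 1) * dx;

  // --- unpack cells ---
  NumericMatrix cs = as<NumericMatrix>(state["cells"]);  // id,x,y,heading
  int n0 = cs.nrow();
  std::vector<int> id(n0);
  std::vector<double> cx(n0), cy(n0), ch(n0);
  for (int k = 0; k < n0; ++k) {
    id[k] = (int)cs(k, 0); cx[k] = cs(k, 1); cy[k] = cs(k, 2); ch[k] = cs(k, 3);
  }
  int W = as<int>(params["window_ticks"]);
  NumericMatrix bufmat = as<NumericMatrix>(state["occ_buf"]);   // W x n
  IntegerVector bufpos = state["buf_pos"];
  LogicalVector primed0 = state["buf_primed"];
  std::vector<CellBuf> bufs(n0);
  for (int k = 0; k < n0; ++k) {
    bufs[k].buf.assign(W, 0.0);
    for (int w = 0; w < W; ++w) bufs[k].buf[w] = bufmat(w, k);
    bufs[k].pos = bufpos[k];
    bufs[k].primed = primed0[k];
  }

  // --- parameters ---
  double tick_s = as<double>(params["tick_s"]);
  int n_sub = as<int>(params["n_sub"]);
  double dt_f = tick_s / n_sub;
  double speed = as<double>(params["speed_um_min"]) / 60.0;  // um/s
  double sigma = as<double>(params["sigma"]);
  double bias = as<double>(params["bias_strength"]);
  double sens = as<double>(params["sensing_scale"]);
  double steer_floor = as<double>(params["steering_floor"]);
  int reorient_every = as<int>(params["reorient_ticks"]);
  double kd = as<double>(params["kd"]);
  double vmax = as<double>(params["vmax"]);   // nM um^2 / min
  double km = as<double>(params["km"]);
  double overlap_r = as<double>(params["overlap_radius"]);
  int deg_mode = as<int>(params["deg_mode"]);  // 0 none, 1 always, 2 induced
  double vb = as<double>(params["vb"]), ki = as<double>(params["ki"]),
         hh = as<double>(params["h"]);
  bool mito = as<bool>(params["mitogen"]);
  double mito_floor = as<double>(params["mitogen_floor"]);
  double mito_tmin = as<double>(params["min_division_time_min"]);
  int record_every = as<int>(params["record_ticks"]);
  int max_cells = as<int>(params["max_cells"]);

  double cell_area = dx * dx;  // per-node footprint area
  double w0 = (1.0 - 4.0 * D * dt_f / (dx * dx)) / (1.0 + 4.0 * D * dt_f / (dx * dx));
  double w1 = 2.0 * D * dt_f / (dx * dx) / (1.0 + 4.0 * D * dt_f / (dx * dx));

  std::vector<double> rec;          // trajectory rows, 8 cols
  std::vector<double> div_rec;      // time, mother, daughter
  std::vector<int> divided_since_record;  // ids flagged for next record
  std::vector<int> rows_s, cols_s;  // scratch for overlaps
  std::vector<double> xs_s, ys_s, vs_s;

  NumericMatrix work(nr, nc);  // scratch level for in-place leapfrog

  for (int step = 0; step < n_ticks; ++step) {
    // (1) field sub-steps
    for (int s = 0; s < n_sub; ++s) {
      clamped_mass += cell_area *
          df_sweep(conc.begin(), prev.begin(), work.begin(), nr, nc, w0, w1);
      // rotate levels: prev <- conc, conc <- work, recycle old prev
      NumericMatrix tmp = prev;
      prev = conc;
      conc = work;
      work = tmp;
      for (int k = 0; k < fixed_idx.size(); ++k) {
        conc[fixed_idx[k]] = fixed_vals[k];
        prev[fixed_idx[k]] = fixed_vals[k];
      }
    }

    int n_at_tick = (int)id.size();
    bool reorient = ((tick0 + step) % reorient_every == 0);

    // (2) per-cell phase, stable id (= index) order
    for (int k = 0; k < n_at_tick; ++k) {
      // --- sense ---
      int jn = (int)std::lround(cx[k] / dx);
      int in_ = (int)std::lround(cy[k] / dx);
      if (jn < 0) jn = 0; if (jn >= nc) jn = nc - 1;
      if (in_ < 0) in_ = 0; if (in_ >= nr) in_ = nr - 1;
      double y_now = occupancy(conc(in_, jn), kd);
      CellBuf& B = bufs[k];
      if (!B.primed) {
        std::fill(B.buf.begin(), B.buf.end(), y_now);
        B.pos = 0;
        B.primed = true;
      } else {
        B.buf[B.pos] = y_now;
        B.pos = (B.pos + 1) % W;
      }
      double y_avg = B.mean();

      overlap_nodes(cx[k], cy[k], overlap_r, dx, nr, nc, rows_s, cols_s);
      size_t np = rows_s.size();

      // --- degrade ---
      if (deg_mode > 0 && vmax > 0) {
        double cmean = 0.0;
        for (size_t p = 0; p < np; ++p) cmean += conc(rows_s[p], cols_s[p]);
        cmean /= np;
        if (cmean > 0) {
          double veff = vmax;
          if (deg_mode == 2) veff *= hill_induction(y_avg, vb, ki, hh);
          double r = veff * cmean / (cmean + km);        // nM um^2 / min
          double dconc = r * (tick_s / 60.0) / (np * cell_area);  // nM per node
          for (size_t p = 0; p < np; ++p) {
            double& cc = conc(rows_s[p], cols_s[p]);
            double& pp = prev(rows_s[p], cols_s[p]);
            double avail = cc < pp ? cc : pp;
            if (avail < 0) avail = 0;
            double d = dconc < avail ? dconc : avail;
            cc -= d; pp -= d;
            cumdeg += d * cell_area;
          }
        }
      }

      // --- reorient ---
      if (reorient) {
        xs_s.clear(); ys_s.clear(); vs_s.clear();
        double y_patch = 0.0;
        for (size_t p = 0; p < np; ++p) {
          xs_s.push_back(cols_s[p] * dx);
          ys_s.push_back(rows_s[p] * dx);
          double yv = occupancy(conc(rows_s[p], cols_s[p]), kd);
          vs_s.push_back(yv);
          y_patch += yv;
        }
        y_patch /= np;
        double gx, gy;
        plane_gradient(xs_s, ys_s, vs_s, gx, gy);
        double gn = std::sqrt(gx * gx + gy * gy);
        double th = wrap_angle(ch[k] + sigma * norm_rand());
        // too few occupied receptors -> no directional information
        if (gn > 0 && bias > 0 && sens > 0 && y_patch >= steer_floor) {
          double b_eff = bias * std::min(gn / sens, 1.0);
          double vx = std::cos(th) + b_eff * gx / gn;
          double vy = std::sin(th) + b_eff * gy / gn;
          if (vx != 0.0 || vy != 0.0) th = std::atan2(vy, vx);
        }
        ch[k] = th;
      }

      // --- move (reflecting walls) ---
      double nx = cx[k] + speed * tick_s * std::cos(ch[k]);
      double ny = cy[k] + speed * tick_s * std::sin(ch[k]);
      if (nx < 0)  { nx = -nx;          ch[k] = wrap_angle(M_PI - ch[k]); }
      if (nx > Lx) { nx = 2 * Lx - nx;  ch[k] = wrap_angle(M_PI - ch[k]); }
      if (ny < 0)  { ny = -ny;          ch[k] = wrap_angle(-ch[k]); }
      if (ny > Ly) { ny = 2 * Ly - ny;  ch[k] = wrap_angle(-ch[k]); }
      cx[k] = nx; cy[k] = ny;

      // --- mitosis ---
      if (mito && (int)id.size() < max_cells) {
        double lam = (y_avg - mito_floor) / (1.0 - mito_floor);
        if (lam > 0) {
          lam /= mito_tmin;                       // per minute
          double pdiv = 1.0 - std::exp(-lam * tick_s / 60.0);
          if (unif_rand() < pdiv) {
            int did = next_id++;
            id.push_back(did);
            cx.push_back(cx[k]); cy.push_back(cy[k]);
            ch.push_back(wrap_angle(unif_rand() * TWO_PI - M_PI));
            CellBuf nb; nb.buf.assign(W, 0.0); nb.pos = 0;
            nb.primed = true;  // refractory: zeroed window, refills by sensing
            bufs.push_back(nb);
            // mother refractory reset
            std::fill(B.buf.begin(), B.buf.end(), 0.0);
            B.pos = 0;
            div_rec.push_back(t + tick_s);
            div_rec.push_back(id[k]);
            div_rec.push_back(did);
            divided_since_record.push_back(id[k]);
            divided_since_record.push_back(did);
          }
        }
      }
    }

    t += tick_s;

    // (3) record
    if (record_every > 0 && ((tick0 + step + 1) % record_every == 0)) {
      for (size_t k = 0; k < id.size(); ++k) {
        int jn = (int)std::lround(cx[k] / dx);
        int in_ = (int)std::lround(cy[k] / dx);
        if (jn < 0) jn = 0; if (jn >= nc) jn = nc - 1;
        if (in_ < 0) in_ = 0; if (in_ >= nr) in_ = nr - 1;
        bool dv = false;
        for (size_t q = 0; q < divided_since_record.size(); ++q)
          if (divided_since_record[q] == id[k]) { dv = true; break; }
        rec.push_back(t);
        rec.push_back(id[k]);
        rec.push_back(cx[k]);
        rec.push_back(cy[k]);
        rec.push_back(ch[k]);
        rec.push_back(occupancy(conc(in_, jn), kd));
        rec.push_back(bufs[k].primed ? bufs[k].mean() : 0.0);
        rec.push_back(dv ? 1.0 : 0.0);
      }
      divided_since_record.clear();
    }
  }

  // --- repack ---
  int n_end = (int)id.size();
  NumericMatrix cells_out(n_end, 4);
  NumericMatrix buf_out(W, n_end);
  IntegerVector pos_out(n_end);
  LogicalVector primed_out(n_end);
  for (int k = 0; k < n_end; ++k) {
    cells_out(k, 0) = id[k]; cells_out(k, 1) = cx[k];
    cells_out(k, 2) = cy[k]; cells_out(k, 3) = ch[k];
    for (int w = 0; w < W; ++w) buf_out(w, k) = bufs[k].buf[w];
    pos_out[k] = bufs[k].pos;
    primed_out[k] = bufs[k].primed;
  }
  int nrec = (int)(rec.size() / 8);
  NumericMatrix traj(nrec, 8);
  for (int r = 0; r < nrec; ++r)
    for (int c = 0; c < 8; ++c) traj(r, c) = rec[r * 8 + c];
  int ndiv = (int)(div_rec.size() / 3);
  NumericMatrix divs(ndiv, 3);
  for (int r = 0; r < ndiv; ++r)
    for (int c = 0; c < 3; ++c) divs(r, c) = div_rec[r * 3 + c];

  return List::create(
      _["conc"] = conc, _["prev"] = prev, _["dx"] = dx, _["D"] = D,
      _["fixed_idx"] = fixed_idx, _["fixed_vals"] = fixed_vals,
      _["cumulative_degraded"] = cumdeg, _["clamped_mass"] = clamped_mass,
      _["time"] = t, _["tick"] = tick0 + n_ticks, _["next_id"] = next_id,
      _["cells"] = cells_out, _["occ_buf"] = buf_out, _["buf_pos"] = pos_out,
      _["buf_primed"] = primed_out, _["traj"] = traj, _["divisions"] = divs);
}
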