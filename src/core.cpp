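#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Bilinear warp of an H x W x C image by a pull transform M (3x3, row-major
// semantics: (r_src, c_src, 1)^T = M %*% (r_out, c_out, 1)^T, 0-based pixel
// centres). Exact integer source coordinates are snapped so that pure
// integer translations degenerate to exact pixel shifts.
// ---------------------------------------------------------------------------

static inline void snap_frac(double x, int &i0, double &f) {
  double fi = std::floor(x);
  i0 = (int)fi;
  f = x - fi;
  if (f < 1e-9) { f = 0.0; }
  else if (f > 1.0 - 1e-9) { i0 += 1; f = 0.0; }
}

// [[Rcpp::export]]
NumericVector cpp_warp_bilinear(NumericVector img, IntegerVector dims,
                                NumericMatrix M, int outH, int outW,
                                NumericVector bg) {
  int H = dims[0], W = dims[1], C = dims[2];
  NumericVector out(Dimension(outH, outW, C));
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2);
  for (int c = 0; c < outW; ++c) {
    for (int r = 0; r < outH; ++r) {
      double sr = m00 * r + m01 * c + m02;
      double sc = m10 * r + m11 * c + m12;
      int r0, c0; double fr, fc;
      snap_frac(sr, r0, fr);
      snap_frac(sc, c0, fc);
      bool r_in = (r0 >= 0 && (fr == 0.0 ? r0 <= H - 1 : r0 + 1 <= H - 1));
      bool c_in = (c0 >= 0 && (fc == 0.0 ? c0 <= W - 1 : c0 + 1 <= W - 1));
      for (int ch = 0; ch < C; ++ch) {
        double val;
        if (!r_in || !c_in) {
          val = bg[ch];
        } else {
          const double *plane = &img[(R_xlen_t)ch * H * W];
          int r1 = (fr == 0.0) ? r0 : r0 + 1;
          int c1 = (fc == 0.0) ? c0 : c0 + 1;
          double v00 = plane[r0 + (R_xlen_t)c0 * H];
          double v01 = plane[r0 + (R_xlen_t)c1 * H];
          double v10 = plane[r1 + (R_xlen_t)c0 * H];
          double v11 = plane[r1 + (R_xlen_t)c1 * H];
          val = (1 - fr) * ((1 - fc) * v00 + fc * v01) +
                fr       * ((1 - fc) * v10 + fc * v11);
        }
        out[r + (R_xlen_t)c * outH + (R_xlen_t)ch * outH * outW] = val;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Distance-field outline match score, batched over candidate transforms.
// Each transform is a row-major 3x3 pull matrix (reference -> source pixel
// coordinates). Forward term: template outline points (reference frame)
// mapped into the source frame, sampled on the source-outline distance map.
// Backward term: source outline points mapped through the inverse into the
// reference frame, sampled on the template-outline distance map. Distances
// saturate at dsat; score = 1 - mean(saturated)/dsat averaged over the two
// directions. Degenerate transforms score 0.
// ---------------------------------------------------------------------------

static inline double sample_dt(const double *dt, int H, int W, double r,
                               double c, double dsat) {
  if (r < 0 || c < 0 || r > H - 1 || c > W - 1) return dsat;
  int r0 = (int)r, c0 = (int)c;
  if (r0 > H - 2) r0 = H - 2;
  if (c0 > W - 2) c0 = W - 2;
  double fr = r - r0, fc = c - c0;
  const double *col0 = dt + (R_xlen_t)c0 * H + r0;
  const double *col1 = col0 + H;
  double v = (1 - fr) * ((1 - fc) * col0[0] + fc * col1[0]) +
             fr       * ((1 - fc) * col0[1] + fc * col1[1]);
  return v > dsat ? dsat : v;
}

// [[Rcpp::export]]
NumericVector cpp_score_dtf_batch(NumericMatrix transforms,
                                  NumericMatrix dt_src, NumericMatrix dt_tpl,
                                  NumericMatrix pts_tpl, NumericMatrix pts_src,
                                  double dsat, double upsample) {
  int nT = transforms.nrow();
  int nPt = pts_tpl.nrow(), nPs = pts_src.nrow();
  NumericVector scores(nT);
  const double *T = &transforms[0];
  const double *ds = &dt_src[0], *dtp = &dt_tpl[0];
  int Hs = dt_src.nrow(), Ws = dt_src.ncol();
  int Ht = dt_tpl.nrow(), Wt = dt_tpl.ncol();
  const double *ptr_r = &pts_tpl[0], *ptr_c = ptr_r + nPt;
  const double *psr_r = &pts_src[0], *psr_c = psr_r + nPs;
  for (int k = 0; k < nT; ++k) {
    double a = T[k], b = T[k + nT], tr = T[k + 2 * (R_xlen_t)nT];
    double d = T[k + 3 * (R_xlen_t)nT], e = T[k + 4 * (R_xlen_t)nT],
           tc = T[k + 5 * (R_xlen_t)nT];
    double det = a * e - b * d;
    bool ok = R_finite(a) && R_finite(b) && R_finite(d) && R_finite(e) &&
              R_finite(tr) && R_finite(tc) && std::fabs(det) > 1e-12;
    if (!ok) { scores[k] = 0.0; continue; }
    double acc_f = 0.0;
    for (int i = 0; i < nPt; ++i) {
      double r = ptr_r[i], c = ptr_c[i];
      acc_f += sample_dt(ds, Hs, Ws, (a * r + b * c + tr) * upsample,
                         (d * r + e * c + tc) * upsample, dsat);
    }
    // inverse of the affine part
    double ia = e / det, ib = -b / det, id = -d / det, ie = a / det;
    double itr = -(ia * tr + ib * tc), itc = -(id * tr + ie * tc);
    double acc_b = 0.0;
    for (int i = 0; i < nPs; ++i) {
      double r = psr_r[i], c = psr_c[i];
      acc_b += sample_dt(dtp, Ht, Wt, (ia * r + ib * c + itr) * upsample,
                         (id * r + ie * c + itc) * upsample, dsat);
    }
    double m = 0.5 * (acc_f / nPt + acc_b / nPs) / dsat;
    scores[k] = 1.0 - m;
  }
  return scores;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a scalar volume (nx, ny, nz), Kuhn 6-tetrahedra
// decomposition of each cell. Produces a level-set surface with shared,
// linearly interpolated edge vertices; faces oriented outward (from values
// above the level toward values below).
// ---------------------------------------------------------------------------

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int edge_point(MTState &st, const double *vol, int nx, int ny, int nz,
                      int64_t g1, int64_t g2, double level,
                      const double *sp, const double *orig) {
  if (g1 > g2) std::swap(g1, g2);
  uint64_t key = ((uint64_t)g1 << 32) | (uint64_t)g2;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double v1 = vol[g1], v2 = vol[g2];
  double t = (level - v1) / (v2 - v1);
  int64_t nxy = (int64_t)nx * ny;
  int i1 = g1 % nx, j1 = (g1 / nx) % ny, k1 = g1 / nxy;
  int i2 = g2 % nx, j2 = (g2 / nx) % ny, k2 = g2 / nxy;
  double x = orig[0] + sp[0] * (i1 + t * (i2 - i1));
  double y = orig[1] + sp[1] * (j1 + t * (j2 - j1));
  double z = orig[2] + sp[2] * (k1 + t * (k2 - k1));
  int id = (int)st.vx.size();
  st.vx.push_back(x); st.vy.push_back(y); st.vz.push_back(z);
  st.edge_vertex[key] = id;
  return id;
}

static void emit_tri(MTState &st, int a, int b, int c,
                     const double *in_cen, const double *out_cen) {
  double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
  double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
  double wx = st.vx[c] - ax, wy = st.vy[c] - ay, wz = st.vz[c] - az;
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  double dx = out_cen[0] - in_cen[0], dy = out_cen[1] - in_cen[1],
         dz = out_cen[2] - in_cen[2];
  if (nx * dx + ny * dy + nz * dz < 0) std::swap(b, c);
  st.f0.push_back(a); st.f1.push_back(b); st.f2.push_back(c);
}

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector vol, IntegerVector dims,
                             double level, NumericVector spacing,
                             NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = &vol[0];
  const double *sp = &spacing[0], *orig = &origin[0];
  MTState st;
  // six Kuhn tetrahedra: cube corner bit order (x, y, z)
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  int64_t nxy = (int64_t)nx * ny;
  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        int64_t base = i + (int64_t)j * nx + (int64_t)k * nxy;
        int64_t corner[8];
        double val[8];
        bool any_in = false, any_out = false;
        for (int b = 0; b < 8; ++b) {
          corner[b] = base + (b & 1) + (int64_t)((b >> 1) & 1) * nx +
                      (int64_t)((b >> 2) & 1) * nxy;
          val[b] = v[corner[b]];
          if (val[b] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int ti[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int ins[4], outs[4]; int ni = 0, no = 0;
          for (int q = 0; q < 4; ++q) {
            if (val[ti[q]] > level) ins[ni++] = ti[q];
            else outs[no++] = ti[q];
          }
          if (ni == 0 || ni == 4) continue;
          double icen[3] = {0, 0, 0}, ocen[3] = {0, 0, 0};
          for (int q = 0; q < ni; ++q) {
            icen[0] += orig[0] + sp[0] * (i + (ins[q] & 1));
            icen[1] += orig[1] + sp[1] * (j + ((ins[q] >> 1) & 1));
            icen[2] += orig[2] + sp[2] * (k + ((ins[q] >> 2) & 1));
          }
          for (int q = 0; q < no; ++q) {
            ocen[0] += orig[0] + sp[0] * (i + (outs[q] & 1));
            ocen[1] += orig[1] + sp[1] * (j + ((outs[q] >> 1) & 1));
            ocen[2] += orig[2] + sp[2] * (k + ((outs[q] >> 2) & 1));
          }
          for (int q = 0; q < 3; ++q) { icen[q] /= ni; ocen[q] /= no; }
          // edge helper over local corner bits -> global linear indices
          auto ep = [&](int b1, int b2) {
            int64_t g1 = base + (b1 & 1) + (int64_t)((b1 >> 1) & 1) * nx +
                         (int64_t)((b1 >> 2) & 1) * nxy;
            int64_t g2 = base + (b2 & 1) + (int64_t)((b2 >> 1) & 1) * nx +
                         (int64_t)((b2 >> 2) & 1) * nxy;
            return edge_point(st, v, nx, ny, nz, g1, g2, level, sp, orig);
          };
          if (ni == 1) {
            int a = ep(ins[0], outs[0]);
            int b = ep(ins[0], outs[1]);
            int c = ep(ins[0], outs[2]);
            emit_tri(st, a, b, c, icen, ocen);
          } else if (ni == 3) {
            int a = ep(outs[0], ins[0]);
            int b = ep(outs[0], ins[1]);
            int c = ep(outs[0], ins[2]);
            emit_tri(st, a, b, c, icen, ocen);
          } else { // ni == 2
            int a = ep(ins[0], outs[0]);
            int b = ep(ins[0], outs[1]);
            int c = ep(ins[1], outs[1]);
            int d = ep(ins[1], outs[0]);
            emit_tri(st, a, b, c, icen, ocen);
            emit_tri(st, a, c, d, icen, ocen);
          }
        }
      }
    }
  }
  int nV = (int)st.vx.size(), nF = (int)st.f0.size();
  NumericMatrix V(nV, 3);
  IntegerMatrix F(nF, 3);
  for (int q = 0; q < nV; ++q) {
    V(q, 0) = st.vx[q]; V(q, 1) = st.vy[q]; V(q, 2) = st.vz[q];
  }
  for (int q = 0; q < nF; ++q) {
    F(q, 0) = st.f0[q] + 1; F(q, 1) = st.f1[q] + 1; F(q, 2) = st.f2[q] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Exact point-to-triangle distance (closest-point-on-triangle, Ericson) and
// a uniform-grid accelerated point-to-mesh query.
// ---------------------------------------------------------------------------

static inline double tri_dist2(const double p[3], const double a[3],
                               const double b[3], const double c[3]) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double cp[3];
  if (d1 <= 0 && d2 <= 0) { cp[0] = a[0]; cp[1] = a[1]; cp[2] = a[2]; goto done; }
  {
    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0 && d4 <= d3) { cp[0] = b[0]; cp[1] = b[1]; cp[2] = b[2]; goto done; }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double t = d1 / (d1 - d3);
      for (int q = 0; q < 3; ++q) cp[q] = a[q] + t * ab[q];
      goto done;
    }
    double cpv[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
    double d5 = ab[0] * cpv[0] + ab[1] * cpv[1] + ab[2] * cpv[2];
    double d6 = ac[0] * cpv[0] + ac[1] * cpv[1] + ac[2] * cpv[2];
    if (d6 >= 0 && d5 <= d6) { cp[0] = c[0]; cp[1] = c[1]; cp[2] = c[2]; goto done; }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double t = d2 / (d2 - d6);
      for (int q = 0; q < 3; ++q) cp[q] = a[q] + t * ac[q];
      goto done;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int q = 0; q < 3; ++q) cp[q] = b[q] + t * (c[q] - b[q]);
      goto done;
    }
    {
      double denom = 1.0 / (va + vb + vc);
      double vv = vb * denom, ww = vc * denom;
      for (int q = 0; q < 3; ++q) cp[q] = a[q] + ab[q] * vv + ac[q] * ww;
    }
  }
done:
  double dx = p[0] - cp[0], dy = p[1] - cp[1], dz = p[2] - cp[2];
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix P, NumericMatrix V,
                                  IntegerMatrix F) {
  int nP = P.nrow(), nF = F.nrow();
  NumericVector out(nP);
  // bounding box of vertices
  double lo[3], hi[3];
  for (int q = 0; q < 3; ++q) { lo[q] = R_PosInf; hi[q] = R_NegInf; }
  for (int i = 0; i < V.nrow(); ++i)
    for (int q = 0; q < 3; ++q) {
      if (V(i, q) < lo[q]) lo[q] = V(i, q);
      if (V(i, q) > hi[q]) hi[q] = V(i, q);
    }
  int ncell = (int)std::cbrt((double)nF);
  if (ncell < 1) ncell = 1;
  if (ncell > 64) ncell = 64;
  double cell[3];
  for (int q = 0; q < 3; ++q) {
    double span = hi[q] - lo[q];
    if (span <= 0) span = 1e-12;
    cell[q] = span / ncell * (1.0 + 1e-12);
  }
  // bin triangles by AABB
  std::vector<std::vector<int>> bins((size_t)ncell * ncell * ncell);
  for (int f = 0; f < nF; ++f) {
    double tlo[3], thi[3];
    for (int q = 0; q < 3; ++q) { tlo[q] = R_PosInf; thi[q] = R_NegInf; }
    for (int s = 0; s < 3; ++s) {
      int vi = F(f, s) - 1;
      for (int q = 0; q < 3; ++q) {
        double val = V(vi, q);
        if (val < tlo[q]) tlo[q] = val;
        if (val > thi[q]) thi[q] = val;
      }
    }
    int i0[3], i1[3];
    for (int q = 0; q < 3; ++q) {
      i0[q] = (int)std::floor((tlo[q] - lo[q]) / cell[q]);
      i1[q] = (int)std::floor((thi[q] - lo[q]) / cell[q]);
      if (i0[q] < 0) i0[q] = 0;
      if (i1[q] > ncell - 1) i1[q] = ncell - 1;
    }
    for (int z = i0[2]; z <= i1[2]; ++z)
      for (int y = i0[1]; y <= i1[1]; ++y)
        for (int x = i0[0]; x <= i1[0]; ++x)
          bins[(size_t)x + (size_t)ncell * (y + (size_t)ncell * z)].push_back(f);
  }
  std::vector<int> stamp((size_t)nF, -1);
  for (int ip = 0; ip < nP; ++ip) {
    double p[3] = {P(ip, 0), P(ip, 1), P(ip, 2)};
    int pc[3];
    for (int q = 0; q < 3; ++q) {
      pc[q] = (int)std::floor((p[q] - lo[q]) / cell[q]);
      if (pc[q] < 0) pc[q] = 0;
      if (pc[q] > ncell - 1) pc[q] = ncell - 1;
    }
    double best = R_PosInf;
    for (int r = 0; r < ncell + 1; ++r) {
      double shell_min = R_PosInf;
      bool any_cell = false;
      for (int dz = -r; dz <= r; ++dz) {
        int z = pc[2] + dz;
        if (z < 0 || z >= ncell) continue;
        for (int dy = -r; dy <= r; ++dy) {
          int y = pc[1] + dy;
          if (y < 0 || y >= ncell) continue;
          for (int dx = -r; dx <= r; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;
            int x = pc[0] + dx;
            if (x < 0 || x >= ncell) continue;
            any_cell = true;
            // exact distance from p to this cell's AABB
            double d2cell = 0;
            int idx3[3] = {x, y, z};
            for (int q = 0; q < 3; ++q) {
              double clo = lo[q] + idx3[q] * cell[q];
              double chi = clo + cell[q];
              double d = (p[q] < clo) ? clo - p[q] : (p[q] > chi ? p[q] - chi : 0);
              d2cell += d * d;
            }
            if (d2cell < shell_min) shell_min = d2cell;
            if (d2cell >= best) continue;
            const std::vector<int> &tri = bins[(size_t)x + (size_t)ncell * (y + (size_t)ncell * z)];
            for (size_t s = 0; s < tri.size(); ++s) {
              int f = tri[s];
              if (stamp[f] == ip) continue;
              stamp[f] = ip;
              int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
              double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
              double b[3] = {V(ib, 0), V(ib, 1), V(ib, 2)};
              double cc[3] = {V(ic, 0), V(ic, 1), V(ic, 2)};
              double d2 = tri_dist2(p, a, b, cc);
              if (d2 < best) best = d2;
            }
          }
        }
      }
      if (R_finite(best) && any_cell && shell_min > best && r > 0) break;
      if (!any_cell && r > 0 && R_finite(best)) break;
    }
    out[ip] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear resampling of a scalar volume into an output grid. `M` is a
// 4x4 pull transform mapping output physical coordinates to input physical
// coordinates; voxels falling outside the input grid get `pad`.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector vol, IntegerVector dims,
                                     NumericVector spacing, NumericVector origin,
                                     IntegerVector odims, NumericVector ospacing,
                                     NumericVector oorigin, NumericMatrix M,
                                     double pad, bool clamp_edges = false) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ox = odims[0], oy = odims[1], oz = odims[2];
  NumericVector out(Dimension(ox, oy, oz));
  const double *v = &vol[0];
  int64_t nxy = (int64_t)nx * ny;
  for (int k = 0; k < oz; ++k) {
    double pz = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < oy; ++j) {
      double py = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < ox; ++i) {
        double px = oorigin[0] + i * ospacing[0];
        double qx = M(0,0)*px + M(0,1)*py + M(0,2)*pz + M(0,3);
        double qy = M(1,0)*px + M(1,1)*py + M(1,2)*pz + M(1,3);
        double qz = M(2,0)*px + M(2,1)*py + M(2,2)*pz + M(2,3);
        double fx = (qx - origin[0]) / spacing[0];
        double fy = (qy - origin[1]) / spacing[1];
        double fz = (qz - origin[2]) / spacing[2];
        if (clamp_edges) {
          if (fx < 0) fx = 0; else if (fx > nx - 1) fx = nx - 1;
          if (fy < 0) fy = 0; else if (fy > ny - 1) fy = ny - 1;
          if (fz < 0) fz = 0; else if (fz > nz - 1) fz = nz - 1;
        }
        int x0, y0, z0; double gx, gy, gz;
        snap_frac(fx, x0, gx);
        snap_frac(fy, y0, gy);
        snap_frac(fz, z0, gz);
        bool xin = (x0 >= 0 && (gx == 0.0 ? x0 <= nx - 1 : x0 + 1 <= nx - 1));
        bool yin = (y0 >= 0 && (gy == 0.0 ? y0 <= ny - 1 : y0 + 1 <= ny - 1));
        bool zin = (z0 >= 0 && (gz == 0.0 ? z0 <= nz - 1 : z0 + 1 <= nz - 1));
        double val;
        if (!xin || !yin || !zin) {
          val = pad;
        } else {
          int x1 = gx == 0.0 ? x0 : x0 + 1;
          int y1 = gy == 0.0 ? y0 : y0 + 1;
          int z1 = gz == 0.0 ? z0 : z0 + 1;
          double c00 = (1-gx) * v[x0 + (int64_t)y0*nx + (int64_t)z0*nxy] +
                       gx     * v[x1 + (int64_t)y0*nx + (int64_t)z0*nxy];
          double c10 = (1-gx) * v[x0 + (int64_t)y1*nx + (int64_t)z0*nxy] +
                       gx     * v[x1 + (int64_t)y1*nx + (int64_t)z0*nxy];
          double c01 = (1-gx) * v[x0 + (int64_t)y0*nx + (int64_t)z1*nxy] +
                       gx     * v[x1 + (int64_t)y0*nx + (int64_t)z1*nxy];
          double c11 = (1-gx) * v[x0 + (int64_t)y1*nx + (int64_t)z1*nxy] +
                       gx     * v[x1 + (int64_t)y1*nx + (int64_t)z1*nxy];
          val = (1-gz) * ((1-gy) * c00 + gy * c10) +
                gz     * ((1-gy) * c01 + gy * c11);
        }
        out[i + (R_xlen_t)j * ox + (R_xlen_t)k * ox * oy] = val;
      }
    }
  }
  return out;
}
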