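// Low-level image kernels: connected components, region adjacency,
// tube rasterization, block matching, weighted grid Dijkstra, multi-source
// geodesic distance, bilinear resampling. All scan orders are fixed so that
// outputs are deterministic.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Label connected components of mask > 0 (4- or 8-connectivity).
// Labels assigned in column-major scan order, starting at 1.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(const IntegerMatrix& mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int cur = 0;
  int ndirs = (connectivity == 8) ? 8 : 4;
  int dr4[4] = {-1, 1, 0, 0};
  int dc4[4] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) > 0 && lab(r, c) == 0) {
        ++cur;
        stack.clear();
        stack.push_back(r + c * nr);
        lab(r, c) = cur;
        while (!stack.empty()) {
          int idx = stack.back(); stack.pop_back();
          int rr = idx % nr, cc = idx / nr;
          for (int d = 0; d < ndirs; ++d) {
            int r2, c2;
            if (connectivity == 8) { r2 = rr + DR8[d]; c2 = cc + DC8[d]; }
            else { r2 = rr + dr4[d]; c2 = cc + dc4[d]; }
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) > 0 && lab(r2, c2) == 0 &&
                mask(r2, c2) == mask(rr, cc)) {
              lab(r2, c2) = cur;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Unique ordered pairs (a, b), a != b, of 4-adjacent values in a vertex-id
// image (0 = background). Each unordered pair returned once with a < b.
// [[Rcpp::export]]
IntegerMatrix adjacency_pairs_cpp(const IntegerMatrix& vid) {
  int nr = vid.nrow(), nc = vid.ncol();
  std::set<std::pair<int,int> > pairs;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int a = vid(r, c);
      if (a == 0) continue;
      if (r + 1 < nr) {
        int b = vid(r + 1, c);
        if (b != 0 && b != a)
          pairs.insert(std::make_pair(std::min(a,b), std::max(a,b)));
      }
      if (c + 1 < nc) {
        int b = vid(r, c + 1);
        if (b != 0 && b != a)
          pairs.insert(std::make_pair(std::min(a,b), std::max(a,b)));
      }
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  int i = 0;
  for (std::set<std::pair<int,int> >::iterator it = pairs.begin();
       it != pairs.end(); ++it, ++i) {
    out(i, 0) = it->first;
    out(i, 1) = it->second;
  }
  return out;
}

// Rasterize timed polylines into two images:
//  dist: min distance of each pixel to any polyline sample (Inf if > radius)
//  time: earliest sample time whose disc of `radius` covers the pixel
// Polylines are Nx3 matrices (col x, row y, t) in 1-based pixel coords.
// [[Rcpp::export]]
List rasterize_polylines_cpp(List polylines, int nrow, int ncol,
                             double radius, double step) {
  NumericMatrix dist(nrow, ncol), tim(nrow, ncol);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  std::fill(tim.begin(), tim.end(), R_PosInf);
  int np = polylines.size();
  for (int p = 0; p < np; ++p) {
    NumericMatrix pl = polylines[p];
    int n = pl.nrow();
    for (int i = 0; i + 1 < n; ++i) {
      double x0 = pl(i, 0), y0 = pl(i, 1), t0 = pl(i, 2);
      double x1 = pl(i+1, 0), y1 = pl(i+1, 1), t1 = pl(i+1, 2);
      double len = std::sqrt((x1-x0)*(x1-x0) + (y1-y0)*(y1-y0));
      int ns = std::max(1, (int)std::ceil(len / step));
      for (int s = 0; s <= ns; ++s) {
        double f = (double)s / ns;
        double x = x0 + f * (x1 - x0);
        double y = y0 + f * (y1 - y0);
        double t = t0 + f * (t1 - t0);
        int rlo = std::max(0, (int)std::floor(y - 1 - radius));
        int rhi = std::min(nrow - 1, (int)std::ceil(y - 1 + radius));
        int clo = std::max(0, (int)std::floor(x - 1 - radius));
        int chi = std::min(ncol - 1, (int)std::ceil(x - 1 + radius));
        for (int cc = clo; cc <= chi; ++cc) {
          for (int rr = rlo; rr <= rhi; ++rr) {
            double dx = (cc + 1) - x, dy = (rr + 1) - y;
            double d = std::sqrt(dx*dx + dy*dy);
            if (d <= radius) {
              if (d < dist(rr, cc)) dist(rr, cc) = d;
              if (t < tim(rr, cc)) tim(rr, cc) = t;
            }
          }
        }
      }
    }
    // degenerate single-node polyline
    if (n == 1) {
      double x = pl(0,0), y = pl(0,1), t = pl(0,2);
      int rlo = std::max(0, (int)std::floor(y - 1 - radius));
      int rhi = std::min(nrow - 1, (int)std::ceil(y - 1 + radius));
      int clo = std::max(0, (int)std::floor(x - 1 - radius));
      int chi = std::min(ncol - 1, (int)std::ceil(x - 1 + radius));
      for (int cc = clo; cc <= chi; ++cc)
        for (int rr = rlo; rr <= rhi; ++rr) {
          double dx = (cc + 1) - x, dy = (rr + 1) - y;
          double d = std::sqrt(dx*dx + dy*dy);
          if (d <= radius) {
            if (d < dist(rr, cc)) dist(rr, cc) = d;
            if (t < tim(rr, cc)) tim(rr, cc) = t;
          }
        }
    }
  }
  return List::create(_["dist"] = dist, _["time"] = tim);
}

static void block_tensor(const NumericMatrix& img, int r0, int c0,
                         int half, double* out) {
  // gradient structure tensor over the block; out = {lmin, lmax, ang}
  // where ang is the orientation of the dominant gradient (edge normal)
  double gxx = 0, gyy = 0, gxy = 0;
  for (int dc = -half + 1; dc <= half - 1; ++dc) {
    for (int dr = -half + 1; dr <= half - 1; ++dr) {
      double gx = 0.5 * (img(r0 + dr, c0 + dc + 1) -
                         img(r0 + dr, c0 + dc - 1));
      double gy = 0.5 * (img(r0 + dr + 1, c0 + dc) -
                         img(r0 + dr - 1, c0 + dc));
      gxx += gx * gx; gyy += gy * gy; gxy += gx * gy;
    }
  }
  double tr = gxx + gyy;
  double det = std::sqrt((gxx - gyy) * (gxx - gyy) + 4.0 * gxy * gxy);
  out[0] = 0.5 * (tr - det);
  out[1] = 0.5 * (tr + det);
  out[2] = 0.5 * std::atan2(2.0 * gxy, gxx - gyy);
}

// Structure-tensor maximum eigenvalue for every block on the matching
// grid (same grid as block_match_cpp with the given margin terms);
// low values mean a flat (textureless) block.
// [[Rcpp::export]]
NumericVector block_feature_cpp(const NumericMatrix& fixed, int half,
                                int stride, int search) {
  int nr = fixed.nrow(), nc = fixed.ncol();
  int margin = half + search + 1;
  std::vector<double> vals;
  for (int cc = margin; cc < nc - margin; cc += stride)
    for (int rr = margin; rr < nr - margin; rr += stride) {
      double t[3];
      block_tensor(fixed, rr, cc, half, t);
      vals.push_back(t[1]);
    }
  return wrap(vals);
}

static double block_ncc(const NumericMatrix& fixed, const NumericMatrix& moving,
                        int fr, int fc, int mr, int mc, int half) {
  // NCC of the (2*half+1)^2 blocks centered at (fr,fc) in fixed and (mr,mc)
  // in moving; caller guarantees in-bounds.
  double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  int n = 0;
  for (int dc = -half; dc <= half; ++dc) {
    for (int dr = -half; dr <= half; ++dr) {
      double f = fixed(fr + dr, fc + dc);
      double m = moving(mr + dr, mc + dc);
      sf += f; sm += m; sff += f*f; smm += m*m; sfm += f*m;
      ++n;
    }
  }
  double vf = sff - sf*sf/n, vm = smm - sm*sm/n;
  if (vf <= 1e-12 || vm <= 1e-12) return -2.0;
  return (sfm - sf*sm/n) / std::sqrt(vf * vm);
}

// Block matching between fixed and moving. For each block (center on a
// stride grid in fixed) with variance >= min_var, find the displacement
// d in [-search, search]^2 maximizing NCC(fixed block, moving block at
// center+d), coarse-to-fine with parabolic sub-pixel refinement.
// Returns rows (cx, cy, dx, dy, ncc) in 1-based pixel coords, where the
// backward map fixed->moving at (cx, cy) is (cx+dx, cy+dy).
// [[Rcpp::export]]
NumericMatrix block_match_cpp(const NumericMatrix& moving,
                              const NumericMatrix& fixed,
                              int half, int stride, int search,
                              double min_var, int coarse) {
  int nr = fixed.nrow(), nc = fixed.ncol();
  std::vector<double> rows;
  int margin = half + search + 1;
  for (int cc = margin; cc < nc - margin; cc += stride) {
    for (int rr = margin; rr < nr - margin; rr += stride) {
      // structure filter: drop flat blocks (1-D blocks are kept and
      // classified by the caller through the tensor columns)
      double tens[3];
      block_tensor(fixed, rr, cc, half, tens);
      if (tens[1] < min_var) continue;
      // coarse search
      int bdr = 0, bdc = 0; double best = -2.0;
      for (int dc = -search; dc <= search; dc += coarse)
        for (int dr = -search; dr <= search; dr += coarse) {
          double v = block_ncc(fixed, moving, rr, cc, rr + dr, cc + dc, half);
          if (v > best) { best = v; bdr = dr; bdc = dc; }
        }
      // fine search around coarse best
      int fdr = bdr, fdc = bdc; best = -2.0;
      int rad = coarse;
      // store fine NCC values for sub-pixel fit
      std::vector<double> vals((2*rad+1)*(2*rad+1), -2.0);
      for (int dc = -rad; dc <= rad; ++dc)
        for (int dr = -rad; dr <= rad; ++dr) {
          int ddr = bdr + dr, ddc = bdc + dc;
          if (std::abs(ddr) > search || std::abs(ddc) > search) continue;
          double v = block_ncc(fixed, moving, rr, cc, rr + ddr, cc + ddc, half);
          vals[(dr+rad) + (dc+rad)*(2*rad+1)] = v;
          if (v > best) { best = v; fdr = ddr; fdc = ddc; }
        }
      if (best <= -1.5) continue;
      // parabolic sub-pixel refinement using neighbors of the fine best
      double sdr = 0, sdc = 0;
      int ir = fdr - bdr + rad, ic = fdc - bdc + rad;
      int w = 2*rad + 1;
      if (ir > 0 && ir < w - 1) {
        double cm = vals[(ir-1) + ic*w], c0 = vals[ir + ic*w],
               cp = vals[(ir+1) + ic*w];
        double den = cm - 2*c0 + cp;
        if (cm > -1.5 && cp > -1.5 && std::fabs(den) > 1e-12) {
          double off = 0.5 * (cm - cp) / den;
          if (std::fabs(off) <= 1.0) sdr = off;
        }
      }
      if (ic > 0 && ic < w - 1) {
        double cm = vals[ir + (ic-1)*w], c0 = vals[ir + ic*w],
               cp = vals[ir + (ic+1)*w];
        double den = cm - 2*c0 + cp;
        if (cm > -1.5 && cp > -1.5 && std::fabs(den) > 1e-12) {
          double off = 0.5 * (cm - cp) / den;
          if (std::fabs(off) <= 1.0) sdc = off;
        }
      }
      rows.push_back(cc + 1);            // cx
      rows.push_back(rr + 1);            // cy
      rows.push_back(fdc + sdc);         // dx
      rows.push_back(fdr + sdr);         // dy
      rows.push_back(best);              // ncc
      rows.push_back(tens[0]);           // lmin
      rows.push_back(tens[1]);           // lmax
      rows.push_back(tens[2]);           // dominant gradient angle
    }
  }
  int nrows = rows.size() / 8;
  NumericMatrix out(nrows, 8);
  for (int i = 0; i < nrows; ++i)
    for (int j = 0; j < 8; ++j) out(i, j) = rows[i*8 + j];
  colnames(out) = CharacterVector::create("cx", "cy", "dx", "dy", "ncc",
                                          "lmin", "lmax", "gang");
  return out;
}

struct QNode {
  double d; int idx;
  bool operator<(const QNode& o) const {
    if (d != o.d) return d > o.d;       // min-heap with deterministic ties
    return idx > o.idx;
  }
};

// Shortest 8-connected pixel path inside mask from (sr, sc) to targets.
// Node weights w; step cost = euclidean * f(w_a, w_b) with
// mode 0: f = 1 / (1 + min(w_a, w_b))   (distance-map centerline weighting)
// mode 1: f = (w_a + w_b) / 2           (intensity-weighted traversal)
// Returns the path (1-based rows, cols) to the first reached target, or a
// 0-row matrix if unreachable.
// [[Rcpp::export]]
IntegerMatrix grid_dijkstra_cpp(const NumericMatrix& w,
                                const IntegerMatrix& mask,
                                int sr, int sc,
                                const IntegerMatrix& targets, int mode) {
  int nr = w.nrow(), nc = w.ncol();
  --sr; --sc;
  std::vector<double> dist((size_t)nr * nc,
                           std::numeric_limits<double>::infinity());
  std::vector<int> prev((size_t)nr * nc, -1);
  std::vector<char> istarget((size_t)nr * nc, 0);
  for (int i = 0; i < targets.nrow(); ++i) {
    int tr = targets(i, 0) - 1, tc = targets(i, 1) - 1;
    if (tr >= 0 && tr < nr && tc >= 0 && tc < nc)
      istarget[tr + (size_t)tc * nr] = 1;
  }
  std::priority_queue<QNode> pq;
  int s = sr + sc * nr;
  dist[s] = 0.0;
  pq.push(QNode{0.0, s});
  int found = -1;
  if (istarget[s]) found = s;
  while (found < 0 && !pq.empty()) {
    QNode top = pq.top(); pq.pop();
    if (top.d > dist[top.idx]) continue;
    int r = top.idx % nr, c = top.idx / nr;
    if (istarget[top.idx]) { found = top.idx; break; }
    double wa = w(r, c);
    for (int d = 0; d < 8; ++d) {
      int r2 = r + DR8[d], c2 = c + DC8[d];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) == 0) continue;
      double wb = w(r2, c2);
      double e = (DR8[d] != 0 && DC8[d] != 0) ? M_SQRT2 : 1.0;
      double f = (mode == 0) ? 1.0 / (1.0 + std::min(wa, wb))
                             : 0.5 * (wa + wb);
      double nd = top.d + e * f;
      int idx2 = r2 + c2 * nr;
      if (nd < dist[idx2]) {
        dist[idx2] = nd;
        prev[idx2] = top.idx;
        pq.push(QNode{nd, idx2});
      }
    }
  }
  if (found < 0) return IntegerMatrix(0, 2);
  std::vector<int> path;
  for (int cur = found; cur >= 0; cur = prev[cur]) path.push_back(cur);
  IntegerMatrix out(path.size(), 2);
  for (size_t i = 0; i < path.size(); ++i) {
    int idx = path[path.size() - 1 - i];
    out(i, 0) = idx % nr + 1;
    out(i, 1) = idx / nr + 1;
  }
  colnames(out) = CharacterVector::create("row", "col");
  return out;
}

// Multi-source geodesic distance inside mask (8-connected, euclidean steps).
// seeds: k x 2 matrix of 1-based (row, col); seed_val: value carried by each
// seed (e.g. a time). Returns dist (Inf where unreachable/outside) and val
// (value of the nearest seed).
// [[Rcpp::export]]
List geodesic_cpp(const IntegerMatrix& mask, const IntegerMatrix& seeds,
                  const NumericVector& seed_val) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix dist(nr, nc), val(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  std::fill(val.begin(), val.end(), NA_REAL);
  std::priority_queue<QNode> pq;
  for (int i = 0; i < seeds.nrow(); ++i) {
    int r = seeds(i, 0) - 1, c = seeds(i, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
    if (dist(r, c) > 0) {
      dist(r, c) = 0.0;
      val(r, c) = seed_val.size() > i ? seed_val[i] : NA_REAL;
      pq.push(QNode{0.0, r + c * nr});
    }
  }
  while (!pq.empty()) {
    QNode top = pq.top(); pq.pop();
    int r = top.idx % nr, c = top.idx / nr;
    if (top.d > dist(r, c)) continue;
    for (int d = 0; d < 8; ++d) {
      int r2 = r + DR8[d], c2 = c + DC8[d];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) == 0) continue;
      double e = (DR8[d] != 0 && DC8[d] != 0) ? M_SQRT2 : 1.0;
      double nd = top.d + e;
      if (nd < dist(r2, c2) - 1e-12) {
        dist(r2, c2) = nd;
        val(r2, c2) = val(r, c);
        pq.push(QNode{nd, r2 + c2 * nr});
      }
    }
  }
  return List::create(_["dist"] = dist, _["val"] = val);
}

// Bilinear sampling of img at (row, col) coordinate maps (same shape as the
// output). Out-of-field samples get `fill`.
// [[Rcpp::export]]
NumericMatrix bilinear_sample_cpp(const NumericMatrix& img,
                                  const NumericMatrix& mapr,
                                  const NumericMatrix& mapc, double fill) {
  int nr = mapr.nrow(), nc = mapr.ncol();
  int inr = img.nrow(), inc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double y = mapr(r, c), x = mapc(r, c);
      if (ISNAN(y) || ISNAN(x) || y < 1 || x < 1 || y > inr || x > inc) {
        out(r, c) = fill;
        continue;
      }
      int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
      if (y0 == inr) y0 = inr - 1;
      if (x0 == inc) x0 = inc - 1;
      double fy = y - y0, fx = x - x0;
      double v00 = img(y0 - 1, x0 - 1);
      double v10 = img(y0, x0 - 1);
      double v01 = img(y0 - 1, x0);
      double v11 = img(y0, x0);
      out(r, c) = v00 * (1 - fy) * (1 - fx) + v10 * fy * (1 - fx) +
                  v01 * (1 - fy) * fx + v11 * fy * fx;
    }
  }
  return out;
}
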