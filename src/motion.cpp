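#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Candidate offsets ordered by (squared norm, dy, dx) so that keeping the
// first strictly-better MAD implements the documented tie-break: smallest
// Euclidean norm first, then lexicographic (dy, dx).
struct Cand { int dy, dx; };

static std::vector<Cand> candidate_order(int w) {
  std::vector<Cand> cands;
  cands.reserve((2 * w + 1) * (2 * w + 1));
  for (int dy = -w; dy <= w; ++dy)
    for (int dx = -w; dx <= w; ++dx)
      cands.push_back({dy, dx});
  std::stable_sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
    int na = a.dy * a.dy + a.dx * a.dx, nb = b.dy * b.dy + b.dx * b.dx;
    if (na != nb) return na < nb;
    if (a.dy != b.dy) return a.dy < b.dy;
    return a.dx < b.dx;
  });
  return cands;
}

// Exhaustive MAD block matching for every consecutive frame pair.
// frames: H x W x T array (column-major). Displacement (dx, dy) means the
// block content at (row, col) in frame k is found at (row+dy, col+dx) in
// frame k+1. Candidates that would push the block outside the frame are
// excluded; low-texture blocks (sample SD < min_std in frame k) are invalid.
// [[Rcpp::export]]
List compute_fields_cpp(NumericVector frames, int N, int w, double min_std) {
  IntegerVector dim = frames.attr("dim");
  const int H = dim[0], W = dim[1], T = dim[2];
  const int gy = H / N, gx = W / N;
  const double *fr = REAL(frames);
  const R_xlen_t HW = (R_xlen_t)H * W;
  const int N2 = N * N;
  std::vector<Cand> cands = candidate_order(w);

  List out(T - 1);
  for (int k = 0; k < T - 1; ++k) {
    const double *fk = fr + (R_xlen_t)k * HW;
    const double *fk1 = fk + HW;
    IntegerMatrix DX(gy, gx), DY(gy, gx);
    NumericMatrix SC(gy, gx);
    LogicalMatrix VA(gy, gx);
    for (int j = 0; j < gx; ++j) {
      for (int i = 0; i < gy; ++i) {
        const int by = i * N, bx = j * N;
        // sample SD of the reference block
        double s = 0.0, s2 = 0.0;
        for (int c = 0; c < N; ++c) {
          const double *col = fk + (R_xlen_t)(bx + c) * H + by;
          for (int r = 0; r < N; ++r) {
            s += col[r];
            s2 += col[r] * col[r];
          }
        }
        double var = (s2 - s * s / N2) / (N2 - 1);
        double sdv = var > 0 ? std::sqrt(var) : 0.0;
        bool valid = sdv >= min_std;
        VA(i, j) = valid;
        int best_dy = 0, best_dx = 0;
        double best_sum = R_PosInf;
        for (const Cand &cd : cands) {
          const int ty = by + cd.dy, tx = bx + cd.dx;
          if (ty < 0 || tx < 0 || ty + N > H || tx + N > W) continue;
          double acc = 0.0;
          for (int c = 0; c < N; ++c) {
            const double *ca = fk + (R_xlen_t)(bx + c) * H + by;
            const double *cb = fk1 + (R_xlen_t)(tx + c) * H + ty;
            for (int r = 0; r < N; ++r) acc += std::fabs(ca[r] - cb[r]);
            if (acc > best_sum) break; // early abandon: cannot strictly improve
          }
          if (acc < best_sum) {
            best_sum = acc;
            best_dy = cd.dy;
            best_dx = cd.dx;
          }
        }
        DX(i, j) = best_dx;
        DY(i, j) = best_dy;
        SC(i, j) = best_sum / N2;
      }
    }
    out[k] = List::create(_["frame_pair_index"] = k, _["dx"] = DX, _["dy"] = DY,
                          _["mad"] = SC, _["valid"] = VA);
  }
  return out;
}

// Generate a full synthetic stack in one pass: for each frame, inverse-warp
// the padded texture by d[t]*(ux, uy)*env and add Gaussian pixel noise drawn
// from R's RNG (so the whole stack is reproducible from set.seed()).
// uniform_env short-circuits the per-pixel envelope lookup: the bilinear
// weights are then constant over the frame.
// [[Rcpp::export]]
NumericVector gen_frames_cpp(NumericMatrix tex, NumericMatrix env,
                             NumericVector d, double ux, double uy, int margin,
                             double noise_sd, bool uniform_env) {
  const int H = env.nrow(), W = env.ncol(), T = d.size();
  const int TH = tex.nrow();
  const double *tx = REAL(tex);
  NumericVector out((R_xlen_t)H * W * T);
  out.attr("dim") = IntegerVector::create(H, W, T);
  double *o = REAL(out);
  RNGScope scope;
  for (int t = 0; t < T; ++t) {
    double *frame = o + (R_xlen_t)t * H * W;
    if (uniform_env) {
      double sy = margin - d[t] * uy, sx = margin - d[t] * ux;
      int oy = (int)std::floor(sy), ox = (int)std::floor(sx);
      double fy = sy - oy, fx = sx - ox;
      double w00 = (1 - fy) * (1 - fx), w01 = (1 - fy) * fx;
      double w10 = fy * (1 - fx), w11 = fy * fx;
      for (int c = 0; c < W; ++c) {
        const double *t0 = tx + (R_xlen_t)(c + ox) * TH + oy;
        const double *t1 = t0 + TH;
        double *oc = frame + (R_xlen_t)c * H;
        for (int r = 0; r < H; ++r)
          oc[r] = w00 * t0[r] + w10 * t0[r + 1] + w01 * t1[r] + w11 * t1[r + 1];
      }
    } else {
      for (int c = 0; c < W; ++c) {
        double *oc = frame + (R_xlen_t)c * H;
        for (int r = 0; r < H; ++r) {
          double e = env(r, c);
          double sy = r + margin - d[t] * uy * e;
          double sx = c + margin - d[t] * ux * e;
          int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
          double fy = sy - y0, fx = sx - x0;
          const double *b = tx + (R_xlen_t)x0 * TH + y0;
          oc[r] = (1 - fy) * ((1 - fx) * b[0] + fx * b[TH]) +
                  fy * ((1 - fx) * b[1] + fx * b[TH + 1]);
        }
      }
    }
    if (noise_sd > 0) {
      NumericVector ns = Rcpp::rnorm((R_xlen_t)H * W, 0.0, noise_sd);
      const double *np = REAL(ns);
      for (R_xlen_t i = 0; i < (R_xlen_t)H * W; ++i) frame[i] += np[i];
    }
  }
  return out;
}

// Inverse bilinear warp: output(r, c) samples the padded texture at
// (r + margin - d*uy*E(r,c), c + margin - d*ux*E(r,c)) so that the visible
// content moves by +d*(ux, uy)*E. tex is (H+2*margin) x (W+2*margin).
// [[Rcpp::export]]
NumericMatrix warp_frame_cpp(NumericMatrix tex, NumericMatrix env, double d,
                             double ux, double uy, int margin) {
  const int H = env.nrow(), W = env.ncol();
  const int TH = tex.nrow(), TW = tex.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double e = env(r, c);
      double sy = r + margin - d * uy * e;
      double sx = c + margin - d * ux * e;
      int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
      double fy = sy - y0, fx = sx - x0;
      if (y0 < 0) { y0 = 0; fy = 0.0; }
      if (x0 < 0) { x0 = 0; fx = 0.0; }
      if (y0 >= TH - 1) { y0 = TH - 2; fy = 1.0; }
      if (x0 >= TW - 1) { x0 = TW - 2; fx = 1.0; }
      out(r, c) = (1 - fy) * ((1 - fx) * tex(y0, x0) + fx * tex(y0, x0 + 1)) +
                  fy * ((1 - fx) * tex(y0 + 1, x0) + fx * tex(y0 + 1, x0 + 1));
    }
  }
  return out;
}
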