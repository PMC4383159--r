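#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Conventions shared with the R layer:
//   * pixel (x, y): x = column, y = row, both 0-based;
//   * matrices are stored row-major from R's point of view, i.e. f(y, x);
//   * reads outside the frame use replicate (edge-clamp) padding;
//   * continuous displacements are rounded half-away-from-zero and clamped
//     to [-W, W] before any fitness evaluation.

static inline int iclamp(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double dclamp(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline int iround_away(double v) {
  return (v >= 0.0) ? (int)std::floor(v + 0.5) : (int)std::ceil(v - 0.5);
}

static inline double px_at(const NumericMatrix& f, int x, int y) {
  if (x < 0) x = 0; else if (x >= f.ncol()) x = f.ncol() - 1;
  if (y < 0) y = 0; else if (y >= f.nrow()) y = f.nrow() - 1;
  return f(y, x);
}

// Mean square error over the n x n block centered at (cx, cy): current-frame
// block against the reference-frame block displaced by the integer vector
// (ux, uy).
static double mse_at(const NumericMatrix& cur, const NumericMatrix& ref,
                     int cx, int cy, int ux, int uy, int n) {
  const int hw = n / 2;
  double acc = 0.0;
  for (int dy = -hw; dy <= hw; ++dy) {
    for (int dx = -hw; dx <= hw; ++dx) {
      const double d =
          px_at(cur, cx + dx, cy + dy) - px_at(ref, cx + ux + dx, cy + uy + dy);
      acc += d * d;
    }
  }
  return acc / ((double)n * (double)n);
}

// Smoothness constraint: mean over the available previous-iteration neighbor
// vectors of the squared vector difference; 0 when no neighbor is available.
static double sc_at(int ux, int uy, const double* nbx, const double* nby,
                    int nnb) {
  if (nnb == 0) return 0.0;
  double acc = 0.0;
  for (int i = 0; i < nnb; ++i) {
    const double dx = ux - nbx[i], dy = uy - nby[i];
    acc += dx * dx + dy * dy;
  }
  return acc / (double)nnb;
}

// Fitness evaluator bound to one block center and one neighbor set; every
// call increments the evaluation counter exactly once (the accounting
// surface used for the efficiency comparison).
struct FitEval {
  const NumericMatrix& cur;
  const NumericMatrix& ref;
  int cx, cy, n, W;
  double lambda;
  const double* nbx;
  const double* nby;
  int nnb;
  double* evals;

  double operator()(double posx, double posy) const {
    const int ux = iclamp(iround_away(posx), -W, W);
    const int uy = iclamp(iround_away(posy), -W, W);
    const double m = mse_at(cur, ref, cx, cy, ux, uy, n);
    const double s = sc_at(ux, uy, nbx, nby, nnb);
    *evals += 1.0;
    return 1.0 / (1.0 + m + lambda * s);
  }
};

// Exhaustive scan over all (2W+1)^2 integer displacements; first maximizer
// in row-major (uy outer, ux inner) order from (-W, -W) wins ties.
static void ifsa_scan(const FitEval& fit, int W, double& outx, double& outy,
                      double& outfit) {
  double best = -1.0;
  int bx = 0, by = 0;
  for (int uy = -W; uy <= W; ++uy) {
    for (int ux = -W; ux <= W; ++ux) {
      const double f = fit((double)ux, (double)uy);
      if (f > best) { best = f; bx = ux; by = uy; }
    }
  }
  outx = (double)bx;
  outy = (double)by;
  outfit = best;
}

static inline void record_best(double posx, double posy, double f, int W,
                               double& bestx, double& besty, double& bestfit) {
  if (f > bestfit) {
    bestfit = f;
    bestx = (double)iclamp(iround_away(posx), -W, W);
    besty = (double)iclamp(iround_away(posy), -W, W);
  }
}

// One firefly-swarm sweep for one pixel.  Brightness of every firefly is
// refreshed against the current neighbor field first (m evaluations), the
// brightest firefly performs a greedy random walk, and every dimmer firefly
// moves toward a randomly chosen brighter partner (convex combination plus
// uniform walk in (-0.5, 0.5) per component).  The elite record
// (bestx, besty, bestfit) is monotone non-decreasing in fitness.
static void ifa_sweep(const FitEval& fit, int m, int W, double gamma,
                      double* posx, double* posy, double* br, double& bestx,
                      double& besty, double& bestfit) {
  for (int i = 0; i < m; ++i) {
    br[i] = fit(posx[i], posy[i]);
    record_best(posx[i], posy[i], br[i], W, bestx, besty, bestfit);
  }
  int ibest = 0;
  for (int i = 1; i < m; ++i)
    if (br[i] > br[ibest]) ibest = i;

  for (int i = 0; i < m; ++i) {
    if (i == ibest) {
      // greedy random walk: keep the new position only on strict improvement
      const double wx = R::runif(-0.5, 0.5), wy = R::runif(-0.5, 0.5);
      const double nx = dclamp(posx[i] + wx, -(double)W, (double)W);
      const double ny = dclamp(posy[i] + wy, -(double)W, (double)W);
      const double f = fit(nx, ny);
      if (f > br[i]) {
        posx[i] = nx; posy[i] = ny; br[i] = f;
        record_best(nx, ny, f, W, bestx, besty, bestfit);
      }
    } else if (m > 1) {
      int j = (int)(unif_rand() * (double)(m - 1));
      if (j >= m - 1) j = m - 2;
      if (j >= i) ++j;
      if (br[i] < br[j]) {
        const double dx = posx[i] - posx[j], dy = posy[i] - posy[j];
        const double r = std::sqrt(dx * dx + dy * dy);
        // beta0 = sum of the two brightness values, clamped after decay so
        // the update stays a convex combination
        const double beta = dclamp((br[i] + br[j]) * std::exp(-gamma * r),
                                   0.0, 1.0);
        const double wx = R::runif(-0.5, 0.5), wy = R::runif(-0.5, 0.5);
        const double nx =
            dclamp((1.0 - beta) * posx[i] + beta * posx[j] + wx,
                   -(double)W, (double)W);
        const double ny =
            dclamp((1.0 - beta) * posy[i] + beta * posy[j] + wy,
                   -(double)W, (double)W);
        posx[i] = nx; posy[i] = ny;
        br[i] = fit(nx, ny);
        record_best(nx, ny, br[i], W, bestx, besty, bestfit);
      }
    }
  }
}

// [[Rcpp::export]]
double cpp_block_mse(NumericMatrix cur, NumericMatrix ref, int cx, int cy,
                     double ux, double uy, int n) {
  return mse_at(cur, ref, cx, cy, iround_away(ux), iround_away(uy), n);
}

// [[Rcpp::export]]
List cpp_ifsa_pixel(NumericMatrix cur, NumericMatrix ref, int cx, int cy,
                    NumericVector nbx, NumericVector nby, int n, int W,
                    double lambda) {
  double evals = 0.0;
  FitEval fit{cur, ref, cx, cy, n, W, lambda,
              nbx.begin(), nby.begin(), (int)nbx.size(), &evals};
  double bx, by, bf;
  ifsa_scan(fit, W, bx, by, bf);
  return List::create(_["ux"] = bx, _["uy"] = by, _["fitness"] = bf,
                      _["evaluations"] = evals);
}

// Full l-iteration swarm for a single pixel against a fixed neighbor field.
// `init` optionally fixes the initial firefly positions (m x 2 matrix of
// (ux, uy)); otherwise positions are drawn uniformly on [-W, W]^2 from R's
// random stream (caller seeds).
// [[Rcpp::export]]
List cpp_ifa_pixel(NumericMatrix cur, NumericMatrix ref, int cx, int cy,
                   NumericVector nbx, NumericVector nby, int n, int W,
                   double lambda, double gamma, int m, int l,
                   Nullable<NumericMatrix> init = R_NilValue) {
  double evals = 0.0;
  FitEval fit{cur, ref, cx, cy, n, W, lambda,
              nbx.begin(), nby.begin(), (int)nbx.size(), &evals};
  std::vector<double> posx(m), posy(m), br(m);
  if (init.isNotNull()) {
    NumericMatrix ini(init);
    if (ini.nrow() != m || ini.ncol() != 2)
      stop("`init` must be an m x 2 matrix of initial displacements");
    for (int i = 0; i < m; ++i) {
      posx[i] = dclamp(ini(i, 0), -(double)W, (double)W);
      posy[i] = dclamp(ini(i, 1), -(double)W, (double)W);
    }
  } else {
    for (int i = 0; i < m; ++i) {
      posx[i] = R::runif(-(double)W, (double)W);
      posy[i] = R::runif(-(double)W, (double)W);
    }
  }
  double bestx = 0.0, besty = 0.0, bestfit = -1.0;
  for (int t = 0; t < l; ++t)
    ifa_sweep(fit, m, W, gamma, posx.data(), posy.data(), br.data(), bestx,
              besty, bestfit);
  return List::create(_["ux"] = bestx, _["uy"] = besty,
                      _["fitness"] = bestfit, _["evaluations"] = evals);
}

// Dense field estimation over an ROI.  Each global iteration performs one
// synchronous (Jacobi) sweep: every pixel is updated against the previous
// iteration's field, so update order cannot influence the result.  Random
// draws come from R's stream in a fixed order (field init pixel-major, then
// swarm init pixel-major/firefly-major, then per sweep pixel-major).
//
// method: 0 = exhaustive full search per pixel per sweep (IFSA),
//         1 = firefly swarm, one sweep per pixel per iteration (IFA).
// [[Rcpp::export]]
List cpp_estimate_field(NumericMatrix cur, NumericMatrix ref, int x0, int y0,
                        int w, int h, int n, int W, double lambda,
                        double gamma, int m, int l, int method,
                        bool record_psnr, bool persist_swarms) {
  const int npix = w * h;
  NumericMatrix fx(h, w), fy(h, w);
  // initial field: uniform draws on [-W, W], rounded (Step 1)
  for (int iy = 0; iy < h; ++iy) {
    for (int ix = 0; ix < w; ++ix) {
      fx(iy, ix) = (double)iround_away(R::runif(-(double)W, (double)W));
      fy(iy, ix) = (double)iround_away(R::runif(-(double)W, (double)W));
    }
  }

  std::vector<double> posx, posy, br, bestx, besty, bestfit;
  if (method == 1) {
    posx.resize((size_t)npix * m);
    posy.resize((size_t)npix * m);
    br.resize((size_t)npix * m);
    bestx.assign(npix, 0.0);
    besty.assign(npix, 0.0);
    bestfit.assign(npix, -1.0);
    for (int p = 0; p < npix; ++p) {
      for (int i = 0; i < m; ++i) {
        posx[(size_t)p * m + i] = R::runif(-(double)W, (double)W);
        posy[(size_t)p * m + i] = R::runif(-(double)W, (double)W);
      }
    }
  }

  double evals = 0.0;
  NumericMatrix fitmat(h, w);
  NumericVector psnr_trace(record_psnr ? l : 0);
  double nbx[8], nby[8];

  for (int t = 1; t <= l; ++t) {
    NumericMatrix nfx(h, w), nfy(h, w);
    for (int iy = 0; iy < h; ++iy) {
      for (int ix = 0; ix < w; ++ix) {
        int nnb = 0;
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0) continue;
            const int nx = ix + dx, ny = iy + dy;
            if (nx < 0 || nx >= w || ny < 0 || ny >= h) continue;
            nbx[nnb] = fx(ny, nx);
            nby[nnb] = fy(ny, nx);
            ++nnb;
          }
        }
        FitEval fit{cur, ref, x0 + ix, y0 + iy, n, W, lambda,
                    nbx, nby, nnb, &evals};
        if (method == 0) {
          double bx, by, bf;
          ifsa_scan(fit, W, bx, by, bf);
          nfx(iy, ix) = bx;
          nfy(iy, ix) = by;
          fitmat(iy, ix) = bf;
        } else {
          const int p = iy * w + ix;
          double* px_ = &posx[(size_t)p * m];
          double* py_ = &posy[(size_t)p * m];
          double* pb_ = &br[(size_t)p * m];
          if (!persist_swarms && t > 1) {
            for (int i = 0; i < m; ++i) {
              px_[i] = R::runif(-(double)W, (double)W);
              py_[i] = R::runif(-(double)W, (double)W);
            }
          }
          ifa_sweep(fit, m, W, gamma, px_, py_, pb_, bestx[p], besty[p],
                    bestfit[p]);
          nfx(iy, ix) = bestx[p];
          nfy(iy, ix) = besty[p];
          fitmat(iy, ix) = bestfit[p];
        }
      }
    }
    fx = nfx;
    fy = nfy;
    if (record_psnr) {
      double acc = 0.0;
      for (int iy = 0; iy < h; ++iy) {
        for (int ix = 0; ix < w; ++ix) {
          const int cx = x0 + ix, cy = y0 + iy;
          const double d = px_at(cur, cx, cy) -
                           px_at(ref, cx + (int)fx(iy, ix),
                                 cy + (int)fy(iy, ix));
          acc += d * d;
        }
      }
      const double mse = acc / (double)npix;
      psnr_trace[t - 1] =
          mse > 0.0 ? 10.0 * std::log10(65025.0 / mse) : R_PosInf;
    }
  }

  return List::create(_["ux"] = fx, _["uy"] = fy, _["evaluations"] = evals,
                      _["fitness"] = fitmat, _["psnr_trace"] = psnr_trace);
}
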