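// Gridding NUFFT (Kaiser-Bessel interpolation on an oversampled FFTW grid)
// and the iterative reconstructions built on it:
//   - CG-SENSE on the density-weighted normal equations (per frame)
//   - monotone FISTA for the temporally TV-regularized problem
//     min_x ||W^1/2 (F_r S x - d)||_2^2 + lambda ||T x||_1
// The exported nufft/operator functions run in double precision; the
// iterative solvers run in single precision internally (the usual precision
// of MRI reconstruction toolboxes) to keep memory traffic down.

#include <Rcpp.h>
#include <fftw3.h>
#include <complex>
#include <cmath>
#include <cstring>
#include <map>
#include <utility>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- Bessel I0
static double bessi0(double x) {
  double ax = std::fabs(x), y;
  if (ax < 3.75) {
    y = x / 3.75; y *= y;
    return 1.0 + y * (3.5156229 + y * (3.0899424 + y * (1.2067492 +
           y * (0.2659732 + y * (0.0360768 + y * 0.0045813)))));
  }
  y = 3.75 / ax;
  return (std::exp(ax) / std::sqrt(ax)) *
         (0.39894228 + y * (0.01328592 + y * (0.00225319 + y * (-0.00157565 +
          y * (0.00916281 + y * (-0.02057706 + y * (0.02635537 +
          y * (-0.01647633 + y * 0.00392377))))))));
}

// -------------------------------------------------- Kaiser-Bessel kernel
struct Kernel {
  int w;           // width in oversampled grid cells
  double os;       // oversampling factor
  double beta, i0beta;
  Kernel(int w_, double os_) : w(w_), os(os_) {
    // Beatty et al. choice of beta for minimal aliasing amplitude
    double t = (double)w * w / (os * os) * (os - 0.5) * (os - 0.5) - 0.8;
    if (t < 0.1) t = 0.1;
    beta = M_PI * std::sqrt(t);
    i0beta = bessi0(beta);
  }
  double kb(double u) const {            // kernel value, |u| <= w/2
    double q = 1.0 - (2.0 * u / w) * (2.0 * u / w);
    if (q <= 0.0) return 0.0;
    return bessi0(beta * std::sqrt(q)) / i0beta;
  }
  double ft(double f) const {            // continuous FT at f cycles/grid-cell
    double a = M_PI * w * f;
    double t = beta * beta - a * a, v;
    if (t > 1e-12)      { double s = std::sqrt(t);  v = std::sinh(s) / s; }
    else if (t < -1e-12){ double s = std::sqrt(-t); v = std::sin(s) / s; }
    else v = 1.0;
    return v * w / i0beta;
  }
};

static int grid_size(int n, double os) {
  int G = (int)std::ceil(os * n);
  if (G % 2) ++G;
  return G;
}

// ------------------------------------------- precomputed sample geometry
struct Geom {
  int M, w, G;
  std::vector<int> jx, jy;       // wrapped grid indices, M*w each
  std::vector<double> wx, wy;    // separable kernel weights, M*w each
};

static void build_geom(Geom &g, const double *kx, const double *ky, int M,
                       int G, const Kernel &K) {
  g.M = M; g.w = K.w; g.G = G;
  g.jx.assign((size_t)M * K.w, 0); g.jy.assign((size_t)M * K.w, 0);
  g.wx.assign((size_t)M * K.w, 0.0); g.wy.assign((size_t)M * K.w, 0.0);
  for (int m = 0; m < M; ++m) {
    double ux = kx[m] * G, uy = ky[m] * G;
    int jx0 = (int)std::ceil(ux - K.w / 2.0);
    int jy0 = (int)std::ceil(uy - K.w / 2.0);
    for (int l = 0; l < K.w; ++l) {
      int ax = jx0 + l, ay = jy0 + l;
      g.wx[(size_t)m * K.w + l] = K.kb(ux - ax);
      g.wy[(size_t)m * K.w + l] = K.kb(uy - ay);
      g.jx[(size_t)m * K.w + l] = ((ax % G) + G) % G;
      g.jy[(size_t)m * K.w + l] = ((ay % G) + G) % G;
    }
  }
}

// deapodization: 1 / FT(kernel) sampled at pixel positions p/G
static std::vector<double> deapod_vec(int n, int G, const Kernel &K) {
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) {
    double p = (double)(i - n / 2);
    d[i] = 1.0 / K.ft(p / (double)G);
  }
  return d;
}

// ------------------------------------------------------- FFTW type traits
template <typename T> struct FT;
template <> struct FT<double> {
  typedef fftw_complex FC; typedef fftw_plan Plan;
  static Plan make(int G, int nb, FC *buf, int sign) {
    int nn[2] = {G, G};
    return fftw_plan_many_dft(2, nn, nb, buf, NULL, 1, G * G,
                              buf, NULL, 1, G * G, sign, FFTW_MEASURE);
  }
  static void exec(Plan p, FC *b) { fftw_execute_dft(p, b, b); }
  static FC *alloc(size_t n) { return (FC *)fftw_malloc(sizeof(FC) * n); }
};
template <> struct FT<float> {
  typedef fftwf_complex FC; typedef fftwf_plan Plan;
  static Plan make(int G, int nb, FC *buf, int sign) {
    int nn[2] = {G, G};
    return fftwf_plan_many_dft(2, nn, nb, buf, NULL, 1, G * G,
                               buf, NULL, 1, G * G, sign, FFTW_MEASURE);
  }
  static void exec(Plan p, FC *b) { fftwf_execute_dft(p, b, b); }
  static FC *alloc(size_t n) { return (FC *)fftwf_malloc(sizeof(FC) * n); }
};

template <typename T>
struct GridFFT {
  int G, nb;
  typename FT<T>::FC *buf;
  typename FT<T>::Plan fwd, bwd;
  GridFFT(int G_, int nb_) : G(G_), nb(nb_) {
    buf = FT<T>::alloc((size_t)G * G * nb);
    fwd = FT<T>::make(G, nb, buf, FFTW_FORWARD);
    bwd = FT<T>::make(G, nb, buf, FFTW_BACKWARD);
  }
  std::complex<T> *grid(int c) {
    return reinterpret_cast<std::complex<T> *>(buf) + (size_t)c * G * G;
  }
  void zero() {
    std::memset(buf, 0, sizeof(typename FT<T>::FC) * (size_t)G * G * nb);
  }
};

template <typename T>
static GridFFT<T> *get_fft(int G, int nb) {
  static std::map<std::pair<int, int>, GridFFT<T> *> cache;
  std::pair<int, int> key(G, nb);
  typename std::map<std::pair<int, int>, GridFFT<T> *>::iterator it =
      cache.find(key);
  if (it != cache.end()) return it->second;
  GridFFT<T> *g = new GridFFT<T>(G, nb);
  cache[key] = g;
  return g;
}

// ------------------------------------------------------- core primitives
// pixel index i (0..n-1) has position p = i - n/2; wrapped grid index:
static std::vector<int> wrap_idx(int n, int G) {
  std::vector<int> w(n);
  for (int i = 0; i < n; ++i) w[i] = (((i - n / 2) % G) + G) % G;
  return w;
}

// The wrapped pixel->grid map splits each axis into two contiguous runs:
// i in [0, n/2) -> g = G - n/2 + i, and i in [n/2, n) -> g = i - n/2.
// The pad/crop loops below exploit that for vectorizable inner loops.

// place (x .* map .* deapod) into grid
template <typename T>
static void pad_in(const std::complex<T> *x, const std::complex<T> *map,
                   std::complex<T> *grid, int n, int G,
                   const std::vector<double> &dap, const std::vector<int> &wr) {
  int h = n / 2, off = G - h;
  for (int iy = 0; iy < n; ++iy) {
    std::complex<T> *row = grid + (size_t)wr[iy] * G;
    T ay = (T)dap[iy];
    const std::complex<T> *xr = x + (size_t)iy * n;
    const std::complex<T> *mr = map ? map + (size_t)iy * n : NULL;
    for (int seg = 0; seg < 2; ++seg) {
      int i0 = seg ? h : 0, len = seg ? n - h : h;
      T *dst = reinterpret_cast<T *>(row + (seg ? 0 : off));
      const T *xs = reinterpret_cast<const T *>(xr + i0);
      const double *ds = &dap[i0];
      if (mr) {
        const T *ms = reinterpret_cast<const T *>(mr + i0);
        for (int i = 0; i < len; ++i) {
          T s = ay * (T)ds[i];
          T a = xs[2 * i], b = xs[2 * i + 1];
          T c = ms[2 * i], d = ms[2 * i + 1];
          dst[2 * i] = (a * c - b * d) * s;
          dst[2 * i + 1] = (a * d + b * c) * s;
        }
      } else {
        for (int i = 0; i < len; ++i) {
          T s = ay * (T)ds[i];
          dst[2 * i] = xs[2 * i] * s;
          dst[2 * i + 1] = xs[2 * i + 1] * s;
        }
      }
    }
  }
}

// out += conj(map) .* deapod .* crop(grid)
template <typename T>
static void crop_out(const std::complex<T> *grid, const std::complex<T> *map,
                     std::complex<T> *out, int n, int G,
                     const std::vector<double> &dap, const std::vector<int> &wr,
                     bool accumulate) {
  int h = n / 2, off = G - h;
  for (int iy = 0; iy < n; ++iy) {
    const std::complex<T> *row = grid + (size_t)wr[iy] * G;
    T ay = (T)dap[iy];
    std::complex<T> *orow = out + (size_t)iy * n;
    const std::complex<T> *mr = map ? map + (size_t)iy * n : NULL;
    for (int seg = 0; seg < 2; ++seg) {
      int i0 = seg ? h : 0, len = seg ? n - h : h;
      const T *src = reinterpret_cast<const T *>(row + (seg ? 0 : off));
      T *dst = reinterpret_cast<T *>(orow + i0);
      const double *ds = &dap[i0];
      if (mr) {
        const T *ms = reinterpret_cast<const T *>(mr + i0);
        for (int i = 0; i < len; ++i) {
          T s = ay * (T)ds[i];
          T a = src[2 * i], b = src[2 * i + 1];
          T c = ms[2 * i], d = -ms[2 * i + 1];   // conj(map)
          T re = (a * c - b * d) * s, im = (a * d + b * c) * s;
          if (accumulate) { dst[2 * i] += re; dst[2 * i + 1] += im; }
          else { dst[2 * i] = re; dst[2 * i + 1] = im; }
        }
      } else {
        for (int i = 0; i < len; ++i) {
          T s = ay * (T)ds[i];
          if (accumulate) {
            dst[2 * i] += src[2 * i] * s;
            dst[2 * i + 1] += src[2 * i + 1] * s;
          } else {
            dst[2 * i] = src[2 * i] * s;
            dst[2 * i + 1] = src[2 * i + 1] * s;
          }
        }
      }
    }
  }
}

template <typename T>
static void gather(const std::complex<T> *grid, const Geom &g,
                   const T *sqdcf, std::complex<T> *y) {
  int w = g.w, G = g.G;
  for (int m = 0; m < g.M; ++m) {
    std::complex<T> acc(0, 0);
    const int *jx = &g.jx[(size_t)m * w], *jy = &g.jy[(size_t)m * w];
    const double *wx = &g.wx[(size_t)m * w], *wy = &g.wy[(size_t)m * w];
    for (int ly = 0; ly < w; ++ly) {
      const std::complex<T> *row = grid + (size_t)jy[ly] * G;
      std::complex<T> inner(0, 0);
      for (int lx = 0; lx < w; ++lx) inner += row[jx[lx]] * (T)wx[lx];
      acc += inner * (T)wy[ly];
    }
    y[m] = sqdcf ? acc * sqdcf[m] : acc;
  }
}

template <typename T>
static void spread(const std::complex<T> *y, const Geom &g, const T *sqdcf,
                   std::complex<T> *grid) {
  int w = g.w, G = g.G;
  for (int m = 0; m < g.M; ++m) {
    std::complex<T> s = sqdcf ? y[m] * sqdcf[m] : y[m];
    if (s.real() == (T)0 && s.imag() == (T)0) continue;
    const int *jx = &g.jx[(size_t)m * w], *jy = &g.jy[(size_t)m * w];
    const double *wx = &g.wx[(size_t)m * w], *wy = &g.wy[(size_t)m * w];
    for (int ly = 0; ly < w; ++ly) {
      std::complex<T> t = s * (T)wy[ly];
      std::complex<T> *row = grid + (size_t)jy[ly] * G;
      for (int lx = 0; lx < w; ++lx) row[jx[lx]] += t * (T)wx[lx];
    }
  }
}

// full multicoil forward: x (n^2) -> y (M*nc); maps may be NULL (nc=1)
template <typename T>
static void op_forward(const std::complex<T> *x, const std::complex<T> *maps,
                       const T *sqdcf, const Geom &g, int n, int nc,
                       const std::vector<double> &dap,
                       const std::vector<int> &wr, GridFFT<T> *fft,
                       std::complex<T> *y) {
  fft->zero();
  for (int c = 0; c < nc; ++c)
    pad_in(x, maps ? maps + (size_t)c * n * n : NULL, fft->grid(c), n, fft->G,
           dap, wr);
  FT<T>::exec(fft->fwd, fft->buf);
  for (int c = 0; c < nc; ++c)
    gather(fft->grid(c), g, sqdcf, y + (size_t)c * g.M);
}

template <typename T>
static void op_adjoint(const std::complex<T> *y, const std::complex<T> *maps,
                       const T *sqdcf, const Geom &g, int n, int nc,
                       const std::vector<double> &dap,
                       const std::vector<int> &wr, GridFFT<T> *fft,
                       std::complex<T> *x) {
  fft->zero();
  for (int c = 0; c < nc; ++c)
    spread(y + (size_t)c * g.M, g, sqdcf, fft->grid(c));
  FT<T>::exec(fft->bwd, fft->buf);
  for (int c = 0; c < nc; ++c)
    crop_out(fft->grid(c), maps ? maps + (size_t)c * n * n : NULL, x, n,
             fft->G, dap, wr, c > 0);
}

// ------------------------------------------------------------ conversions
template <typename T>
static std::vector<std::complex<T> > as_cplx(const ComplexVector &v) {
  std::vector<std::complex<T> > out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i)
    out[i] = std::complex<T>((T)v[i].r, (T)v[i].i);
  return out;
}

template <typename T>
static void fill_rcplx(const std::vector<std::complex<T> > &v,
                       ComplexVector &out) {
  for (R_xlen_t i = 0; i < out.size(); ++i) {
    out[i].r = (double)v[i].real();
    out[i].i = (double)v[i].imag();
  }
}

// ======================================================== exported NUFFT

// [[Rcpp::export]]
ComplexMatrix cpp_nufft_forward(ComplexVector img, NumericVector kx,
                                NumericVector ky, int n, int nc, double os,
                                int width) {
  Kernel K(width, os);
  int G = grid_size(n, os), M = kx.size();
  Geom g; build_geom(g, kx.begin(), ky.begin(), M, G, K);
  std::vector<double> dap = deapod_vec(n, G, K);
  std::vector<int> wr = wrap_idx(n, G);
  GridFFT<double> *fft = get_fft<double>(G, nc);
  std::vector<std::complex<double> > x = as_cplx<double>(img);
  std::vector<std::complex<double> > y((size_t)M * nc);
  fft->zero();
  for (int c = 0; c < nc; ++c)
    pad_in(&x[(size_t)c * n * n], (std::complex<double> *)NULL, fft->grid(c),
           n, G, dap, wr);
  FT<double>::exec(fft->fwd, fft->buf);
  for (int c = 0; c < nc; ++c)
    gather(fft->grid(c), g, (double *)NULL, &y[(size_t)c * M]);
  ComplexMatrix out(M, nc);
  ComplexVector ov(out);
  fill_rcplx(y, ov);
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_nufft_adjoint(ComplexMatrix samp, NumericVector kx,
                                NumericVector ky, int n, int nc, double os,
                                int width) {
  Kernel K(width, os);
  int G = grid_size(n, os), M = kx.size();
  Geom g; build_geom(g, kx.begin(), ky.begin(), M, G, K);
  std::vector<double> dap = deapod_vec(n, G, K);
  std::vector<int> wr = wrap_idx(n, G);
  GridFFT<double> *fft = get_fft<double>(G, nc);
  std::vector<std::complex<double> > y = as_cplx<double>(ComplexVector(samp));
  std::vector<std::complex<double> > x((size_t)n * n * nc);
  fft->zero();
  for (int c = 0; c < nc; ++c)
    spread(&y[(size_t)c * M], g, (double *)NULL, fft->grid(c));
  FT<double>::exec(fft->bwd, fft->buf);
  for (int c = 0; c < nc; ++c)
    crop_out(fft->grid(c), (std::complex<double> *)NULL,
             &x[(size_t)c * n * n], n, G, dap, wr, false);
  ComplexVector out((R_xlen_t)n * n * nc);
  fill_rcplx(x, out);
  out.attr("dim") = IntegerVector::create(n, n, nc);
  return out;
}

// coil-weighted encoding operator (double precision, for adjoint checks)

// [[Rcpp::export]]
ComplexMatrix cpp_op_forward(ComplexVector img, ComplexVector maps,
                             NumericVector sqdcf, NumericVector kx,
                             NumericVector ky, int n, int nc, double os,
                             int width) {
  Kernel K(width, os);
  int G = grid_size(n, os), M = kx.size();
  Geom g; build_geom(g, kx.begin(), ky.begin(), M, G, K);
  std::vector<double> dap = deapod_vec(n, G, K);
  std::vector<int> wr = wrap_idx(n, G);
  GridFFT<double> *fft = get_fft<double>(G, nc);
  std::vector<std::complex<double> > x = as_cplx<double>(img);
  std::vector<std::complex<double> > S = as_cplx<double>(maps);
  std::vector<std::complex<double> > y((size_t)M * nc);
  op_forward(&x[0], &S[0], sqdcf.begin(), g, n, nc, dap, wr, fft, &y[0]);
  ComplexMatrix out(M, nc);
  ComplexVector ov(out);
  fill_rcplx(y, ov);
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_op_adjoint(ComplexMatrix samp, ComplexVector maps,
                             NumericVector sqdcf, NumericVector kx,
                             NumericVector ky, int n, int nc, double os,
                             int width) {
  Kernel K(width, os);
  int G = grid_size(n, os), M = kx.size();
  Geom g; build_geom(g, kx.begin(), ky.begin(), M, G, K);
  std::vector<double> dap = deapod_vec(n, G, K);
  std::vector<int> wr = wrap_idx(n, G);
  GridFFT<double> *fft = get_fft<double>(G, nc);
  std::vector<std::complex<double> > y = as_cplx<double>(ComplexVector(samp));
  std::vector<std::complex<double> > S = as_cplx<double>(maps);
  std::vector<std::complex<double> > x((size_t)n * n);
  op_adjoint(&y[0], &S[0], sqdcf.begin(), g, n, nc, dap, wr, fft, &x[0]);
  ComplexVector out((R_xlen_t)n * n);
  fill_rcplx(x, out);
  out.attr("dim") = IntegerVector::create(n, n);
  return out;
}

// ===================================================== 1D TV denoising
// Exact prox of lam*TV via the taut-string construction. Scans left to
// right keeping the feasible interval [rmax, rmin] of segment values; when
// extending the segment empties the interval, the earlier bound is frozen
// as a jump and the scan restarts after it (worst case O(N^2), N is the
// number of time frames here).
static void tv1d_ws(const double *y, double *x, int N, double lam,
                    double *cs) {
  if (N <= 0) return;
  if (lam <= 0.0) { std::memcpy(x, y, sizeof(double) * N); return; }
  cs[0] = 0.0;
  for (int i = 0; i < N; ++i) cs[i + 1] = cs[i] + y[i];
  int k0 = 0;          // segment start
  double uL = 0.0;     // dual value entering the segment (0, +lam or -lam)
  while (k0 < N) {
    // candidate values: Vdown(j) if a downward jump follows j,
    //                   Vup(j) if an upward jump follows j
    double rmin = 0.0, rmax = 0.0;  // min Vdown / max Vup so far
    int km = k0, kp = k0;
    bool done = false;
    for (int k = k0; k < N; ++k) {
      double len = (double)(k - k0 + 1);
      double s = cs[k + 1] - cs[k0] + uL;
      double vd = (s + lam) / len, vu = (s - lam) / len;
      if (k == k0) { rmin = vd; km = k; rmax = vu; kp = k; }
      else {
        if (vu > rmax) {
          if (vu > rmin) {  // interval empty: freeze down-jump at km
            for (int i = k0; i <= km; ++i) x[i] = rmin;
            k0 = km + 1; uL = -lam; done = false; break;
          }
          rmax = vu; kp = k;
        }
        if (vd < rmin) {
          if (vd < rmax) {  // freeze up-jump at kp
            for (int i = k0; i <= kp; ++i) x[i] = rmax;
            k0 = kp + 1; uL = lam; done = false; break;
          }
          rmin = vd; km = k;
        }
      }
      if (k == N - 1) {
        // terminal segment must close the dual at 0
        double v0 = (cs[N] - cs[k0] + uL) / len;
        if (v0 > rmin) {
          for (int i = k0; i <= km; ++i) x[i] = rmin;
          k0 = km + 1; uL = -lam;
        } else if (v0 < rmax) {
          for (int i = k0; i <= kp; ++i) x[i] = rmax;
          k0 = kp + 1; uL = lam;
        } else {
          for (int i = k0; i < N; ++i) x[i] = v0;
          k0 = N; done = true;
        }
        break;
      }
    }
    if (done) break;
  }
}


static void tv1d(const double *y, double *x, int N, double lam) {
  std::vector<double> cs((size_t)N + 1);
  tv1d_ws(y, x, N, lam, &cs[0]);
}

// [[Rcpp::export]]
NumericVector cpp_tv_denoise(NumericVector y, double lam) {
  NumericVector out(y.size());
  tv1d(y.begin(), out.begin(), y.size(), lam);
  return out;
}

// ========================================================= CG-SENSE
// Per-frame conjugate gradients on E^H E x = E^H W d with
// E = W^1/2 F_r S; early stop on relative normal-equation residual.

// [[Rcpp::export]]
List cpp_cg_sense(ComplexVector d, NumericMatrix kx, NumericMatrix ky,
                  ComplexVector maps, NumericVector sqdcf, int n, int nc,
                  int nframes, double os, int width, int max_iter,
                  double tol) {
  typedef std::complex<float> CF;
  Kernel K(width, os);
  int G = grid_size(n, os);
  int M = kx.nrow();
  size_t n2 = (size_t)n * n;
  std::vector<double> dap = deapod_vec(n, G, K);
  std::vector<int> wr = wrap_idx(n, G);
  GridFFT<float> *fft = get_fft<float>(G, nc);
  std::vector<CF> S = as_cplx<float>(maps);
  std::vector<float> sw(sqdcf.begin(), sqdcf.end());
  std::vector<CF> dd = as_cplx<float>(d);  // (M, nc, nframes)

  std::vector<CF> xall(n2 * nframes, CF(0, 0));
  std::vector<CF> b(n2), r(n2), p(n2), q(n2), dw((size_t)M * nc),
      yt((size_t)M * nc);
  IntegerVector iters(nframes);
  NumericVector relres(nframes);
  Geom g;
  for (int f = 0; f < nframes; ++f) {
    build_geom(g, &kx(0, f), &ky(0, f), M, G, K);
    // b = E^H (W^1/2 d): pre-multiply data by sqdcf once, op_adjoint adds one
    const CF *df = &dd[(size_t)f * M * nc];
    for (size_t i = 0; i < (size_t)M * nc; ++i)
      dw[i] = df[i] * sw[i % (size_t)M];
    op_adjoint(&dw[0], &S[0], &sw[0], g, n, nc, dap, wr, fft, &b[0]);
    double bn = 0.0;
    for (size_t i = 0; i < n2; ++i) bn += std::norm(b[i]);
    bn = std::sqrt(bn);
    CF *x = &xall[n2 * f];
    if (bn == 0.0) { iters[f] = 0; relres[f] = 0.0; continue; }
    std::memcpy(&r[0], &b[0], sizeof(CF) * n2);
    std::memcpy(&p[0], &b[0], sizeof(CF) * n2);
    double rs = bn * bn, rs0 = rs;
    int it = 0;
    for (; it < max_iter; ++it) {
      op_forward(&p[0], &S[0], &sw[0], g, n, nc, dap, wr, fft, &yt[0]);
      op_adjoint(&yt[0], &S[0], &sw[0], g, n, nc, dap, wr, fft, &q[0]);
      double pq = 0.0;
      for (size_t i = 0; i < n2; ++i)
        pq += p[i].real() * q[i].real() + p[i].imag() * q[i].imag();
      if (pq <= 0.0) break;
      float alpha = (float)(rs / pq);
      double rs_new = 0.0;
      for (size_t i = 0; i < n2; ++i) {
        x[i] += alpha * p[i];
        r[i] -= alpha * q[i];
        rs_new += std::norm(r[i]);
      }
      if (std::sqrt(rs_new / rs0) < tol) { rs = rs_new; ++it; break; }
      float bet = (float)(rs_new / rs);
      rs = rs_new;
      for (size_t i = 0; i < n2; ++i) p[i] = r[i] + bet * p[i];
    }
    iters[f] = it;
    relres[f] = std::sqrt(rs) / bn;
  }
  ComplexVector out(n2 * nframes);
  fill_rcplx(xall, out);
  out.attr("dim") = IntegerVector::create(n, n, nframes);
  return List::create(_["x"] = out, _["iters"] = iters,
                      _["relres"] = relres);
}

// ================================================ monotone FISTA with TV
static double xorshift_unif(unsigned long long &s) {
  s ^= s << 13; s ^= s >> 7; s ^= s << 17;
  return (double)(s % 1000003ULL) / 1000003.0 - 0.5;
}

// [[Rcpp::export]]
List cpp_cs_tv(ComplexVector d, NumericMatrix kx, NumericMatrix ky,
               ComplexVector maps, NumericVector sqdcf, int n, int nc,
               int nframes, double os, int width, double lambda,
               int n_iter) {
  typedef std::complex<float> CF;
  Kernel K(width, os);
  int G = grid_size(n, os);
  int M = kx.nrow();
  size_t n2 = (size_t)n * n, nt = n2 * nframes;
  std::vector<double> dap = deapod_vec(n, G, K);
  std::vector<int> wr = wrap_idx(n, G);
  GridFFT<float> *fft = get_fft<float>(G, nc);
  std::vector<CF> S = as_cplx<float>(maps);
  std::vector<float> sw(sqdcf.begin(), sqdcf.end());
  std::vector<CF> dd = as_cplx<float>(d);

  std::vector<Geom> geoms(nframes);
  for (int f = 0; f < nframes; ++f)
    build_geom(geoms[f], &kx(0, f), &ky(0, f), M, G, K);

  // weighted data W^1/2 d
  std::vector<CF> dw((size_t)M * nc * nframes);
  for (int f = 0; f < nframes; ++f)
    for (size_t i = 0; i < (size_t)M * nc; ++i)
      dw[(size_t)f * M * nc + i] =
          dd[(size_t)f * M * nc + i] * sw[i % (size_t)M];

  std::vector<CF> yt((size_t)M * nc), tmp(n2);

  // Lipschitz constant: L = 2 * max_f lambda_max(E_f^H E_f), power iteration
  double lmax = 0.0;
  {
    std::vector<CF> v(n2), w(n2);
    for (int f = 0; f < nframes; ++f) {
      unsigned long long st = 88172645463325252ULL + 7919ULL * (f + 1);
      for (size_t i = 0; i < n2; ++i)
        v[i] = CF((float)xorshift_unif(st), (float)xorshift_unif(st));
      double lam_f = 0.0;
      for (int itp = 0; itp < 10; ++itp) {
        double nv = 0.0;
        for (size_t i = 0; i < n2; ++i) nv += std::norm(v[i]);
        nv = std::sqrt(nv);
        if (nv == 0.0) break;
        for (size_t i = 0; i < n2; ++i) v[i] *= (float)(1.0 / nv);
        op_forward(&v[0], &S[0], &sw[0], geoms[f], n, nc, dap, wr, fft,
                   &yt[0]);
        op_adjoint(&yt[0], &S[0], &sw[0], geoms[f], n, nc, dap, wr, fft,
                   &w[0]);
        double vw = 0.0;
        for (size_t i = 0; i < n2; ++i)
          vw += v[i].real() * w[i].real() + v[i].imag() * w[i].imag();
        lam_f = vw;
        std::swap(v, w);
      }
      if (lam_f > lmax) lmax = lam_f;
    }
  }
  double L = 2.0 * lmax * 1.05;
  if (L <= 0.0) L = 1.0;
  float tau = (float)(1.0 / L);

  std::vector<CF> x(nt, CF(0, 0)), xprev(nt, CF(0, 0)), yv(nt, CF(0, 0)),
      z(nt), gr(nt);
  std::vector<double> seq(nframes), den(nframes), csws(nframes + 1);
  NumericVector obj(n_iter);

  // objective of the all-zero start
  double F_x = 0.0;
  for (size_t i = 0; i < (size_t)M * nc * nframes; ++i) F_x += std::norm(dw[i]);

  double tk = 1.0;
  double tvw = (double)tau * lambda;
  for (int it = 0; it < n_iter; ++it) {
    // gradient of data term at yv
    for (int f = 0; f < nframes; ++f) {
      op_forward(&yv[n2 * f], &S[0], &sw[0], geoms[f], n, nc, dap, wr, fft,
                 &yt[0]);
      for (size_t i = 0; i < (size_t)M * nc; ++i)
        yt[i] -= dw[(size_t)f * M * nc + i];
      op_adjoint(&yt[0], &S[0], &sw[0], geoms[f], n, nc, dap, wr, fft,
                 &tmp[0]);
      CF *gf = &gr[n2 * f];
      for (size_t i = 0; i < n2; ++i) gf[i] = (float)2.0 * tmp[i];
    }
    // proximal step (cache-blocked over pixels: the time axis has stride
    // n^2, so gather blocks of pixels into a contiguous transpose first)
    for (size_t i = 0; i < nt; ++i) z[i] = yv[i] - tau * gr[i];
    double tvsum = 0.0;
    if (lambda > 0.0 && nframes > 1) {
      const size_t B = 128;
      std::vector<float> tbuf(2 * B * nframes);
      for (size_t p0 = 0; p0 < n2; p0 += B) {
        size_t nb = std::min(B, n2 - p0);
        for (int f = 0; f < nframes; ++f) {
          const CF *zf = &z[n2 * f + p0];
          for (size_t i = 0; i < nb; ++i) {
            tbuf[(2 * i) * nframes + f] = zf[i].real();
            tbuf[(2 * i + 1) * nframes + f] = zf[i].imag();
          }
        }
        for (size_t i = 0; i < 2 * nb; ++i) {
          float *row = &tbuf[i * nframes];
          for (int f = 0; f < nframes; ++f) seq[f] = row[f];
          tv1d_ws(&seq[0], &den[0], nframes, tvw, &csws[0]);
          for (int f = 0; f < nframes; ++f) row[f] = (float)den[f];
          for (int f = 1; f < nframes; ++f)
            tvsum += std::fabs(den[f] - den[f - 1]);
        }
        for (int f = 0; f < nframes; ++f) {
          CF *zf = &z[n2 * f + p0];
          for (size_t i = 0; i < nb; ++i)
            zf[i] = CF(tbuf[(2 * i) * nframes + f],
                       tbuf[(2 * i + 1) * nframes + f]);
        }
      }
    }
    // objective at the candidate
    double F_z = lambda * tvsum;
    for (int f = 0; f < nframes; ++f) {
      op_forward(&z[n2 * f], &S[0], &sw[0], geoms[f], n, nc, dap, wr, fft,
                 &yt[0]);
      for (size_t i = 0; i < (size_t)M * nc; ++i)
        F_z += std::norm(yt[i] - dw[(size_t)f * M * nc + i]);
    }
    // monotone step: keep the better of candidate and previous iterate
    bool accept = (F_z <= F_x);
    double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    std::swap(xprev, x);
    if (accept) { std::memcpy(&x[0], &z[0], sizeof(CF) * nt); F_x = F_z; }
    else std::memcpy(&x[0], &xprev[0], sizeof(CF) * nt);
    float c1 = (float)(tk / tk1), c2 = (float)((tk - 1.0) / tk1);
    for (size_t i = 0; i < nt; ++i)
      yv[i] = x[i] + c1 * (z[i] - x[i]) + c2 * (x[i] - xprev[i]);
    tk = tk1;
    obj[it] = F_x;
  }

  ComplexVector out(nt);
  fill_rcplx(x, out);
  out.attr("dim") = IntegerVector::create(n, n, nframes);
  return List::create(_["x"] = out, _["objective"] = obj,
                      _["lipschitz"] = L);
}

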