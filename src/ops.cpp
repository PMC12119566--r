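// Dense 3D network kernels and the Euclidean distance transform.
// Feature maps are R arrays with dim (X, Y, Z, C), column-major, so the
// x-axis is the fastest index. Convolution weights have dim (k, k, k, Cin,
// Cout). All kernels are written for small channel counts and desk-scale
// grids; GEMM work goes through Armadillo/BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather sliding-window columns: rows indexed by (kx, ky, kz, ci), columns by
// output voxel. Zero padding outside the grid.
static arma::mat im2col3d(const double* x, int X, int Y, int Z, int C,
                          int k, int stride, int pad) {
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  const int ncol = Xo * Yo * Zo;
  arma::mat K(k * k * k * C, ncol, arma::fill::zeros);
  for (int zo = 0; zo < Zo; ++zo)
    for (int yo = 0; yo < Yo; ++yo)
      for (int xo = 0; xo < Xo; ++xo) {
        const int col = xo + Xo * (yo + Yo * zo);
        double* dst = K.colptr(col);
        const int x0 = xo * stride - pad;
        const int y0 = yo * stride - pad;
        const int z0 = zo * stride - pad;
        for (int ci = 0; ci < C; ++ci)
          for (int kz = 0; kz < k; ++kz) {
            const int zz = z0 + kz;
            if (zz < 0 || zz >= Z) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int yy = y0 + ky;
              if (yy < 0 || yy >= Y) continue;
              const double* src = x + (size_t)X * (yy + (size_t)Y * (zz + (size_t)Z * ci));
              double* drow = dst + k * (ky + k * (kz + k * ci));
              for (int kx = 0; kx < k; ++kx) {
                const int xx = x0 + kx;
                if (xx < 0 || xx >= X) continue;
                drow[kx] = src[xx];
              }
            }
          }
      }
  return K;
}

// Adjoint of im2col3d: scatter-add columns back into the input grid.
static void col2im3d(const arma::mat& K, double* gx, int X, int Y, int Z,
                     int C, int k, int stride, int pad) {
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  for (int zo = 0; zo < Zo; ++zo)
    for (int yo = 0; yo < Yo; ++yo)
      for (int xo = 0; xo < Xo; ++xo) {
        const int col = xo + Xo * (yo + Yo * zo);
        const double* src = K.colptr(col);
        const int x0 = xo * stride - pad;
        const int y0 = yo * stride - pad;
        const int z0 = zo * stride - pad;
        for (int ci = 0; ci < C; ++ci)
          for (int kz = 0; kz < k; ++kz) {
            const int zz = z0 + kz;
            if (zz < 0 || zz >= Z) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int yy = y0 + ky;
              if (yy < 0 || yy >= Y) continue;
              double* dst = gx + (size_t)X * (yy + (size_t)Y * (zz + (size_t)Z * ci));
              const double* srow = src + k * (ky + k * (kz + k * ci));
              for (int kx = 0; kx < k; ++kx) {
                const int xx = x0 + kx;
                if (xx < 0 || xx >= X) continue;
                dst[xx] += srow[kx];
              }
            }
          }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector b, int stride, int pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int k = wdim[0], Cin = wdim[3], Cout = wdim[4];
  if (Cin != C) stop("conv3d: input has %d channels, weight expects %d", C, Cin);
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  arma::mat K = im2col3d(x.begin(), X, Y, Z, C, k, stride, pad);
  arma::mat W(const_cast<double*>(w.begin()), k * k * k * Cin, Cout, false, true);
  arma::mat Yt = K.t() * W;  // (Nout x Cout): column-major == (Xo,Yo,Zo,Cout)
  Yt.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector out(Yt.begin(), Yt.end());
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim, NumericVector w,
                    IntegerVector wdim, NumericVector gy, int stride, int pad,
                    bool need_gx) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int k = wdim[0], Cin = wdim[3], Cout = wdim[4];
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  const int Nout = Xo * Yo * Zo;
  arma::mat Gy(const_cast<double*>(gy.begin()), Nout, Cout, false, true);
  arma::mat K = im2col3d(x.begin(), X, Y, Z, C, k, stride, pad);
  arma::mat Gw = K * Gy;  // (k3*Cin x Cout)
  NumericVector gwv(Gw.begin(), Gw.end());
  gwv.attr("dim") = wdim;
  NumericVector gbv(Cout);
  arma::rowvec gb = arma::sum(Gy, 0);
  std::copy(gb.begin(), gb.end(), gbv.begin());
  List res = List::create(_["gw"] = gwv, _["gb"] = gbv);
  if (need_gx) {
    arma::mat W(const_cast<double*>(w.begin()), k * k * k * Cin, Cout, false, true);
    arma::mat Gcols = W * Gy.t();  // (k3*Cin x Nout)
    NumericVector gxv(x.size());
    col2im3d(Gcols, gxv.begin(), X, Y, Z, C, k, stride, pad);
    gxv.attr("dim") = xdim;
    res["gx"] = gxv;
  }
  return res;
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping upsampling).
// w has dim (2, 2, 2, Cin, Cout); output dim (2X, 2Y, 2Z, Cout).
// [[Rcpp::export]]
NumericVector cpp_convt3d_fwd(NumericVector x, IntegerVector xdim,
                              NumericVector w, NumericVector b) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int Cout = w.size() / (8 * Cin);
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector out((size_t)Xo * Yo * Zo * Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const double bc = b[co];
    double* obase = op + (size_t)Xo * Yo * Zo * co;
    for (size_t i = 0; i < (size_t)Xo * Yo * Zo; ++i) obase[i] = bc;
  }
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci) {
      const double* wk = wp + 8 * (ci + (size_t)Cin * co);
      const double* xc = xp + (size_t)X * Y * Z * ci;
      double* oc = op + (size_t)Xo * Yo * Zo * co;
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
          for (int x0 = 0; x0 < X; ++x0) {
            const double v = xc[x0 + (size_t)X * (y + (size_t)Y * z)];
            if (v == 0.0) continue;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx)
                  oc[(2 * x0 + dx) + (size_t)Xo * ((2 * y + dy) + (size_t)Yo * (2 * z + dz))]
                    += v * wk[dx + 2 * (dy + 2 * dz)];
          }
    }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_convt3d_bwd(NumericVector x, IntegerVector xdim, NumericVector w,
                     NumericVector gy) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int Cout = w.size() / (8 * Cin);
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector gx(x.size());
  NumericVector gw(w.size());
  NumericVector gb(Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gy.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + (size_t)Xo * Yo * Zo * co;
    double s = 0.0;
    for (size_t i = 0; i < (size_t)Xo * Yo * Zo; ++i) s += gc[i];
    gb[co] = s;
  }
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci) {
      const double* wk = wp + 8 * (ci + (size_t)Cin * co);
      double* gwk = gw.begin() + 8 * (ci + (size_t)Cin * co);
      const double* xc = xp + (size_t)X * Y * Z * ci;
      double* gxc = gx.begin() + (size_t)X * Y * Z * ci;
      const double* gc = gp + (size_t)Xo * Yo * Zo * co;
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
          for (int x0 = 0; x0 < X; ++x0) {
            const size_t xi = x0 + (size_t)X * (y + (size_t)Y * z);
            const double v = xc[xi];
            double acc = 0.0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const double g = gc[(2 * x0 + dx) +
                    (size_t)Xo * ((2 * y + dy) + (size_t)Yo * (2 * z + dz))];
                  acc += g * wk[dx + 2 * (dy + 2 * dz)];
                  gwk[dx + 2 * (dy + 2 * dz)] += g * v;
                }
            gxc[xi] += acc;
          }
    }
  gx.attr("dim") = xdim;
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

struct AxisInterp {
  std::vector<int> i0, i1;
  std::vector<double> t;
};

// Half-voxel-aligned source coordinates for integer-factor upsampling.
static AxisInterp axis_interp(int n_out, int n_in, int f) {
  AxisInterp a;
  a.i0.resize(n_out); a.i1.resize(n_out); a.t.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double src = (i + 0.5) / f - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int i0 = (int)std::floor(src);
    int i1 = std::min(i0 + 1, n_in - 1);
    a.i0[i] = i0; a.i1[i] = i1; a.t[i] = src - i0;
  }
  return a;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3d(NumericVector x, IntegerVector xdim, int f) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int Xo = X * f, Yo = Y * f, Zo = Z * f;
  AxisInterp ax = axis_interp(Xo, X, f), ay = axis_interp(Yo, Y, f),
             az = axis_interp(Zo, Z, f);
  NumericVector out((size_t)Xo * Yo * Zo * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)X * Y * Z * c;
    double* oc = op + (size_t)Xo * Yo * Zo * c;
    for (int z = 0; z < Zo; ++z) {
      const int z0 = az.i0[z], z1 = az.i1[z]; const double tz = az.t[z];
      for (int y = 0; y < Yo; ++y) {
        const int y0 = ay.i0[y], y1 = ay.i1[y]; const double ty = ay.t[y];
        for (int x0i = 0; x0i < Xo; ++x0i) {
          const int x0 = ax.i0[x0i], x1 = ax.i1[x0i]; const double tx = ax.t[x0i];
          const double c000 = xc[x0 + (size_t)X * (y0 + (size_t)Y * z0)];
          const double c100 = xc[x1 + (size_t)X * (y0 + (size_t)Y * z0)];
          const double c010 = xc[x0 + (size_t)X * (y1 + (size_t)Y * z0)];
          const double c110 = xc[x1 + (size_t)X * (y1 + (size_t)Y * z0)];
          const double c001 = xc[x0 + (size_t)X * (y0 + (size_t)Y * z1)];
          const double c101 = xc[x1 + (size_t)X * (y0 + (size_t)Y * z1)];
          const double c011 = xc[x0 + (size_t)X * (y1 + (size_t)Y * z1)];
          const double c111 = xc[x1 + (size_t)X * (y1 + (size_t)Y * z1)];
          const double c00 = c000 + tx * (c100 - c000);
          const double c10 = c010 + tx * (c110 - c010);
          const double c01 = c001 + tx * (c101 - c001);
          const double c11 = c011 + tx * (c111 - c011);
          const double c0 = c00 + ty * (c10 - c00);
          const double c1 = c01 + ty * (c11 - c01);
          oc[x0i + (size_t)Xo * (y + (size_t)Yo * z)] = c0 + tz * (c1 - c0);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3d_bwd(NumericVector gy, IntegerVector xdim, int f) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  const int Xo = X * f, Yo = Y * f, Zo = Z * f;
  AxisInterp ax = axis_interp(Xo, X, f), ay = axis_interp(Yo, Y, f),
             az = axis_interp(Zo, Z, f);
  NumericVector gx((size_t)X * Y * Z * C);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)X * Y * Z * c;
    const double* oc = gp + (size_t)Xo * Yo * Zo * c;
    for (int z = 0; z < Zo; ++z) {
      const int z0 = az.i0[z], z1 = az.i1[z]; const double tz = az.t[z];
      for (int y = 0; y < Yo; ++y) {
        const int y0 = ay.i0[y], y1 = ay.i1[y]; const double ty = ay.t[y];
        for (int x0i = 0; x0i < Xo; ++x0i) {
          const int x0 = ax.i0[x0i], x1 = ax.i1[x0i]; const double tx = ax.t[x0i];
          const double g = oc[x0i + (size_t)Xo * (y + (size_t)Yo * z)];
          xc[x0 + (size_t)X * (y0 + (size_t)Y * z0)] += g * (1 - tx) * (1 - ty) * (1 - tz);
          xc[x1 + (size_t)X * (y0 + (size_t)Y * z0)] += g * tx * (1 - ty) * (1 - tz);
          xc[x0 + (size_t)X * (y1 + (size_t)Y * z0)] += g * (1 - tx) * ty * (1 - tz);
          xc[x1 + (size_t)X * (y1 + (size_t)Y * z0)] += g * tx * ty * (1 - tz);
          xc[x0 + (size_t)X * (y0 + (size_t)Y * z1)] += g * (1 - tx) * (1 - ty) * tz;
          xc[x1 + (size_t)X * (y0 + (size_t)Y * z1)] += g * tx * (1 - ty) * tz;
          xc[x0 + (size_t)X * (y1 + (size_t)Y * z1)] += g * (1 - tx) * ty * tz;
          xc[x1 + (size_t)X * (y1 + (size_t)Y * z1)] += g * tx * ty * tz;
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// 1D lower-envelope-of-parabolas squared distance transform at arbitrary
// sample positions p[j] = j*s (Felzenszwalb & Huttenlocher).
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& zbuf) {
  int kk = 0;
  v[0] = 0;
  zbuf[0] = -INFINITY;
  zbuf[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double sm;
    while (true) {
      const int p = v[kk];
      sm = ((f[q] + (double)q * q * s * s) - (f[p] + (double)p * p * s * s)) /
           (2.0 * s * s * (q - p));
      if (sm <= zbuf[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    zbuf[kk] = sm;
    zbuf[kk + 1] = INFINITY;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[kk + 1] < q) ++kk;
    const double dq = (q - v[kk]) * s;
    d[q] = dq * dq + f[v[kk]];
  }
}

// Euclidean distance (physical units) from every voxel to the nearest
// seed voxel (on != 0). Off voxels start at a large finite sentinel rather
// than Inf so the envelope intersections stay well-defined; an all-off
// input therefore returns ~1e10, not Inf (callers reject empty masks).
// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector on, IntegerVector dim,
                        NumericVector spacing) {
  const int X = dim[0], Y = dim[1], Z = dim[2];
  NumericVector d((size_t)X * Y * Z);
  for (size_t i = 0; i < (size_t)X * Y * Z; ++i)
    d[i] = on[i] ? 0.0 : 1e20;
  const int nmax = std::max(X, std::max(Y, Z));
  std::vector<double> f(nmax), dd(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      double* row = d.begin() + (size_t)X * (y + (size_t)Y * z);
      dt1d(row, dd.data(), X, spacing[0], v, zbuf);
      std::copy(dd.begin(), dd.begin() + X, row);
    }
  // y pass
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < X; ++x) {
      for (int y = 0; y < Y; ++y) f[y] = d[x + (size_t)X * (y + (size_t)Y * z)];
      dt1d(f.data(), dd.data(), Y, spacing[1], v, zbuf);
      for (int y = 0; y < Y; ++y) d[x + (size_t)X * (y + (size_t)Y * z)] = dd[y];
    }
  // z pass
  for (int y = 0; y < Y; ++y)
    for (int x = 0; x < X; ++x) {
      for (int z = 0; z < Z; ++z) f[z] = d[x + (size_t)X * (y + (size_t)Y * z)];
      dt1d(f.data(), dd.data(), Z, spacing[2], v, zbuf);
      for (int z = 0; z < Z; ++z) d[x + (size_t)X * (y + (size_t)Y * z)] = dd[z];
    }
  for (size_t i = 0; i < (size_t)X * Y * Z; ++i) d[i] = std::sqrt(d[i]);
  d.attr("dim") = dim;
  return d;
}
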