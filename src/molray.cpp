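#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---- CRC-32 (IEEE 802.3), table computed on first use ----------------------

static uint32_t crc_table[256];
static bool crc_table_ready = false;

static void crc_init() {
  for (uint32_t n = 0; n < 256; ++n) {
    uint32_t c = n;
    for (int k = 0; k < 8; ++k)
      c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
    crc_table[n] = c;
  }
  crc_table_ready = true;
}

// [[Rcpp::export]]
double crc32_raw(RawVector data, double seed = 0) {
  if (!crc_table_ready) crc_init();
  uint32_t c = static_cast<uint32_t>(seed) ^ 0xFFFFFFFFu;
  const R_xlen_t n = data.size();
  for (R_xlen_t i = 0; i < n; ++i)
    c = crc_table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return static_cast<double>(c ^ 0xFFFFFFFFu);
}

// ---- PNG scanline unfiltering (filter types 0-4, 8-bit RGBA) ---------------

static inline int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export]]
RawVector png_unfilter(RawVector filtered, int height, int stride, int bpp) {
  if ((R_xlen_t)(height) * (stride + 1) != filtered.size())
    stop("filtered data length does not match height*(stride+1)");
  RawVector out((R_xlen_t)height * stride);
  std::vector<unsigned char> prev(stride, 0), cur(stride, 0);
  R_xlen_t src = 0;
  for (int row = 0; row < height; ++row) {
    int ft = filtered[src++];
    for (int i = 0; i < stride; ++i) {
      int x = filtered[src + i];
      int a = (i >= bpp) ? cur[i - bpp] : 0;
      int b = prev[i];
      int c = (i >= bpp) ? prev[i - bpp] : 0;
      int v;
      switch (ft) {
      case 0: v = x; break;
      case 1: v = x + a; break;
      case 2: v = x + b; break;
      case 3: v = x + ((a + b) >> 1); break;
      case 4: v = x + paeth(a, b, c); break;
      default: stop("unsupported PNG filter type %d", ft);
      }
      cur[i] = static_cast<unsigned char>(v & 0xFF);
    }
    src += stride;
    std::copy(cur.begin(), cur.end(), out.begin() + (R_xlen_t)row * stride);
    std::swap(prev, cur);
  }
  return out;
}

// ---- Exact squared Euclidean distance transform (separable) ----------------
// Felzenszwalb & Huttenlocher lower-envelope-of-parabolas 1-D transform,
// applied along each axis in turn; exact for arbitrary nonneg. inputs.

static void dt1d(const double* f, double* d, int* v, double* z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// like dt1d but also reports, for each output position, the input index
// (0-based) whose parabola realizes the minimum.
static void dt1d_arg(const double* f, double* d, int* arg, int* v, double* z,
                     int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
    arg[q] = v[k];
  }
}

// Feature transform: squared distance to the nearest site plus the linear
// (0-based) index of that site. vals: 0 (or nonneg seed) at sites, +Inf
// elsewhere.
// [[Rcpp::export]]
List edt3d_feature(NumericVector vals, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != vals.size()) stop("dims do not match length");
  NumericVector out = clone(vals);
  IntegerVector site(out.size());
  const double BIG = 1e20;
  for (R_xlen_t t = 0; t < out.size(); ++t) {
    site[t] = (int)t;
    if (out[t] == std::numeric_limits<double>::infinity()) out[t] = BIG;
  }
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax), arg(nmax), ids(nmax);

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) { f[i] = out[base + i]; ids[i] = site[base + i]; }
      dt1d_arg(f.data(), d.data(), arg.data(), v.data(), z.data(), nx);
      for (int i = 0; i < nx; ++i) {
        out[base + i] = d[i];
        site[base + i] = ids[arg[i]];
      }
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) {
        f[j] = out[base + (R_xlen_t)nx * j];
        ids[j] = site[base + (R_xlen_t)nx * j];
      }
      dt1d_arg(f.data(), d.data(), arg.data(), v.data(), z.data(), ny);
      for (int j = 0; j < ny; ++j) {
        out[base + (R_xlen_t)nx * j] = d[j];
        site[base + (R_xlen_t)nx * j] = ids[arg[j]];
      }
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t step = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) {
        f[k] = out[base + step * k];
        ids[k] = site[base + step * k];
      }
      dt1d_arg(f.data(), d.data(), arg.data(), v.data(), z.data(), nz);
      for (int k = 0; k < nz; ++k) {
        out[base + step * k] = d[k];
        site[base + step * k] = ids[arg[k]];
      }
    }
  return List::create(Named("sq") = out, Named("site") = site);
}

// vals: 0 at sites, +Inf elsewhere (or any nonneg squared seeds); dims c(nx,ny,nz)
// [[Rcpp::export]]
NumericVector edt3d_sq(NumericVector vals, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != vals.size()) stop("dims do not match length");
  NumericVector out = clone(vals);
  const double BIG = 1e20; // finite sentinel for "no site"; exceeds any grid distance
  for (R_xlen_t t = 0; t < out.size(); ++t)
    if (out[t] == std::numeric_limits<double>::infinity()) out[t] = BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) { f[i] = out[base + i]; }
      dt1d(f.data(), d.data(), v.data(), z.data(), nx);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) { f[j] = out[base + (R_xlen_t)nx * j]; }
      dt1d(f.data(), d.data(), v.data(), z.data(), ny);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t step = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) { f[k] = out[base + step * k]; }
      dt1d(f.data(), d.data(), v.data(), z.data(), nz);
      for (int k = 0; k < nz; ++k) out[base + step * k] = d[k];
    }
  return out;
}
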