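#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact anisotropic squared Euclidean distance transform
// (lower-envelope-of-parabolas algorithm, separable per axis).
// Distances are in physical units: grid position q on an axis with
// spacing d sits at physical coordinate q*d.

static const double DT_INF = 1e15; // sentinel: "no site on this line yet"
static const double REAL_INF = std::numeric_limits<double>::infinity();

// Lower envelope over the parabolas (x - q*spacing)^2 + f[q], built only
// from finite f entries: within a line of physical length n*spacing the
// squared offsets are tiny compared to DT_INF, so an empty-entry parabola
// can never contribute to the envelope once any real site exists.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double spacing) {
    int k = -1;
    for (int q = 0; q < n; ++q) {
        if (f[q] >= DT_INF) continue;
        double xq = q * spacing;
        if (k < 0) {
            k = 0;
            v[0] = q;
            z[0] = -REAL_INF;
            z[1] = REAL_INF;
            continue;
        }
        double s;
        for (;;) {
            double xv = v[k] * spacing;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
            if (s <= z[k]) --k; else break;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = REAL_INF;
    }
    if (k < 0) { // no sites anywhere on this line
        for (int q = 0; q < n; ++q) d[q] = DT_INF;
        return;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * spacing;
        while (z[k + 1] < xq) ++k;
        double diff = xq - v[k] * spacing;
        d[q] = diff * diff + f[v[k]];
    }
}

// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(LogicalVector mask, IntegerVector dims,
                          NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : DT_INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // x pass
    for (int kz = 0; kz < nz; ++kz)
        for (int ky = 0; ky < ny; ++ky) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
            for (int q = 0; q < nx; ++q) f[q] = out[base + q];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int q = 0; q < nx; ++q) out[base + q] = d[q];
        }
    // y pass
    for (int kz = 0; kz < nz; ++kz)
        for (int kx = 0; kx < nx; ++kx) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
            for (int q = 0; q < ny; ++q) f[q] = out[base + (R_xlen_t)q * nx];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int q = 0; q < ny; ++q) out[base + (R_xlen_t)q * nx] = d[q];
        }
    // z pass
    R_xlen_t slab = (R_xlen_t)nx * ny;
    for (int ky = 0; ky < ny; ++ky)
        for (int kx = 0; kx < nx; ++kx) {
            R_xlen_t base = (R_xlen_t)ky * nx + kx;
            for (int q = 0; q < nz; ++q) f[q] = out[base + (R_xlen_t)q * slab];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int q = 0; q < nz; ++q) out[base + (R_xlen_t)q * slab] = d[q];
        }
    return out;
}
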