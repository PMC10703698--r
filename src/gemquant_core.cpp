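#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large finite stand-in for +inf: keeps the lower-envelope intersection
// formula finite on all-empty scan lines (squared distances stay < 1e20).
static const double DT_INF = 1e20;

// 1D squared distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. f: input costs, d: output, n: length.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -DT_INF;
    z[1] = DT_INF;
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                (2.0 * q - 2.0 * v[k]);
            if (s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = DT_INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        double dq = (double)q - v[k];
        d[q] = dq * dq + f[v[k]];
    }
}

// Exact squared Euclidean distance transform of a 3D mask: for every voxel,
// squared distance (in voxel units) to the nearest TRUE voxel. Separable
// passes along x, y, z; column-major layout, dims = (nx, ny, nz).
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dim) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = mask[i] ? 0.0 : DT_INF;

    std::vector<double> f, d;

    // pass along x
    f.resize(nx); d.resize(nx);
    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            for (int i = 0; i < nx; ++i) f[i] = out[base + i];
            dt1d(f, d, nx);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    }
    // pass along y
    f.resize(ny); d.resize(ny);
    for (int k = 0; k < nz; ++k) {
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + (R_xlen_t)nx * ny * k;
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
            dt1d(f, d, ny);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
        }
    }
    // pass along z
    f.resize(nz); d.resize(nz);
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + (R_xlen_t)nx * j;
            for (int k = 0; k < nz; ++k) f[k] = out[base + nxy * k];
            dt1d(f, d, nz);
            for (int k = 0; k < nz; ++k) out[base + nxy * k] = d[k];
        }
    }
    return out;
}

// Connected-component labelling of a 3D mask under 6- (face) or
// 26- (face+edge+corner) connectivity. Labels are 1..n_components in
// first-encounter (column-major scan) order; background voxels get 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector labels(n);  // zero-initialised

    // neighbour offsets
    std::vector<int> dxs, dys, dzs;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (connectivity == 6 && manh != 1) continue;
                dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
            }
    const int nn = (int)dxs.size();

    std::vector<R_xlen_t> stack;
    int current = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || labels[s] != 0) continue;
        ++current;
        labels[s] = current;
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t idx = stack.back();
            stack.pop_back();
            int i = (int)(idx % nx);
            int j = (int)((idx / nx) % ny);
            int k = (int)(idx / ((R_xlen_t)nx * ny));
            for (int q = 0; q < nn; ++q) {
                int ii = i + dxs[q], jj = j + dys[q], kk = k + dzs[q];
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny ||
                    kk < 0 || kk >= nz) continue;
                R_xlen_t nidx = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
                if (mask[nidx] && labels[nidx] == 0) {
                    labels[nidx] = current;
                    stack.push_back(nidx);
                }
            }
        }
    }
    return labels;
}
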