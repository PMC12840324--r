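#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Neighbour offsets for 6-, 18- or 26-connectivity in 3D.
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
    std::vector<std::array<int, 3>> out;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int order = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (order == 0) continue;
                if (connectivity == 6 && order > 1) continue;
                if (connectivity == 18 && order > 2) continue;
                out.push_back({dx, dy, dz});
            }
    return out;
}

// BFS connected-component labelling of a binary 3D volume.
// Labels are assigned consecutively from 1 in raster-scan order of the
// first voxel encountered, which makes the labelling deterministic.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector vox, IntegerVector dims,
                                   int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
    IntegerVector labels(n, 0);
    std::vector<std::array<int, 3>> offs = neighbour_offsets(connectivity);
    std::vector<R_xlen_t> stack;
    int next_label = 0;

    for (R_xlen_t start = 0; start < n; ++start) {
        if (vox[start] == 0 || labels[start] != 0) continue;
        ++next_label;
        labels[start] = next_label;
        stack.clear();
        stack.push_back(start);
        while (!stack.empty()) {
            R_xlen_t idx = stack.back();
            stack.pop_back();
            int x = idx % nx;
            int y = (idx / nx) % ny;
            int z = idx / (static_cast<R_xlen_t>(nx) * ny);
            for (const auto &o : offs) {
                int xx = x + o[0], yy = y + o[1], zz = z + o[2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                R_xlen_t j = xx + static_cast<R_xlen_t>(nx) * (yy + static_cast<R_xlen_t>(ny) * zz);
                if (vox[j] != 0 && labels[j] == 0) {
                    labels[j] = next_label;
                    stack.push_back(j);
                }
            }
        }
    }
    labels.attr("n_components") = next_label;
    return labels;
}

// Boundary voxels: foreground voxels with at least one background
// 6-neighbour; voxels on the volume face count as boundary (out-of-grid
// is treated as background).
// [[Rcpp::export]]
LogicalVector boundary_voxels_cpp(IntegerVector vox, IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
    LogicalVector out(n, false);
    for (R_xlen_t idx = 0; idx < n; ++idx) {
        if (vox[idx] == 0) continue;
        int x = idx % nx;
        int y = (idx / nx) % ny;
        int z = idx / (static_cast<R_xlen_t>(nx) * ny);
        bool bnd = (x == 0 || x == nx - 1 || y == 0 || y == ny - 1 ||
                    z == 0 || z == nz - 1);
        if (!bnd) {
            const int dx[6] = {-1, 1, 0, 0, 0, 0};
            const int dy[6] = {0, 0, -1, 1, 0, 0};
            const int dz[6] = {0, 0, 0, 0, -1, 1};
            for (int k = 0; k < 6 && !bnd; ++k) {
                R_xlen_t j = (x + dx[k]) +
                    static_cast<R_xlen_t>(nx) * ((y + dy[k]) +
                    static_cast<R_xlen_t>(ny) * (z + dz[k]));
                if (vox[j] == 0) bnd = true;
            }
        }
        out[idx] = bnd;
    }
    return out;
}

// One-dimensional squared distance transform (Felzenszwalb & Huttenlocher)
// with physical sample spacing s: sample i sits at coordinate i*s.
static void dt1d(const double *f, double *d, int n, double s,
                 std::vector<int> &v, std::vector<double> &zbuf) {
    const double INF = std::numeric_limits<double>::infinity();
    v.resize(n);
    zbuf.resize(n + 1);
    int k = 0;
    v[0] = 0;
    zbuf[0] = -INF;
    zbuf[1] = INF;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF) continue;
        if (f[v[k]] == INF) { v[k] = q; continue; }
        double xq = q * s;
        double sline;
        while (true) {
            double xv = v[k] * s;
            sline = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
            if (sline <= zbuf[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        zbuf[k] = sline;
        zbuf[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * s;
        while (zbuf[k + 1] < xq) ++k;
        double xv = v[k] * s;
        d[q] = (f[v[k]] == INF) ? INF : (xq - xv) * (xq - xv) + f[v[k]];
    }
}

// Exact anisotropic squared Euclidean distance transform of a seed set.
// Returns, per voxel, the squared distance in mm to the nearest seed voxel
// centre (Inf when the seed set is empty).
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector seed, IntegerVector dims,
                              NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
    const double INF = std::numeric_limits<double>::infinity();
    NumericVector d(n);
    for (R_xlen_t i = 0; i < n; ++i) d[i] = seed[i] ? 0.0 : INF;

    std::vector<double> f(std::max(nx, std::max(ny, nz)));
    std::vector<double> g(f.size());
    std::vector<int> v;
    std::vector<double> zbuf;

    // pass along x
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
            R_xlen_t base = static_cast<R_xlen_t>(nx) * (y + static_cast<R_xlen_t>(ny) * z);
            for (int x = 0; x < nx; ++x) f[x] = d[base + x];
            dt1d(f.data(), g.data(), nx, spacing[0], v, zbuf);
            for (int x = 0; x < nx; ++x) d[base + x] = g[x];
        }
    // pass along y
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = x + static_cast<R_xlen_t>(nx) * ny * static_cast<R_xlen_t>(z);
            for (int y = 0; y < ny; ++y) f[y] = d[base + static_cast<R_xlen_t>(nx) * y];
            dt1d(f.data(), g.data(), ny, spacing[1], v, zbuf);
            for (int y = 0; y < ny; ++y) d[base + static_cast<R_xlen_t>(nx) * y] = g[y];
        }
    // pass along z
    const R_xlen_t plane = static_cast<R_xlen_t>(nx) * ny;
    for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = x + static_cast<R_xlen_t>(nx) * y;
            for (int z = 0; z < nz; ++z) f[z] = d[base + plane * z];
            dt1d(f.data(), g.data(), nz, spacing[2], v, zbuf);
            for (int z = 0; z < nz; ++z) d[base + plane * z] = g[z];
        }
    return d;
}
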