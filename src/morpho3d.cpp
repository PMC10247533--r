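#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large finite stand-in for "no background reachable"; distances in this
// package are < 1e4 um so squared values stay far below this.
static const double BIG = 1e30;

// 1D squared-distance transform (lower envelope of parabolas) with sample
// spacing s. f holds squared distances on input, d on output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double s) {
    int k = 0;
    v[0] = 0;
    z[0] = -BIG;
    z[1] = BIG;
    for (int q = 1; q < n; q++) {
        double sq = s * q;
        while (true) {
            double sv = s * v[k];
            double sep = (f[q] + sq * sq - f[v[k]] - sv * sv) / (2.0 * (sq - sv));
            if (k > 0 && sep <= z[k]) {
                k--;
            } else {
                k++;
                v[k] = q;
                z[k] = sep;
                z[k + 1] = BIG;
                break;
            }
        }
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        double sq = s * q;
        while (z[k + 1] < sq) k++;
        double dd = sq - s * v[k];
        d[q] = dd * dd + f[v[k]];
    }
}

// Squared Euclidean distance from every voxel to the nearest FALSE voxel,
// with per-axis physical spacing. dims = c(n1, n2, n3) in column-major
// order (n3 = 1 gives the 2D transform). Voxels outside the array are not
// considered background.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
    int n1 = dims[0], n2 = dims[1], n3 = dims.size() > 2 ? dims[2] : 1;
    R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? BIG : 0.0;

    int nmax = std::max(n1, std::max(n2, n3));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along axis 1 (stride 1)
    for (int k = 0; k < n3; k++)
        for (int j = 0; j < n2; j++) {
            R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
            for (int i = 0; i < n1; i++) f[i] = out[base + i];
            dt1d(f, d, v, z, n1, spacing[0]);
            for (int i = 0; i < n1; i++) out[base + i] = d[i];
        }
    // axis 2 (stride n1)
    for (int k = 0; k < n3; k++)
        for (int i = 0; i < n1; i++) {
            R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
            for (int j = 0; j < n2; j++) f[j] = out[base + (R_xlen_t)j * n1];
            dt1d(f, d, v, z, n2, spacing[1]);
            for (int j = 0; j < n2; j++) out[base + (R_xlen_t)j * n1] = d[j];
        }
    // axis 3 (stride n1*n2)
    if (n3 > 1) {
        R_xlen_t s3 = (R_xlen_t)n1 * n2;
        for (int j = 0; j < n2; j++)
            for (int i = 0; i < n1; i++) {
                R_xlen_t base = (R_xlen_t)j * n1 + i;
                for (int k = 0; k < n3; k++) f[k] = out[base + (R_xlen_t)k * s3];
                dt1d(f, d, v, z, n3, spacing[2]);
                for (int k = 0; k < n3; k++) out[base + (R_xlen_t)k * s3] = d[k];
            }
    }
    for (R_xlen_t i = 0; i < n; i++)
        if (out[i] >= BIG) out[i] = R_PosInf;
    return out;
}

// Connected-component labeling of a 3D (or 2D, n3 = 1) logical array.
// connectivity: 6 (faces) or 26 (faces, edges, corners). Labels are
// assigned in first-encounter (column-major) order starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
    int n1 = dims[0], n2 = dims[1], n3 = dims.size() > 2 ? dims[2] : 1;
    R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    IntegerVector lab(n, 0);

    std::vector<int> off1, off2, off3;
    for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
            for (int di = -1; di <= 1; di++) {
                if (di == 0 && dj == 0 && dk == 0) continue;
                int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
                if (connectivity == 6 && manh != 1) continue;
                off1.push_back(di);
                off2.push_back(dj);
                off3.push_back(dk);
            }
    int noff = (int)off1.size();

    std::vector<R_xlen_t> queue;
    queue.reserve(1024);
    int next = 0;
    for (R_xlen_t s = 0; s < n; s++) {
        if (!mask[s] || lab[s] != 0) continue;
        next++;
        lab[s] = next;
        queue.clear();
        queue.push_back(s);
        size_t head = 0;
        while (head < queue.size()) {
            R_xlen_t cur = queue[head++];
            int k = (int)(cur / ((R_xlen_t)n1 * n2));
            int rem = (int)(cur - (R_xlen_t)k * n1 * n2);
            int j = rem / n1;
            int i = rem - j * n1;
            for (int o = 0; o < noff; o++) {
                int ii = i + off1[o], jj = j + off2[o], kk = k + off3[o];
                if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
                    continue;
                R_xlen_t q = (R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1 + ii;
                if (mask[q] && lab[q] == 0) {
                    lab[q] = next;
                    queue.push_back(q);
                }
            }
        }
    }
    lab.attr("n_labels") = next;
    return lab;
}
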