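#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sentinel for "no site in this scan line"; squared pixel distances in any
// raster we handle are bounded far below this.
static const double BIG = 1e20;

// One-dimensional squared distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher). Exact for integer site positions.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
    int k = 0;
    v[0] = 0;
    z[0] = -BIG;
    z[1] = BIG;
    for (int q = 1; q < n; q++) {
        double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                   (2.0 * q - 2.0 * v[k]);
        while (s <= z[k]) {
            k--;
            s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
                (2.0 * q - 2.0 * v[k]);
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = BIG;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        while (z[k + 1] < q) k++;
        double dq = q - v[k];
        d[q] = dq * dq + f[v[k]];
    }
}

//' Exact squared Euclidean distance transform.
//'
//' For every pixel, the squared Euclidean distance (in pixel units, between
//' pixel centers) to the nearest TRUE pixel of `sites`. Cells of a raster
//' with no TRUE pixel at all come back >= 1e19 (treated as infinite by the
//' R wrappers).
//'
//' @param sites logical matrix of site pixels.
//' @return numeric matrix of squared distances.
//' @keywords internal
// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(LogicalMatrix sites) {
    int H = sites.nrow(), W = sites.ncol();
    NumericMatrix out(H, W);
    int n = (H > W) ? H : W;
    std::vector<double> f(n), d(n);
    std::vector<int> v(n);
    std::vector<double> z(n + 1);

    for (int c = 0; c < W; c++) {
        for (int r = 0; r < H; r++) f[r] = sites(r, c) ? 0.0 : BIG;
        dt1d(f, d, v, z, H);
        for (int r = 0; r < H; r++) out(r, c) = d[r];
    }
    for (int r = 0; r < H; r++) {
        for (int c = 0; c < W; c++) f[c] = out(r, c);
        dt1d(f, d, v, z, W);
        for (int c = 0; c < W; c++) out(r, c) = d[c];
    }
    return out;
}

//' Connected-component labeling with deterministic raster-scan label order.
//'
//' Components are numbered 1..k in the order their first pixel is met in a
//' row-major (row by row, left to right) scan.
//'
//' @param m logical matrix, TRUE = foreground.
//' @param connectivity 4 or 8.
//' @return integer matrix of labels, 0 = background.
//' @keywords internal
// [[Rcpp::export(name = ".label_cc")]]
IntegerMatrix label_cc(LogicalMatrix m, int connectivity) {
    int H = m.nrow(), W = m.ncol();
    IntegerMatrix lab(H, W);
    std::vector<int> stack;
    stack.reserve(1024);
    int nextLab = 0;
    static const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
    static const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1},
                     dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
    int nn = (connectivity == 8) ? 8 : 4;
    const int* dr = (connectivity == 8) ? dr8 : dr4;
    const int* dc = (connectivity == 8) ? dc8 : dc4;

    for (int r = 0; r < H; r++) {
        for (int c = 0; c < W; c++) {
            if (m(r, c) && lab(r, c) == 0) {
                nextLab++;
                lab(r, c) = nextLab;
                stack.push_back(r * W + c);
                while (!stack.empty()) {
                    int p = stack.back();
                    stack.pop_back();
                    int pr = p / W, pc = p % W;
                    for (int i = 0; i < nn; i++) {
                        int r2 = pr + dr[i], c2 = pc + dc[i];
                        if (r2 >= 0 && r2 < H && c2 >= 0 && c2 < W &&
                            m(r2, c2) && lab(r2, c2) == 0) {
                            lab(r2, c2) = nextLab;
                            stack.push_back(r2 * W + c2);
                        }
                    }
                }
            }
        }
    }
    return lab;
}

//' Boundary pixels of a binary region.
//'
//' A pixel is boundary if it is TRUE and at least one of its 8 neighbours is
//' FALSE or lies outside the raster.
//'
//' @param m logical matrix.
//' @return logical matrix of boundary pixels.
//' @keywords internal
// [[Rcpp::export(name = ".boundary_px")]]
LogicalMatrix boundary_px(LogicalMatrix m) {
    int H = m.nrow(), W = m.ncol();
    LogicalMatrix out(H, W);
    for (int r = 0; r < H; r++) {
        for (int c = 0; c < W; c++) {
            if (!m(r, c)) continue;
            bool edge = false;
            for (int i = -1; i <= 1 && !edge; i++) {
                for (int j = -1; j <= 1 && !edge; j++) {
                    if (i == 0 && j == 0) continue;
                    int r2 = r + i, c2 = c + j;
                    if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W || !m(r2, c2))
                        edge = true;
                }
            }
            out(r, c) = edge;
        }
    }
    return out;
}
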