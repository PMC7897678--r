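#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Seeded watershed flooding on a 3D grid (6-connectivity).
//
// Regions grow from seed voxels in order of decreasing intensity (priority
// flood on the inverted image); a voxel joins region r only if its intensity
// reaches the per-seed threshold thresh[r-1].  Ties are broken by insertion
// order, which makes the labelling deterministic for a fixed seed order.
// `seeds` are 0-based linear indices (x fastest, then y, then z).
// [[Rcpp::export]]
IntegerVector ws_flood3d(NumericVector img, IntegerVector dims,
                         IntegerVector seeds, NumericVector thresh) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double nxy = (double)nx * ny;
    const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
    if (img.size() != ntot) stop("image length does not match dims");
    if (seeds.size() != thresh.size()) stop("one threshold per seed required");
    IntegerVector lab(ntot, 0);

    struct Node { double v; long long ord; int idx; int lab; };
    struct Cmp {
        bool operator()(const Node& a, const Node& b) const {
            if (a.v != b.v) return a.v < b.v;  // pop highest intensity first
            return a.ord > b.ord;              // FIFO among equals
        }
    };
    std::priority_queue<Node, std::vector<Node>, Cmp> pq;

    long long ord = 0;
    for (int s = 0; s < seeds.size(); ++s) {
        int idx = seeds[s];
        if (idx < 0 || idx >= ntot) stop("seed index out of range");
        if (img[idx] < thresh[s]) continue;   // seed itself below threshold
        if (lab[idx] != 0) continue;          // duplicate seed voxel
        lab[idx] = s + 1;
        pq.push({img[idx], ord++, idx, s + 1});
    }

    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    while (!pq.empty()) {
        Node nd = pq.top(); pq.pop();
        const int z = (int)(nd.idx / (R_xlen_t)(nx * ny));
        const int rem = (int)(nd.idx % (R_xlen_t)(nx * ny));
        const int y = rem / nx, x = rem % nx;
        for (int k = 0; k < 6; ++k) {
            const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
            const R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (lab[j] != 0) continue;
            if (img[j] < thresh[nd.lab - 1]) continue;
            lab[j] = nd.lab;
            pq.push({img[j], ord++, (int)j, nd.lab});
        }
    }
    (void)nxy;
    return lab;
}

// 6-connected component labelling of a 3D logical mask; labels are assigned
// in raster order of the first voxel of each component.
// [[Rcpp::export]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
    if (mask.size() != ntot) stop("mask length does not match dims");
    IntegerVector lab(ntot, 0);
    std::vector<R_xlen_t> stack;
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    int next = 0;
    for (R_xlen_t i = 0; i < ntot; ++i) {
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back(); stack.pop_back();
            const int z = (int)(cur / (R_xlen_t)(nx * ny));
            const int rem = (int)(cur % (R_xlen_t)(nx * ny));
            const int y = rem / nx, x = rem % nx;
            for (int k = 0; k < 6; ++k) {
                const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz) continue;
                const R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
            }
        }
    }
    return lab;
}

// For each row of A (n x 3), the minimal Euclidean distance to any row of B.
// [[Rcpp::export]]
NumericVector nn_min_dist(NumericMatrix A, NumericMatrix B) {
    const int na = A.nrow(), nb = B.nrow();
    if (nb == 0) stop("B must be non-empty");
    NumericVector out(na);
    for (int i = 0; i < na; ++i) {
        const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
        double best = R_PosInf;
        for (int j = 0; j < nb; ++j) {
            const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < best) best = d2;
        }
        out[i] = std::sqrt(best);
    }
    return out;
}
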