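#include <Rcpp.h>
#include <deque>
#include <map>
using namespace Rcpp;

// Sliding min/max along the row index (within each column) with
// half-width w, using a monotonic deque; windows are truncated at the
// image border (min/max over in-bounds pixels only).
static NumericMatrix run_filter(const NumericMatrix &img, int w, bool maxf) {
    int nr = img.nrow(), nc = img.ncol();
    NumericMatrix out(nr, nc);
    std::vector<int> q(nr);
    for (int j = 0; j < nc; ++j) {
        const double *col = &img(0, j);
        double *oc = &out(0, j);
        int head = 0, tail = 0;            // queue is q[head..tail)
        for (int i = 0; i < nr + w; ++i) {
            if (i < nr) {
                double v = col[i];
                while (tail > head &&
                       (maxf ? col[q[tail - 1]] <= v
                             : col[q[tail - 1]] >= v))
                    --tail;
                q[tail++] = i;
            }
            int centre = i - w;
            if (centre >= 0) {
                while (q[head] < centre - w) ++head;
                oc[centre] = col[q[head]];
            }
        }
    }
    return out;
}

// Grayscale erosion (erode = true) or dilation with a disc structuring
// element of the given radius, decomposed into horizontal runs: the
// disc at column offset dj spans row offsets [-w(dj), w(dj)] with
// w(dj) = floor(sqrt(r^2 - dj^2)).
// [[Rcpp::export]]
NumericMatrix disc_morph(NumericMatrix img, int radius, bool erode) {
    int nr = img.nrow(), nc = img.ncol();
    bool maxf = !erode;
    std::map<int, NumericMatrix> cache;
    NumericMatrix out(nr, nc);
    double init = erode ? R_PosInf : R_NegInf;
    std::fill(out.begin(), out.end(), init);
    for (int dj = -radius; dj <= radius; ++dj) {
        int w = (int)std::floor(std::sqrt((double)radius * radius -
                                          (double)dj * dj));
        if (cache.find(w) == cache.end())
            cache.emplace(w, run_filter(img, w, maxf));
        const NumericMatrix &H = cache.at(w);
        int j0 = std::max(0, -dj), j1 = std::min(nc, nc - dj);
        for (int j = j0; j < j1; ++j) {
            const double *hj = &H(0, j + dj);
            double *oj = &out(0, j);
            if (erode) {
                for (int i = 0; i < nr; ++i)
                    if (hj[i] < oj[i]) oj[i] = hj[i];
            } else {
                for (int i = 0; i < nr; ++i)
                    if (hj[i] > oj[i]) oj[i] = hj[i];
            }
        }
    }
    return out;
}

// Two-pass connected-component labelling with union-find.
// connectivity: 4 or 8. Labels are 1..K in first-encounter order.

static int uf_find(std::vector<int> &parent, int x) {
    while (parent[x] != x) {
        parent[x] = parent[parent[x]];
        x = parent[x];
    }
    return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
    if (connectivity != 4 && connectivity != 8)
        stop("connectivity must be 4 or 8");
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> parent;
    parent.push_back(0); // dummy so labels are 1-based
    int next = 1;

    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (!mask(i, j)) continue;
            int l = 0;
            // previously visited neighbours in column-major order
            if (i > 0 && mask(i - 1, j)) l = lab(i - 1, j);
            if (j > 0) {
                if (mask(i, j - 1)) {
                    int m = lab(i, j - 1);
                    if (l && m != l) uf_union(parent, l, m);
                    if (!l || m < l) l = m;
                }
                if (connectivity == 8) {
                    if (i > 0 && mask(i - 1, j - 1)) {
                        int m = lab(i - 1, j - 1);
                        if (l && m != l) uf_union(parent, l, m);
                        if (!l || m < l) l = m;
                    }
                    if (i + 1 < nr && mask(i + 1, j - 1)) {
                        int m = lab(i + 1, j - 1);
                        if (l && m != l) uf_union(parent, l, m);
                        if (!l || m < l) l = m;
                    }
                }
            }
            if (!l) {
                l = next++;
                parent.push_back(l);
            }
            lab(i, j) = l;
        }
    }

    // resolve and renumber sequentially
    std::vector<int> remap(next, 0);
    int k = 0;
    for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i)
            if (lab(i, j)) {
                int r = uf_find(parent, lab(i, j));
                if (!remap[r]) remap[r] = ++k;
                lab(i, j) = remap[r];
            }
    return lab;
}
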