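#include <Rcpp.h>
using namespace Rcpp;

// Single-population coalescent under a piecewise-constant size history in the
// ms time scale: time in units of 4N0 generations, so k active lineages in a
// population of relative size x coalesce at rate k(k-1)/x, and the number of
// infinite-sites mutations is Poisson(theta * total branch length) with
// theta = 4 N0 mu per locus.  Size-change events (t_i, x_i) must be passed
// sorted by increasing time.  Uses R's RNG so results are reproducible via
// set.seed().

// [[Rcpp::export(name = ".simWindowCpp")]]
List simWindowCpp(int n, double theta, NumericVector eventTimes,
                  NumericVector eventSizes, bool haplotypes) {
    if (n < 2) stop("sample size must be >= 2");
    int nNodes = 2 * n - 1;
    std::vector<double> nodeTime(nNodes, 0.0);
    std::vector<int> left(nNodes, -1), right(nNodes, -1), parent(nNodes, -1);
    std::vector<int> active(n);
    for (int i = 0; i < n; ++i) active[i] = i;

    double t = 0.0, x = 1.0;
    int ei = 0, nev = eventTimes.size(), k = n, nxt = n;
    while (k > 1) {
        double rate = (double)k * (k - 1) / x;
        double w = exp_rand() / rate;
        if (ei < nev && t + w > eventTimes[ei]) {
            t = eventTimes[ei];
            x = eventSizes[ei];
            ++ei;
            continue;
        }
        t += w;
        int i = (int)(unif_rand() * k);
        if (i >= k) i = k - 1;
        int j = (int)(unif_rand() * (k - 1));
        if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        int a = active[i], b = active[j];
        nodeTime[nxt] = t;
        left[nxt] = a;
        right[nxt] = b;
        parent[a] = nxt;
        parent[b] = nxt;
        // remove i and j, append nxt
        if (i > j) std::swap(i, j);
        active[i] = nxt;
        active[j] = active[k - 1];
        ++nxt;
        --k;
    }

    int root = nNodes - 1;
    std::vector<double> blen(nNodes, 0.0);
    double ttot = 0.0;
    for (int v = 0; v < root; ++v) {
        blen[v] = nodeTime[parent[v]] - nodeTime[v];
        ttot += blen[v];
    }
    std::vector<int> nleaf(nNodes, 0);
    for (int v = 0; v < n; ++v) nleaf[v] = 1;
    for (int v = n; v < nNodes; ++v) nleaf[v] = nleaf[left[v]] + nleaf[right[v]];

    int S = (int)R::rpois(theta * ttot);
    IntegerVector counts(S);
    IntegerMatrix haps;
    if (haplotypes) haps = IntegerMatrix(n, S);

    if (S > 0) {
        // cumulative branch lengths for weighted branch choice
        std::vector<double> cum(root);
        double acc = 0.0;
        for (int v = 0; v < root; ++v) {
            acc += blen[v];
            cum[v] = acc;
        }
        std::vector<int> stack;
        for (int m = 0; m < S; ++m) {
            double u = unif_rand() * acc;
            int lo = 0, hi = root - 1;
            while (lo < hi) {
                int mid = (lo + hi) / 2;
                if (cum[mid] < u) lo = mid + 1; else hi = mid;
            }
            counts[m] = nleaf[lo];
            if (haplotypes) {
                stack.clear();
                stack.push_back(lo);
                while (!stack.empty()) {
                    int v = stack.back();
                    stack.pop_back();
                    if (v < n) haps(v, m) = 1;
                    else {
                        stack.push_back(left[v]);
                        stack.push_back(right[v]);
                    }
                }
            }
        }
    }
    List out = List::create(_["counts"] = counts, _["ttot"] = ttot);
    if (haplotypes) out["haplotypes"] = haps;
    return out;
}
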