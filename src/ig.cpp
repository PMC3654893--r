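#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Information gain (bits) of each attribute row with respect to each
// requested target row.  `bins` is a genes x samples integer matrix with
// values in 0..nbins-1; `targets` holds 1-based row indices.  The result
// is a genes x length(targets) matrix: out(a, j) = IG(T = targets[j], a).
// [[Rcpp::export]]
NumericMatrix ig_columns_cpp(IntegerMatrix bins, int nbins,
                             IntegerVector targets) {
    const int G = bins.nrow(), S = bins.ncol(), T = targets.size();
    if (S < 1) stop("at least one sample is required");
    NumericMatrix out(G, T);
    std::vector<int> joint(nbins * nbins);
    std::vector<int> tcount(nbins), acount(nbins);
    const double ln2 = std::log(2.0);
    // log2 lookup table for counts 0..S avoids most log() calls:
    // H = log2(n) - sum(c * log2(c)) / n over the nonzero cells
    std::vector<double> lg(S + 1);
    lg[0] = 0.0;
    for (int i = 1; i <= S; ++i) lg[i] = std::log((double)i) / ln2;
    std::vector<int> tb(S);
    for (int j = 0; j < T; ++j) {
        const int t = targets[j] - 1;
        if (t < 0 || t >= G) stop("target index out of range");
        for (int s = 0; s < S; ++s) {
            tb[s] = bins(t, s);
            if (tb[s] < 0 || tb[s] >= nbins) stop("bin index out of range");
        }
        std::fill(tcount.begin(), tcount.end(), 0);
        for (int s = 0; s < S; ++s) tcount[tb[s]]++;
        double ht = lg[S];
        for (int v = 0; v < nbins; ++v)
            if (tcount[v] > 0) ht -= tcount[v] * lg[tcount[v]] / S;
        for (int a = 0; a < G; ++a) {
            std::fill(joint.begin(), joint.end(), 0);
            std::fill(acount.begin(), acount.end(), 0);
            for (int s = 0; s < S; ++s) {
                const int av = bins(a, s);
                if (av < 0 || av >= nbins) stop("bin index out of range");
                joint[av * nbins + tb[s]]++;
                acount[av]++;
            }
            double cond = 0.0;
            for (int v = 0; v < nbins; ++v) {
                const int na = acount[v];
                if (na == 0) continue;
                double sum = 0.0;
                for (int w = 0; w < nbins; ++w) {
                    const int c = joint[v * nbins + w];
                    if (c > 0) sum += c * lg[c];
                }
                cond += ((double)na / S) * (lg[na] - sum / na);
            }
            double ig = ht - cond;
            out(a, j) = ig < 0.0 ? 0.0 : ig;
        }
    }
    return out;
}
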