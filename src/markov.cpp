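#include <Rcpp.h>
using namespace Rcpp;

// Two-state dinucleotide chain used by the genome simulator.
//
// Bases are drawn from `baseProbs` (order A, C, G, T) except immediately
// after a C, where P(G) is pinned to `pGAfterC` and the remaining mass is
// redistributed over A, C, T in proportion to their base probabilities.
// Setting pGAfterC = oe * P(G) makes the realized CpG observed/expected
// ratio track `oe` while GC content stays at the base composition, which an
// i.i.d. base model cannot do.
//
// Uses R's RNG (unif_rand) so set.seed() in R makes output reproducible.
// [[Rcpp::export(name = ".markov_dinuc")]]
std::string markov_dinuc(int n, NumericVector baseProbs, double pGAfterC) {
    static const char alphabet[4] = {'A', 'C', 'G', 'T'};
    if (n <= 0)
        return std::string();
    if (baseProbs.size() != 4)
        stop("baseProbs must have length 4 (A, C, G, T)");
    double total = 0.0;
    for (int i = 0; i < 4; ++i) {
        if (baseProbs[i] < 0)
            stop("base probabilities must be non-negative");
        total += baseProbs[i];
    }
    if (total <= 0)
        stop("base probabilities sum to zero");
    if (pGAfterC < 0 || pGAfterC >= 1)
        stop("pGAfterC must lie in [0, 1)");

    double q[4];
    for (int i = 0; i < 4; ++i)
        q[i] = baseProbs[i] / total;

    // distribution used for the base following a C
    double rest = q[0] + q[1] + q[3];
    if (rest <= 0)
        stop("A, C and T probabilities cannot all be zero");
    double qc[4];
    double scale = (1.0 - pGAfterC) / rest;
    qc[0] = q[0] * scale;
    qc[1] = q[1] * scale;
    qc[2] = pGAfterC;
    qc[3] = q[3] * scale;

    std::string out(n, 'A');
    int prev = -1; // index of previous base; 1 == C
    for (int i = 0; i < n; ++i) {
        double u = unif_rand();
        const double *p = (prev == 1) ? qc : q;
        double cum = 0.0;
        int b = 3;
        for (int j = 0; j < 4; ++j) {
            cum += p[j];
            if (u <= cum) {
                b = j;
                break;
            }
        }
        out[i] = alphabet[b];
        prev = b;
    }
    return out;
}
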