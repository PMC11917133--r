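#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-chromosome CLR scan kernel.  pos: sorted site positions (bp);
// cls: 1-based folded frequency class per site; logNull: log background
// probability per site; tab: log-probability lookup (rows: uniform grid in
// log(alpha*d) with origin lx0 and spacing dx, clamped at both ends;
// columns: folded classes).  For each grid position the sweep
// log-likelihood is maximized over the alpha grid with the neutral model
// included, giving CLR = 2 * (max logL - logL0) >= 0.
// [[Rcpp::export(name = ".clrScanChromCpp")]]
List clrScanChromCpp(NumericVector pos, IntegerVector cls,
                     NumericVector logNull, NumericMatrix tab,
                     double lx0, double dx, NumericVector gridPos,
                     NumericVector alphaGrid, double maxWindow) {
    const int nS = pos.size(), nG = gridPos.size(), nA = alphaGrid.size();
    const int nX = tab.nrow();
    NumericVector clr(nG), ah(nG, NA_REAL);
    std::vector<double> cumLn(nS + 1, 0.0);
    for (int i = 0; i < nS; ++i) cumLn[i + 1] = cumLn[i] + logNull[i];
    std::vector<double> logAlpha(nA);
    for (int a = 0; a < nA; ++a) logAlpha[a] = std::log(alphaGrid[a]);
    std::vector<double> logd;
    std::vector<int> kk;
    for (int g = 0; g < nG; ++g) {
        const double x = gridPos[g];
        const int lo = std::lower_bound(pos.begin(), pos.end(),
                                        x - maxWindow) - pos.begin();
        const int hi = std::upper_bound(pos.begin(), pos.end(),
                                        x + maxWindow) - pos.begin();
        if (hi <= lo) { clr[g] = 0.0; continue; }
        const int m = hi - lo;
        logd.resize(m);
        kk.resize(m);
        for (int s = 0; s < m; ++s) {
            double d = std::fabs(pos[lo + s] - x);
            if (d < 1.0) d = 1.0;
            logd[s] = std::log(d);
            kk[s] = cls[lo + s] - 1;
        }
        const double l0 = cumLn[hi] - cumLn[lo];
        double best = l0, bestA = NA_REAL;
        for (int a = 0; a < nA; ++a) {
            const double shift = logAlpha[a] - lx0;
            double ll = 0.0;
            for (int s = 0; s < m; ++s) {
                int bin = (int)std::floor((shift + logd[s]) / dx);
                if (bin < 0) bin = 0; else if (bin >= nX) bin = nX - 1;
                ll += tab(bin, kk[s]);
            }
            if (ll > best) { best = ll; bestA = alphaGrid[a]; }
        }
        clr[g] = 2.0 * (best - l0);
        ah[g] = bestA;
    }
    return List::create(_["clr"] = clr, _["alphaHat"] = ah);
}
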