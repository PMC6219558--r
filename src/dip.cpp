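#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Hartigan & Hartigan's dip statistic: the largest vertical distance between
// the empirical CDF and the closest unimodal CDF, found by cycling over
// candidate modal intervals [low, high].  Within each cycle the greatest
// convex minorant (GCM) is fitted below the modal interval and the least
// concave majorant (LCM) above it; the interval shrinks until the distance
// between the two fits drops below the dip accumulated so far.  All
// distances are carried in count units (2n * dip) and rescaled once at the
// end, so dip >= 1/(2n) on every input.
//
// x must be sorted ascending; 1-based indexing via offset pointers.
static double dip_sorted(const double *x_, int n)
{
    if (n < 2)
        return n == 1 ? 0.5 : 0.0;
    const double *x = x_ - 1; /* x[1..n] */
    if (x[n] == x[1] || n < 4)
        return 1.0 / (2.0 * n);

    std::vector<int> mn_(n + 2), mj_(n + 2), gcm_(n + 2), lcm_(n + 2);
    int *mn = mn_.data(), *mj = mj_.data(), *gcm = gcm_.data(), *lcm = lcm_.data();

    int low = 1, high = n;
    double D = 1.0; /* dip in 2n units; 1.0 <=> the 1/(2n) floor */

    for (;;) {
        /* GCM touch chain on [low, high]: mn[j] = previous touchpoint */
        mn[low] = low;
        for (int j = low + 1; j <= high; ++j) {
            mn[j] = j - 1;
            for (;;) {
                int mnj = mn[j];
                if (mnj == low) break;
                int mnmnj = mn[mnj];
                if ((x[j] - x[mnj]) * (mnj - mnmnj) <
                    (x[mnj] - x[mnmnj]) * (j - mnj)) break;
                mn[j] = mnmnj;
            }
        }
        /* LCM touch chain on [low, high]: mj[k] = next touchpoint */
        mj[high] = high;
        for (int k = high - 1; k >= low; --k) {
            mj[k] = k + 1;
            for (;;) {
                int mjk = mj[k];
                if (mjk == high) break;
                int mjmjk = mj[mjk];
                if ((x[k] - x[mjk]) * (mjk - mjmjk) <
                    (x[mjk] - x[mjmjk]) * (k - mjk)) break;
                mj[k] = mjmjk;
            }
        }

        /* collect GCM touchpoints high -> low, LCM touchpoints low -> high */
        int l_gcm, l_lcm, i;
        gcm[1] = high;
        for (i = 1; gcm[i] > low; ++i) gcm[i + 1] = mn[gcm[i]];
        l_gcm = i;
        lcm[1] = low;
        for (i = 1; lcm[i] < high; ++i) lcm[i + 1] = mj[lcm[i]];
        l_lcm = i;

        /* largest distance between the GCM and LCM curves on [low, high];
           ig/ih mark the touchpoints bracketing the new modal interval */
        int ig = l_gcm, ih = l_lcm;
        int ix = l_gcm - 1, iv = 2;
        double d = 0.0;
        if (l_gcm != 2 || l_lcm != 2) {
            do {
                int gcmix = gcm[ix], lcmiv = lcm[iv];
                double dx;
                if (gcmix > lcmiv) {
                    /* evaluate at the LCM touchpoint against the GCM chord */
                    int gcmi1 = gcm[ix + 1];
                    dx = (lcmiv - gcmi1 + 1) -
                        (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) /
                        (x[gcmix] - x[gcmi1]);
                    ++iv;
                    if (dx >= d) { d = dx; ig = ix + 1; ih = iv - 1; }
                } else {
                    /* evaluate at the GCM touchpoint against the LCM chord */
                    int lcmiv1 = lcm[iv - 1];
                    dx = (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
                        (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1);
                    --ix;
                    if (dx >= d) { d = dx; ig = ix + 1; ih = iv; }
                }
                if (ix < 1) ix = 1;
                if (iv > l_lcm) iv = l_lcm;
            } while (gcm[ix] != lcm[iv]);
        } else {
            d = 1.0;
        }
        if (d < D) break; /* converged */

        /* deviation of the empirical cdf from the GCM below the new modal
           interval, and from the LCM above it */
        double dip_l = 0.0;
        for (int j = ig; j < l_gcm; ++j) {
            double max_t = 1.0;
            int jb = gcm[j + 1], je = gcm[j];
            if (je - jb > 1 && x[je] != x[jb]) {
                double C = (je - jb) / (x[je] - x[jb]);
                for (int jj = jb; jj <= je; ++jj) {
                    double t = (jj - jb + 1) - (x[jj] - x[jb]) * C;
                    if (t > max_t) max_t = t;
                }
            }
            if (max_t > dip_l) dip_l = max_t;
        }
        double dip_u = 0.0;
        for (int j = ih; j < l_lcm; ++j) {
            double max_t = 1.0;
            int jb = lcm[j], je = lcm[j + 1];
            if (je - jb > 1 && x[je] != x[jb]) {
                double C = (je - jb) / (x[je] - x[jb]);
                for (int jj = jb; jj <= je; ++jj) {
                    double t = (x[jj] - x[jb]) * C - (jj - jb - 1);
                    if (t > max_t) max_t = t;
                }
            }
            if (max_t > dip_u) dip_u = max_t;
        }

        double dipnew = dip_l > dip_u ? dip_l : dip_u;
        if (dipnew > D) D = dipnew;

        int new_low = gcm[ig], new_high = lcm[ih];
        if (new_low == low && new_high == high) break; /* no shrink possible */
        low = new_low;
        high = new_high;
    }
    return D / (2.0 * n);
}

// [[Rcpp::export(name = ".dip_c")]]
double dip_c(Rcpp::NumericVector x)
{
    int n = x.size();
    std::vector<double> xs(x.begin(), x.end());
    std::sort(xs.begin(), xs.end());
    return dip_sorted(xs.data(), n);
}

// Dip statistics of `reps` uniform(0,1) samples of size n, drawn from R's
// RNG stream (so set.seed() governs reproducibility).
// [[Rcpp::export(name = ".dip_null_c")]]
Rcpp::NumericVector dip_null_c(int n, int reps)
{
    Rcpp::NumericVector out(reps);
    std::vector<double> xs(n);
    for (int r = 0; r < reps; ++r) {
        for (int i = 0; i < n; ++i) xs[i] = R::unif_rand();
        std::sort(xs.begin(), xs.end());
        out[r] = dip_sorted(xs.data(), n);
    }
    return out;
}
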