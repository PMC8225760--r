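#include <Rcpp.h>
using namespace Rcpp;

// Cavity rule evaluated at arbitrary query points: a point qualifies when
// its nearest-atom distance lies in [d_min, d_max] and at least `min_hits`
// of the supplied ray directions hit an atom (0 < projection <= ray_length
// and perpendicular distance <= hit_radius). Used for both grid nodes and
// Monte-Carlo samples so both routes share one rule.
// [[Rcpp::export(name = ".cavityRuleCpp")]]
LogicalVector cavityRuleCpp(NumericMatrix pts, NumericMatrix atoms,
                            double d_min, double d_max, NumericMatrix dirs,
                            int min_hits, double ray_length,
                            double hit_radius) {
    const int np = pts.nrow(), na = atoms.nrow(), nd = dirs.nrow();
    const double dmin2 = d_min * d_min, dmax2 = d_max * d_max;
    const double r2 = hit_radius * hit_radius;
    const double reach2 = ray_length * ray_length + r2;
    LogicalVector out(np);
    std::vector<double> rx(na), ry(na), rz(na), d2(na);
    for (int i = 0; i < np; ++i) {
        const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
        double best = R_PosInf;
        int nnear = 0;
        for (int j = 0; j < na; ++j) {
            const double dx = atoms(j, 0) - px;
            const double dy = atoms(j, 1) - py;
            const double dz = atoms(j, 2) - pz;
            const double dd = dx * dx + dy * dy + dz * dz;
            if (dd < best) best = dd;
            if (dd <= reach2) {
                rx[nnear] = dx; ry[nnear] = dy; rz[nnear] = dz;
                d2[nnear] = dd; ++nnear;
            }
        }
        if (best < dmin2 || best > dmax2) { out[i] = false; continue; }
        int hits = 0;
        for (int d = 0; d < nd; ++d) {
            const double ux = dirs(d, 0), uy = dirs(d, 1), uz = dirs(d, 2);
            for (int j = 0; j < nnear; ++j) {
                const double t = rx[j] * ux + ry[j] * uy + rz[j] * uz;
                if (t > 1e-9 && t <= ray_length && d2[j] - t * t <= r2) {
                    ++hits;
                    break;
                }
            }
            if (hits + (nd - d - 1) < min_hits) break;  // cannot reach
        }
        out[i] = hits >= min_hits;
    }
    return out;
}
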