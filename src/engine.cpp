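#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact voxel-traversal line integral of density along the segment p0 -> p1
// (Amanatides & Woo stepping on the Siddon parametrisation). Lengths in mm,
// density in g/cm^3; returns the integral in mm * g/cm^3. Portions of the
// segment outside the grid contribute zero.
static double traceLine(const double* dens, const int* dim,
                        const double* sp, const double* org,
                        const double* p0, const double* p1) {
    double d[3], lo[3], hi[3];
    double L2 = 0.0;
    for (int k = 0; k < 3; ++k) {
        d[k] = p1[k] - p0[k];
        L2 += d[k] * d[k];
        lo[k] = org[k] - 0.5 * sp[k];
        hi[k] = org[k] + (dim[k] - 0.5) * sp[k];
    }
    const double L = std::sqrt(L2);
    if (L <= 0.0) return 0.0;

    // clip the parametric interval [0, 1] to the grid bounding box
    double t0 = 0.0, t1 = 1.0;
    for (int k = 0; k < 3; ++k) {
        if (d[k] == 0.0) {
            if (p0[k] < lo[k] || p0[k] > hi[k]) return 0.0;
        } else {
            double ta = (lo[k] - p0[k]) / d[k];
            double tb = (hi[k] - p0[k]) / d[k];
            if (ta > tb) std::swap(ta, tb);
            if (ta > t0) t0 = ta;
            if (tb < t1) t1 = tb;
        }
    }
    if (t0 >= t1) return 0.0;

    const double eps = 1e-12;
    double start[3];
    int idx[3], step[3];
    double tMax[3], tDelta[3];
    for (int k = 0; k < 3; ++k) {
        start[k] = p0[k] + (t0 + eps) * d[k];
        int i = (int)std::floor((start[k] - lo[k]) / sp[k]);
        if (i < 0) i = 0;
        if (i > dim[k] - 1) i = dim[k] - 1;
        idx[k] = i;
        if (d[k] > 0.0) {
            step[k] = 1;
            tMax[k] = (lo[k] + (i + 1) * sp[k] - p0[k]) / d[k];
            tDelta[k] = sp[k] / d[k];
        } else if (d[k] < 0.0) {
            step[k] = -1;
            tMax[k] = (lo[k] + i * sp[k] - p0[k]) / d[k];
            tDelta[k] = -sp[k] / d[k];
        } else {
            step[k] = 0;
            tMax[k] = std::numeric_limits<double>::infinity();
            tDelta[k] = std::numeric_limits<double>::infinity();
        }
    }

    const R_xlen_t nx = dim[0], nxy = (R_xlen_t)dim[0] * dim[1];
    double acc = 0.0, tCur = t0;
    while (tCur < t1 - eps) {
        int ax = 0;
        if (tMax[1] < tMax[ax]) ax = 1;
        if (tMax[2] < tMax[ax]) ax = 2;
        double tNext = tMax[ax] < t1 ? tMax[ax] : t1;
        if (tNext > tCur) {
            R_xlen_t lin = idx[0] + nx * idx[1] + nxy * idx[2];
            acc += dens[lin] * (tNext - tCur) * L;
            tCur = tNext;
        }
        if (tMax[ax] >= t1) break;
        idx[ax] += step[ax];
        if (idx[ax] < 0 || idx[ax] >= dim[ax]) break;
        tMax[ax] += tDelta[ax];
    }
    return acc;
}

// [[Rcpp::export]]
double cppRadiologicalPath(NumericVector density, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           NumericVector p0, NumericVector p1) {
    // returns areal density in g/cm^2 (1 mm * g/cm^3 = 0.1 g/cm^2)
    return 0.1 * traceLine(REAL(density), INTEGER(dim), REAL(spacing),
                           REAL(origin), REAL(p0), REAL(p1));
}

// Primary (pre-scatter) dose of one divergent beam.
// dose(v) = weight * inAperture(v) * (SAD / d(v))^2 * exp(-muW * rp(src, v))
// with d(v) the distance from source along the beam axis, rp in g/cm^2 and
// muW in cm^2/g. The aperture is a logical raster in the isocentre plane of
// the beam's-eye view (pixel pitch du mm; (u0, w0) = centre of pixel [1,1]).
// [[Rcpp::export]]
NumericVector cppBeamDose(NumericVector density, IntegerVector dim,
                          NumericVector spacing, NumericVector origin,
                          NumericVector src, NumericVector axis,
                          NumericVector ex, NumericVector ez,
                          double sad, LogicalMatrix aperture,
                          double du, double u0, double w0,
                          double muW, double weight) {
    const int* dm = INTEGER(dim);
    const double* sp = REAL(spacing);
    const double* org = REAL(origin);
    const double* s = REAL(src);
    const double* a = REAL(axis);
    const double* eu = REAL(ex);
    const double* ew = REAL(ez);
    const int nu = aperture.nrow(), nw = aperture.ncol();
    const R_xlen_t n = (R_xlen_t)dm[0] * dm[1] * dm[2];
    NumericVector out(n);
    const double* dens = REAL(density);
    double* o = REAL(out);

    double v[3];
    R_xlen_t lin = 0;
    for (int iz = 0; iz < dm[2]; ++iz) {
        v[2] = org[2] + iz * sp[2];
        for (int iy = 0; iy < dm[1]; ++iy) {
            v[1] = org[1] + iy * sp[1];
            for (int ix = 0; ix < dm[0]; ++ix, ++lin) {
                v[0] = org[0] + ix * sp[0];
                double rel0 = v[0] - s[0], rel1 = v[1] - s[1], rel2 = v[2] - s[2];
                double dpar = rel0 * a[0] + rel1 * a[1] + rel2 * a[2];
                if (dpar < 1e-6) continue;  // behind the source
                double scale = sad / dpar;
                double u = (rel0 * eu[0] + rel1 * eu[1] + rel2 * eu[2]) * scale;
                double w = (rel0 * ew[0] + rel1 * ew[1] + rel2 * ew[2]) * scale;
                int iu = (int)std::lround((u - u0) / du);
                int iw = (int)std::lround((w - w0) / du);
                if (iu < 0 || iu >= nu || iw < 0 || iw >= nw) continue;
                if (!aperture(iu, iw)) continue;
                double rp = 0.1 * traceLine(dens, dm, sp, org, s, v);
                o[lin] = weight * scale * scale * std::exp(-muW * rp);
            }
        }
    }
    return out;
}

// Separable Gaussian convolution with kernel renormalised at the grid
// boundary (no mass is invented outside the grid). sigmaVox in voxels.
// [[Rcpp::export]]
NumericVector cppGaussBlur(NumericVector arr, IntegerVector dim,
                           NumericVector sigmaVox) {
    const int* dm = INTEGER(dim);
    const R_xlen_t n = (R_xlen_t)dm[0] * dm[1] * dm[2];
    NumericVector cur = clone(arr);

    R_xlen_t stride[3] = {1, (R_xlen_t)dm[0], (R_xlen_t)dm[0] * dm[1]};
    for (int ax = 0; ax < 3; ++ax) {
        double sg = REAL(sigmaVox)[ax];
        if (sg <= 0.0) continue;
        int rad = (int)std::ceil(3.5 * sg);
        std::vector<double> ker(2 * rad + 1);
        for (int k = -rad; k <= rad; ++k)
            ker[k + rad] = std::exp(-0.5 * (k / sg) * (k / sg));

        NumericVector nxt(n);
        const double* in = REAL(cur);
        double* out = REAL(nxt);
        const int len = dm[ax];
        const R_xlen_t st = stride[ax];
        // iterate over all 1-d lines along axis `ax`
        int odim[2];
        R_xlen_t ostr[2];
        int j = 0;
        for (int k = 0; k < 3; ++k)
            if (k != ax) { odim[j] = dm[k]; ostr[j] = stride[k]; ++j; }
        for (int b = 0; b < odim[1]; ++b) {
            for (int a2 = 0; a2 < odim[0]; ++a2) {
                R_xlen_t base = a2 * ostr[0] + b * ostr[1];
                for (int i = 0; i < len; ++i) {
                    int k0 = i - rad < 0 ? -i : -rad;
                    int k1 = i + rad >= len ? len - 1 - i : rad;
                    double s = 0.0, wsum = 0.0;
                    for (int k = k0; k <= k1; ++k) {
                        double wk = ker[k + rad];
                        s += wk * in[base + (R_xlen_t)(i + k) * st];
                        wsum += wk;
                    }
                    out[base + (R_xlen_t)i * st] = s / wsum;
                }
            }
        }
        cur = nxt;
    }
    return cur;
}
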