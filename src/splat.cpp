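#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel-driven pinhole projector. Every voxel centre is rotated about the
// z axis (the rotation axis), mapped through each aperture sample point onto
// the detector plane, and bilinearly splatted into the frame with a
// solid-angle weight cos^3(psi) * b^2 / r^2 (normalized so that an on-axis
// voxel in the pinhole plane has weight ~1). The adjoint gathers with the
// same rays and weights, so the pair is an exact matrix transpose.
//
// Conventions: pinhole centre at (0, b, 0); detector plane y = b + f with
// u along +x, v along +z, origin at the detector centre; frame pixel (iu,
// iv) centre at u = (iu + 0.5 - nu/2) * pitch (0-based iu). Volumes are
// column-major [nx, ny, nz] with voxel centres origin + (i + 0.5) * voxel.
//
// Loop structure: for fixed (angle, x, y, aperture sample) the detector u
// coordinate and the transverse part of the ray are independent of z, so
// they are hoisted out of the z loop; only v and the solid-angle weight
// vary along a voxel column.

struct ColumnRay {
    bool ok;
    int iu0;
    double du;      // u interpolation fraction
    double s;       // magnification f / (b - yr)
    double az;      // aperture z offset
    double dxy2;    // transverse squared distance voxel -> aperture point
    double dy3b2;   // dy^3 * b^2 (weight numerator)
};

static inline void column_ray(double xr, double yr, double b, double f,
                              double ax, double az, double pitch, int nu,
                              ColumnRay &cr) {
    cr.ok = false;
    double dy = b - yr;
    if (dy <= 1e-9) return;
    double dx = ax - xr;
    cr.s = f / dy;
    double u = ax + cr.s * dx;
    double fu = u / pitch + 0.5 * nu - 0.5;
    int iu0 = (int)std::floor(fu);
    if (iu0 < -1 || iu0 > nu - 1) return;
    cr.iu0 = iu0;
    cr.du = fu - iu0;
    cr.az = az;
    cr.dxy2 = dx * dx + dy * dy;
    cr.dy3b2 = dy * dy * dy * b * b;
    cr.ok = true;
}

// weight and v-position of the voxel at height pz along this column ray
static inline bool ray_at_z(const ColumnRay &cr, double pz, double pitch,
                            int nv, int &iv0, double &dv, double &w) {
    double dz = cr.az - pz;
    double r2 = cr.dxy2 + dz * dz;
    w = cr.dy3b2 / (r2 * r2 * std::sqrt(r2));
    double v = cr.az + cr.s * dz;
    double fv = v / pitch + 0.5 * nv - 0.5;
    iv0 = (int)std::floor(fv);
    if (iv0 < -1 || iv0 > nv - 1) return false;
    dv = fv - iv0;
    return true;
}

// [[Rcpp::export]]
NumericVector splat_forward_cpp(NumericVector vol, IntegerVector voldim,
                                NumericVector voxel, NumericVector origin,
                                NumericVector angles_rad,
                                double b, double f,
                                NumericMatrix aper,
                                int nu, int nv, double pitch, double scale) {
    const int nx = voldim[0], ny = voldim[1], nz = voldim[2];
    const int nang = angles_rad.size();
    const int nap = aper.nrow();
    NumericVector frames(static_cast<R_xlen_t>(nu) * nv * nang);
    const double *pv = vol.begin();
    double *pf = frames.begin();
    const R_xlen_t plane = static_cast<R_xlen_t>(nx) * ny;
    std::vector<ColumnRay> rays(nap);
    for (int a = 0; a < nang; ++a) {
        double ca = std::cos(angles_rad[a]);
        double sa = std::sin(angles_rad[a]);
        double *frame = pf + static_cast<R_xlen_t>(a) * nu * nv;
        for (int j = 0; j < ny; ++j) {
            double py = origin[1] + (j + 0.5) * voxel[1];
            for (int i = 0; i < nx; ++i) {
                double px = origin[0] + (i + 0.5) * voxel[0];
                double xr = px * ca - py * sa;
                double yr = px * sa + py * ca;
                bool any = false;
                for (int q = 0; q < nap; ++q) {
                    column_ray(xr, yr, b, f, aper(q, 0), aper(q, 1),
                               pitch, nu, rays[q]);
                    any = any || rays[q].ok;
                }
                if (!any) continue;
                const double *col = pv + i + static_cast<R_xlen_t>(nx) * j;
                for (int k = 0; k < nz; ++k) {
                    double val = col[plane * k];
                    if (val == 0.0) continue;
                    double pz = origin[2] + (k + 0.5) * voxel[2];
                    for (int q = 0; q < nap; ++q) {
                        if (!rays[q].ok) continue;
                        int iv0; double dv, w;
                        if (!ray_at_z(rays[q], pz, pitch, nv, iv0, dv, w))
                            continue;
                        double c = val * w * scale;
                        int iu0 = rays[q].iu0;
                        double du = rays[q].du;
                        double *base = frame + iu0 + static_cast<R_xlen_t>(nu) * iv0;
                        if (iu0 >= 0 && iv0 >= 0)
                            base[0] += c * (1 - du) * (1 - dv);
                        if (iu0 + 1 < nu && iv0 >= 0)
                            base[1] += c * du * (1 - dv);
                        if (iu0 >= 0 && iv0 + 1 < nv)
                            base[nu] += c * (1 - du) * dv;
                        if (iu0 + 1 < nu && iv0 + 1 < nv)
                            base[nu + 1] += c * du * dv;
                    }
                }
            }
        }
    }
    return frames;
}

// [[Rcpp::export]]
NumericVector splat_adjoint_cpp(NumericVector frames, IntegerVector voldim,
                                NumericVector voxel, NumericVector origin,
                                NumericVector angles_rad,
                                double b, double f,
                                NumericMatrix aper,
                                int nu, int nv, double pitch, double scale) {
    const int nx = voldim[0], ny = voldim[1], nz = voldim[2];
    const int nang = angles_rad.size();
    const int nap = aper.nrow();
    NumericVector vol(static_cast<R_xlen_t>(nx) * ny * nz);
    double *pv = vol.begin();
    const double *pf = frames.begin();
    const R_xlen_t plane = static_cast<R_xlen_t>(nx) * ny;
    std::vector<ColumnRay> rays(nap);
    for (int a = 0; a < nang; ++a) {
        double ca = std::cos(angles_rad[a]);
        double sa = std::sin(angles_rad[a]);
        const double *frame = pf + static_cast<R_xlen_t>(a) * nu * nv;
        for (int j = 0; j < ny; ++j) {
            double py = origin[1] + (j + 0.5) * voxel[1];
            for (int i = 0; i < nx; ++i) {
                double px = origin[0] + (i + 0.5) * voxel[0];
                double xr = px * ca - py * sa;
                double yr = px * sa + py * ca;
                bool any = false;
                for (int q = 0; q < nap; ++q) {
                    column_ray(xr, yr, b, f, aper(q, 0), aper(q, 1),
                               pitch, nu, rays[q]);
                    any = any || rays[q].ok;
                }
                if (!any) continue;
                double *col = pv + i + static_cast<R_xlen_t>(nx) * j;
                for (int k = 0; k < nz; ++k) {
                    double pz = origin[2] + (k + 0.5) * voxel[2];
                    double acc = 0.0;
                    for (int q = 0; q < nap; ++q) {
                        if (!rays[q].ok) continue;
                        int iv0; double dv, w;
                        if (!ray_at_z(rays[q], pz, pitch, nv, iv0, dv, w))
                            continue;
                        int iu0 = rays[q].iu0;
                        double du = rays[q].du;
                        const double *base = frame + iu0 + static_cast<R_xlen_t>(nu) * iv0;
                        double g = 0.0;
                        if (iu0 >= 0 && iv0 >= 0)
                            g += base[0] * (1 - du) * (1 - dv);
                        if (iu0 + 1 < nu && iv0 >= 0)
                            g += base[1] * du * (1 - dv);
                        if (iu0 >= 0 && iv0 + 1 < nv)
                            g += base[nu] * (1 - du) * dv;
                        if (iu0 + 1 < nu && iv0 + 1 < nv)
                            g += base[nu + 1] * du * dv;
                        acc += g * w;
                    }
                    if (acc != 0.0) col[plane * k] += acc * scale;
                }
            }
        }
    }
    return vol;
}
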