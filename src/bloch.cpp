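#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gyromagnetic ratio of 31P in Hz per microtesla (17.235 MHz/T).
static const double GAMMA_P31_HZ_PER_UT = 17.235;
static const double TWO_PI = 6.283185307179586476925286766559;

// Rotation matrix R = exp([w]x) for rotation vector w (Rodrigues).
static inline void rodrigues(const double w[3], double R[9]) {
    double th2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
    double th = std::sqrt(th2);
    double A, B;
    if (th < 1e-9) {
        // series: sin(th)/th, (1-cos th)/th^2
        A = 1.0 - th2 / 6.0;
        B = 0.5 - th2 / 24.0;
    } else {
        A = std::sin(th) / th;
        B = (1.0 - std::cos(th)) / th2;
    }
    // R = I + A [w]x + B [w]x^2
    double wx = w[0], wy = w[1], wz = w[2];
    R[0] = 1.0 + B * (-wy * wy - wz * wz);
    R[1] = -A * wz + B * wx * wy;
    R[2] = A * wy + B * wx * wz;
    R[3] = A * wz + B * wx * wy;
    R[4] = 1.0 + B * (-wx * wx - wz * wz);
    R[5] = -A * wx + B * wy * wz;
    R[6] = -A * wy + B * wx * wz;
    R[7] = A * wx + B * wy * wz;
    R[8] = 1.0 + B * (-wx * wx - wy * wy);
}

static inline void matvec(const double R[9], const double v[3], double out[3]) {
    out[0] = R[0] * v[0] + R[1] * v[1] + R[2] * v[2];
    out[1] = R[3] * v[0] + R[4] * v[1] + R[5] * v[2];
    out[2] = R[6] * v[0] + R[7] * v[1] + R[8] * v[2];
}

static inline void mattvec(const double R[9], const double v[3], double out[3]) {
    out[0] = R[0] * v[0] + R[3] * v[1] + R[6] * v[2];
    out[1] = R[1] * v[0] + R[4] * v[1] + R[7] * v[2];
    out[2] = R[2] * v[0] + R[5] * v[1] + R[8] * v[2];
}

// Derivative of R = exp([w]x) with respect to w_k (Gallego & Yezzi closed
// form), applied to a vector v: out = (dR/dw_k) v.
static inline void drot_dwk_times_v(const double w[3], const double R[9],
                                    int k, const double v[3], double out[3]) {
    double th2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
    double Rv[3];
    matvec(R, v, Rv);
    if (th2 < 1e-14) {
        // dR/dw_k -> [e_k]x as w -> 0
        double ek[3] = {0.0, 0.0, 0.0};
        ek[k] = 1.0;
        out[0] = ek[1] * Rv[2] - ek[2] * Rv[1];
        out[1] = ek[2] * Rv[0] - ek[0] * Rv[2];
        out[2] = ek[0] * Rv[1] - ek[1] * Rv[0];
        return;
    }
    // u = w x ((I - R) e_k);  dR/dw_k = (w_k [w]x + [u]x) / th2 * R
    double col[3] = {R[k], R[3 + k], R[6 + k]};      // R e_k
    double imr[3] = {-col[0], -col[1], -col[2]};
    imr[k] += 1.0;                                    // (I - R) e_k
    double u[3] = {w[1] * imr[2] - w[2] * imr[1],
                   w[2] * imr[0] - w[0] * imr[2],
                   w[0] * imr[1] - w[1] * imr[0]};
    double wk = w[k];
    out[0] = (wk * (w[1] * Rv[2] - w[2] * Rv[1]) + (u[1] * Rv[2] - u[2] * Rv[1])) / th2;
    out[1] = (wk * (w[2] * Rv[0] - w[0] * Rv[2]) + (u[2] * Rv[0] - u[0] * Rv[2])) / th2;
    out[2] = (wk * (w[0] * Rv[1] - w[1] * Rv[0]) + (u[0] * Rv[1] - u[1] * Rv[0])) / th2;
}

struct Relax {
    double e1, e2, dz;
    Relax(double dt, double t1, double t2, double m0) {
        e1 = std::isfinite(t1) ? std::exp(-dt / t1) : 1.0;
        e2 = std::isfinite(t2) ? std::exp(-dt / t2) : 1.0;
        dz = m0 * (1.0 - e1);
    }
};

// One full pulse played at one offset; M modified in place.
// Evolution per sample: exact rotation about the effective field,
// then T1/T2 relaxation toward (0, 0, m0) (operator splitting).
static void run_pulse(const double* ure, const double* uim, int n, double dwell,
                      double offset_hz, double scale, const Relax& rx,
                      double M[3]) {
    double g = TWO_PI * GAMMA_P31_HZ_PER_UT * scale;
    double wz = -dwell * TWO_PI * offset_hz;
    double w[3], R[9], tmp[3];
    for (int j = 0; j < n; ++j) {
        w[0] = -dwell * g * ure[j];
        w[1] = -dwell * g * uim[j];
        w[2] = wz;
        rodrigues(w, R);
        matvec(R, M, tmp);
        M[0] = rx.e2 * tmp[0];
        M[1] = rx.e2 * tmp[1];
        M[2] = rx.e1 * tmp[2] + rx.dz;
    }
}

// [[Rcpp::export(name = ".cpp_simulate_pulse")]]
NumericMatrix cpp_simulate_pulse(NumericVector ure, NumericVector uim,
                                 double dwell, NumericVector offsets_hz,
                                 double b1_scale, double t1, double t2,
                                 double m0, NumericVector minit) {
    int n = ure.size(), noff = offsets_hz.size();
    Relax rx(dwell, t1, t2, m0);
    NumericMatrix out(3, noff);
    for (int i = 0; i < noff; ++i) {
        double M[3] = {minit[0], minit[1], minit[2]};
        run_pulse(&ure[0], &uim[0], n, dwell, offsets_hz[i], b1_scale, rx, M);
        out(0, i) = M[0];
        out(1, i) = M[1];
        out(2, i) = M[2];
    }
    return out;
}

// Repeated subpulse train with ideal crushers (Mxy -> 0) between repeats.
// Returns final magnetization per (scale, offset) as mz and |mxy| grids.
// [[Rcpp::export(name = ".cpp_chain_map")]]
List cpp_chain_map(NumericVector ure, NumericVector uim, double dwell,
                   int nrep, NumericVector offsets_hz, NumericVector b1_scales,
                   double t1, double t2, double m0,
                   bool crusher_between, bool crusher_after,
                   double idle_seconds) {
    int n = ure.size(), noff = offsets_hz.size(), nsc = b1_scales.size();
    Relax rx(dwell, t1, t2, m0);
    // idle time after the last repeat (chain shorter than total duration):
    // free relaxation toward equilibrium, transverse decay.
    double ei1 = std::isfinite(t1) ? std::exp(-idle_seconds / t1) : 1.0;
    double ei2 = std::isfinite(t2) ? std::exp(-idle_seconds / t2) : 1.0;
    NumericMatrix mz(nsc, noff), amxy(nsc, noff);
    for (int s = 0; s < nsc; ++s) {
        for (int i = 0; i < noff; ++i) {
            double M[3] = {0.0, 0.0, m0};
            for (int r = 0; r < nrep; ++r) {
                run_pulse(&ure[0], &uim[0], n, dwell, offsets_hz[i],
                          b1_scales[s], rx, M);
                if (crusher_between && r < nrep - 1) { M[0] = 0.0; M[1] = 0.0; }
            }
            if (idle_seconds > 0.0) {
                // precession during idle does not change |mxy| or mz
                M[0] *= ei2; M[1] *= ei2;
                M[2] = m0 + (M[2] - m0) * ei1;
            }
            if (crusher_after) { M[0] = 0.0; M[1] = 0.0; }
            mz(s, i) = M[2];
            amxy(s, i) = std::sqrt(M[0] * M[0] + M[1] * M[1]);
        }
    }
    return List::create(_["mz"] = mz, _["abs_mxy"] = amxy);
}

// Trajectory of mz after each repeat of the chain at a single
// (offset, scale); crushers between repeats if requested.
// [[Rcpp::export(name = ".cpp_chain_traj")]]
NumericVector cpp_chain_traj(NumericVector ure, NumericVector uim, double dwell,
                             int nrep, double offset_hz, double b1_scale,
                             double t1, double t2, double m0,
                             bool crusher_between) {
    int n = ure.size();
    Relax rx(dwell, t1, t2, m0);
    NumericVector mz(nrep);
    double M[3] = {0.0, 0.0, m0};
    for (int r = 0; r < nrep; ++r) {
        run_pulse(&ure[0], &uim[0], n, dwell, offset_hz, b1_scale, rx, M);
        mz[r] = M[2];
        if (crusher_between && r < nrep - 1) { M[0] = 0.0; M[1] = 0.0; }
    }
    return mz;
}

// Cost and adjoint gradient of the optimal-control objective
//   J = 1/2 sum_i sum_c W[c,i] (M[c,i](T) - Md[c,i])^2
//       + lambda/2 sum_j (ux_j^2 + uy_j^2) dt
// with respect to the RF samples (ux, uy) in microtesla.  The forward model
// is the stepped rotation/relaxation evolution of run_pulse starting from
// equilibrium (0, 0, m0).  The gradient is exact for that discrete model
// (adjoint state method with the closed-form rotation-matrix derivative).
// [[Rcpp::export(name = ".cpp_oc_cost_grad")]]
List cpp_oc_cost_grad(NumericVector ure, NumericVector uim, double dwell,
                      NumericVector offsets_hz, NumericMatrix weights,
                      NumericMatrix target, double lambda, double b1_scale,
                      double t1, double t2, double m0) {
    int n = ure.size(), noff = offsets_hz.size();
    Relax rx(dwell, t1, t2, m0);
    double g = TWO_PI * GAMMA_P31_HZ_PER_UT * b1_scale;
    double cu = -dwell * g;   // dw_{x,y} / du_{x,y}
    std::vector<double> traj(3 * (n + 1));
    NumericVector gre(n), gim(n);
    double cost = 0.0;
    double w[3], R[9], tmp[3], dv[3];
    for (int i = 0; i < noff; ++i) {
        double wz = -dwell * TWO_PI * offsets_hz[i];
        // forward pass, storing the state before each sample
        double M[3] = {0.0, 0.0, m0};
        for (int j = 0; j < n; ++j) {
            traj[3 * j] = M[0]; traj[3 * j + 1] = M[1]; traj[3 * j + 2] = M[2];
            w[0] = -dwell * g * ure[j];
            w[1] = -dwell * g * uim[j];
            w[2] = wz;
            rodrigues(w, R);
            matvec(R, M, tmp);
            M[0] = rx.e2 * tmp[0];
            M[1] = rx.e2 * tmp[1];
            M[2] = rx.e1 * tmp[2] + rx.dz;
        }
        traj[3 * n] = M[0]; traj[3 * n + 1] = M[1]; traj[3 * n + 2] = M[2];
        // terminal misfit and adjoint seed
        double p[3];
        for (int c = 0; c < 3; ++c) {
            double r = M[c] - target(c, i);
            cost += 0.5 * weights(c, i) * r * r;
            p[c] = weights(c, i) * r;
        }
        // backward pass
        for (int j = n - 1; j >= 0; --j) {
            w[0] = -dwell * g * ure[j];
            w[1] = -dwell * g * uim[j];
            w[2] = wz;
            rodrigues(w, R);
            // q = D^T p  (D diagonal)
            double q[3] = {rx.e2 * p[0], rx.e2 * p[1], rx.e1 * p[2]};
            const double* Mj = &traj[3 * j];
            double Mjv[3] = {Mj[0], Mj[1], Mj[2]};
            drot_dwk_times_v(w, R, 0, Mjv, dv);
            gre[j] += cu * (q[0] * dv[0] + q[1] * dv[1] + q[2] * dv[2]);
            drot_dwk_times_v(w, R, 1, Mjv, dv);
            gim[j] += cu * (q[0] * dv[0] + q[1] * dv[1] + q[2] * dv[2]);
            // p_j = R^T q
            mattvec(R, q, p);
        }
    }
    // RF power penalty
    double pen = 0.0;
    for (int j = 0; j < n; ++j) {
        pen += ure[j] * ure[j] + uim[j] * uim[j];
        gre[j] += lambda * ure[j] * dwell;
        gim[j] += lambda * uim[j] * dwell;
    }
    cost += 0.5 * lambda * pen * dwell;
    return List::create(_["cost"] = cost, _["grad_re"] = gre,
                        _["grad_im"] = gim);
}
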