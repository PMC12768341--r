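/* Compiled derivative function for the oxidative phosphorylation model.
 *
 * Called by deSolve (func = "ox_derivs", initfunc = "ox_init",
 * dllname = "oxphosim").  State ordering matches R/ox_state_names();
 * parameter ordering matches R/.ox_parvec(); the 18 output slots are the
 * fluxes in R/ox_flux_names() order.
 */

#include <R.h>
#include <math.h>

static double p[40];

void ox_init(void (*odeparms)(int *, double *))
{
    int n = 40;
    odeparms(&n, p);
}

#define x_CI     p[0]
#define x_CIII   p[1]
#define x_CIV    p[2]
#define x_F1     p[3]
#define x_Hle    p[4]
#define x_DH     p[5]
#define K_dyn    p[6]
#define K_cons   p[7]
#define c_CI     p[8]
#define c_CIII   p[9]
#define c_CIV    p[10]
#define c_F1     p[11]
#define c_Hle    p[12]
#define c_DH     p[13]
#define c_dyn    p[14]
#define c_cons   p[15]
#define a_ANT    p[16]
#define a_PiC    p[17]
#define a_Kuni   p[18]
#define a_KHE    p[19]
#define a_exH    p[20]
#define a_exK    p[21]
#define k_CI     p[22]
#define k_CIII   p[23]
#define k_CIV    p[24]
#define keq_F1   p[25]
#define n_F1     p[26]
#define r_DH     p[27]
#define rho_nadh p[28]
#define rho_qh2  p[29]
#define k_clr_m  p[30]
#define k_diff   p[31]
#define k_clr_c  p[32]
#define K_O2     p[33]
#define rt_f     p[34]
#define c_mem    p[35]
#define W_m      p[36]
#define W_i      p[37]
#define V_c      p[38]
#define beta_pH  p[39]

void ox_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double dpsi = y[0], nadh = y[1], nad = y[2], q = y[3], qh2 = y[4];
    double cred = y[5], cox = y[6], o2 = y[7];
    double atp_m = y[8], adp_m = y[9], pi_m = y[10], h_m = y[11], k_m = y[12];
    double h_i = y[13], k_i = y[14];
    double atp_c = y[15], adp_c = y[16], pi_c = y[17], h_c = y[18], k_c = y[19];
    double h2o2_m = y[20], h2o2_c = y[21];

    double A = dpsi / rt_f;
    double g = A + log(h_i / h_m);
    double eA2 = exp(A / 2.0), emA2 = exp(-A / 2.0);

    /* symmetric thermokinetic form for the proton pumps */
    double D1 = k_CI - 4.0 * g;
    double D3 = k_CIII - 2.0 * g;
    double D4 = k_CIV - 2.0 * g - 2.0 * A;
    double DF = n_F1 * g + log(keq_F1);

    double J_DH   = x_DH * c_DH * (r_DH * nad - nadh);
    double J_CI   = x_CI * c_CI *
        (nadh * q * exp(D1 / 2.0) - nad * qh2 * exp(-D1 / 2.0));
    double J_CIII = x_CIII * c_CIII *
        (qh2 * cox * cox * exp(D3 / 2.0) - q * cred * cred * exp(-D3 / 2.0));
    double J_CIV  = x_CIV * c_CIV * (o2 / (o2 + K_O2)) *
        (cred * cred * exp(D4 / 2.0) - cox * cox * exp(-D4 / 2.0));
    double J_F1   = x_F1 * c_F1 *
        (adp_m * pi_m * exp(DF / 2.0) - atp_m * exp(-DF / 2.0));
    double J_ANT  = a_ANT * (atp_m * adp_c - atp_c * adp_m * exp(-A));
    double J_Hle  = x_Hle * c_Hle * (h_i * eA2 - h_m * emA2);
    double J_PiC  = a_PiC * (pi_c * h_i - pi_m * h_m);
    double J_Kuni = a_Kuni * (k_i * eA2 - k_m * emA2);
    double J_KHE  = a_KHE * (k_m * h_i - k_i * h_m);
    double J_KDyn = K_dyn * c_dyn * adp_c;
    double J_KCons = K_cons * c_cons * atp_c;
    double J_exH  = a_exH * (h_c - h_i);
    double J_exK  = a_exK * (k_c - k_i);
    double J_ros  = rho_nadh * nadh + rho_qh2 * qh2;
    double J_clear_m = k_clr_m * h2o2_m;
    double Jd     = k_diff * (h2o2_m - h2o2_c);
    double J_clear_c = k_clr_c * h2o2_c;

    double bm = M_LN10 * h_m / beta_pH;
    double bi = M_LN10 * h_i / beta_pH;

    ydot[0] = (4.0 * J_CI + 2.0 * J_CIII + 4.0 * J_CIV - n_F1 * J_F1 -
               J_ANT - J_Hle - J_Kuni) / c_mem;
    ydot[1] = (J_DH - J_CI) / W_m;
    ydot[2] = -ydot[1];
    ydot[3] = (J_CIII - J_CI) / W_m;
    ydot[4] = -ydot[3];
    ydot[5] = 2.0 * (J_CIII - J_CIV) / W_i;
    ydot[6] = -ydot[5];
    ydot[7] = 0.0;
    ydot[8] = (J_F1 - J_ANT) / W_m;
    ydot[9] = -ydot[8];
    ydot[10] = (J_PiC - J_F1) / W_m;
    ydot[11] = bm * (-4.0 * J_CI - 2.0 * J_CIII - 4.0 * J_CIV +
                     n_F1 * J_F1 + J_Hle + J_PiC + J_KHE) / W_m;
    ydot[12] = (J_Kuni - J_KHE) / W_m;
    ydot[13] = bi * (4.0 * J_CI + 2.0 * J_CIII + 2.0 * J_CIV -
                     n_F1 * J_F1 - J_Hle - J_PiC - J_KHE + J_exH) / W_i;
    ydot[14] = (J_KHE - J_Kuni + J_exK) / W_i;
    ydot[15] = (J_ANT + J_KDyn - J_KCons) / V_c;
    ydot[16] = -ydot[15];
    ydot[17] = (J_KCons - J_KDyn - J_PiC) / V_c;
    ydot[18] = 0.0;
    ydot[19] = 0.0;
    ydot[20] = (J_ros - J_clear_m - Jd) / W_m;
    ydot[21] = (Jd - J_clear_c) / V_c;

    if (ip[0] >= 18) {
        yout[0] = J_DH;   yout[1] = J_CI;    yout[2] = J_CIII;
        yout[3] = J_CIV;  yout[4] = J_F1;    yout[5] = J_ANT;
        yout[6] = J_Hle;  yout[7] = J_PiC;   yout[8] = J_Kuni;
        yout[9] = J_KHE;  yout[10] = J_KDyn; yout[11] = J_KCons;
        yout[12] = J_exH; yout[13] = J_exK;  yout[14] = J_ros;
        yout[15] = J_clear_m; yout[16] = Jd; yout[17] = J_clear_c;
    }
}
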