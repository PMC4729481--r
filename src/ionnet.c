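/* Compiled right-hand side of the ion-homeostasis model for deSolve.
 *
 * State ordering (must match R/model.R):
 *   0 H_in  1 K_in  2 Na_in  3 Cl_in
 *   4 H_out 5 K_out 6 Na_out 7 Cl_out
 *   8 dphi  9 ATP
 *  10 L_HH 11 L_KK 12 L_HAr 13 L_KAr
 *
 * parms layout (must match as_parms_vector()):
 *   0 Surf 1 V_in 2 V_out 3 T 4 Cm 5 Bf 6 R 7 F
 *   8 L_HK 9 L_HNa 10 L_HCl 11 L_KNa 12 L_KCl 13 L_NaCl 14 L_NaNa 15 L_ClCl
 *  16 k_incrHH 17 k_decrHH 18 k_incrKK 19 k_decrKK
 *  20 k_incrHAr 21 k_decrHAr 22 k_incrKAr 23 k_decrKAr
 *  24 C_ATP 25 Keq 26 k_ATPincr 27 k_ATPdecr 28 glucose_on
 */
#include <R.h>
#include <math.h>

#define NPARMS 29

static double p[NPARMS];

/* log with a linear extension below CMIN: keeps the rhs finite and smooth
 * when a stiff-solver trial step undershoots zero, so the step can be
 * rejected and retried instead of propagating NaN. Reported states are
 * positivity-checked on the R side. */
#define CMIN 1e-15
static double safe_log(double x)
{
    return (x > CMIN) ? log(x) : (log(CMIN) + (x - CMIN) / CMIN);
}

void ionnet_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

void ionnet_rhs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double Surf = p[0], Vin = p[1], Vout = p[2], T = p[3], Cm = p[4],
           Bf = p[5], Rg = p[6], Fd = p[7];
    double LHK = p[8], LHNa = p[9], LHCl = p[10], LKNa = p[11],
           LKCl = p[12], LNaCl = p[13], LNaNa = p[14], LClCl = p[15];
    double g = p[28];

    double LHH = y[10], LKK = y[11], LHAr = y[12], LKAr = y[13];

    double fphi = Fd * y[8] / T;
    double XH  = Rg * (safe_log(y[0]) - safe_log(y[4])) + fphi;
    double XK  = Rg * (safe_log(y[1]) - safe_log(y[5])) + fphi;
    double XNa = Rg * (safe_log(y[2]) - safe_log(y[6])) + fphi;
    double XCl = Rg * (safe_log(y[3]) - safe_log(y[7])) - fphi;
    double XAr = (Rg / p[24]) * (y[9] - p[24]) * (1.0 + p[25]); /* A_Ar/T */

    double JH  = LHH * XH + LHK * XK + LHNa * XNa + LHCl * XCl + LHAr * XAr;
    double JK  = LHK * XH + LKK * XK + LKNa * XNa + LKCl * XCl + LKAr * XAr;
    double JNa = LHNa * XH + LKNa * XK + LNaNa * XNa + LNaCl * XCl;
    double JCl = LHCl * XH + LKCl * XK + LNaCl * XNa + LClCl * XCl;
    double JAr = LHAr * XH + LKAr * XK; /* L_ArAr = 0 */

    double ain = Surf / Vin, aout = Surf / Vout;

    ydot[0] = -JH * ain / Bf;
    ydot[1] = -JK * ain;
    ydot[2] = -JNa * ain;
    ydot[3] = -JCl * ain;
    ydot[4] = JH * aout;
    ydot[5] = JK * aout;
    ydot[6] = JNa * aout;
    ydot[7] = JCl * aout;
    ydot[8] = -(2.0 * Fd / Cm) * (JH + JK + JNa - JCl);
    ydot[9] = g * (p[26] - p[27] * y[9]);
    ydot[10] = g * (p[16] - p[17] * LHH);
    ydot[11] = g * (p[18] - p[19] * LKK);
    ydot[12] = g * (p[20] - p[21] * LHAr);
    ydot[13] = g * (p[22] - p[23] * LKAr);

    if (ip[0] >= 11) {
        yout[0] = JH;  yout[1] = JK;  yout[2] = JNa; yout[3] = JCl;
        yout[4] = JAr;
        yout[5] = XH;  yout[6] = XK;  yout[7] = XNa; yout[8] = XCl;
        yout[9] = XAr;
        yout[10] = JH * XH + JK * XK + JNa * XNa + JCl * XCl + JAr * XAr;
    }
}
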