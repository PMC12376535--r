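/* Compiled right-hand side of the voltage-clamp artifact ODE system, for use
 * with deSolve's compiled-code interface.  The R function
 * evaluate_derivatives() is the reference implementation of the same
 * equations; the two are cross-checked in the test suite.
 *
 * Internal units: mV, ms, pA, pF, nS, GOhm (GOhm*pF = ms, nS*mV = pA).
 *
 * Parameter vector layout (0-based, padded to NPARMS by the R caller):
 *   0 Rs        (GOhm)   true series resistance
 *   1 Cm        (pF)     true membrane capacitance
 *   2 Cp        (pF)     true pipette capacitance
 *   3 g_leak    (nS)     true leak conductance
 *   4 E_leak    (mV)     leak reversal
 *   5 Voff      (mV)     residual voltage-offset error
 *   6 alpha_R            series-resistance compensation fraction
 *   7 alpha_P            supercharging / prediction fraction
 *   8 Rs_est    (GOhm)   machine estimate of Rs
 *   9 Cm_est    (pF)     machine estimate of Cm
 *  10 Cp_est    (pF)     machine estimate of Cp
 *  11 tau_clamp (ms)     amplifier delay
 *  12 tau_sum   (ms)     compensation-summation delay
 *  13 tau_z     (ms)     recording filter time constant
 *  14 Vcmd     (mV)      command voltage (constant within a segment)
 *  15 kind               ionic model id (0 none, 1 passive, 2 HH m3h,
 *                        3 O'Hara-style INa, 4 electrical model cell)
 *  16 n_ion             number of ionic state variables
 *  17.. ionic model parameters (layout depends on kind, see below)
 *
 * State vector: y[0]=Vm, y[1]=Vp, y[2]=Vest, y[3]=Vclamp, y[4]=Iout,
 * y[5..]=ionic states (all of relaxation form dx/dt = (x_inf - x)/tau).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 64
#define MAX_ION 8

static double parms[NPARMS];

void clampsim_init(void (*odeparms)(int *, double *))
{
    int N = NPARMS;
    odeparms(&N, parms);
}

static double sigm(double x)
{
    return 1.0 / (1.0 + exp(-x));
}

/* tau(V) = base + amp * exp(delta*x) / (1 + exp(x)), x = (V - vmid)/k.
 * Evaluated in an overflow-safe form. Covers constant (amp = 0), sigmoid
 * (delta = 0) and skewed-bell (0 < delta < 1) time-constant curves. */
static double tau_curve(double V, const double *q)
{
    double x = (V - q[2]) / q[3];
    double val;
    if (x > 0.0)
        val = exp((q[4] - 1.0) * x) / (1.0 + exp(-x));
    else
        val = exp(q[4] * x) / (1.0 + exp(x));
    return q[0] + q[1] * val;
}

/* O'Hara-style fast INa rate functions (fast+slow inactivation and the slow
 * recovery gate j; non-phosphorylated pathway only). */
static void ohara_inf_tau(double V, double *inf, double *tau)
{
    inf[0] = sigm((V + 39.57) / 9.871);                       /* m   */
    tau[0] = 1.0 / (6.765 * exp((V + 11.64) / 34.77) +
                    8.552 * exp(-(V + 77.42) / 5.955));
    inf[1] = sigm(-(V + 82.90) / 6.086);                      /* h_f */
    tau[1] = 1.0 / (1.432e-5 * exp(-(V + 1.196) / 6.285) +
                    6.149 * exp((V + 0.5096) / 20.27));
    inf[2] = inf[1];                                          /* h_s */
    tau[2] = 1.0 / (0.009794 * exp(-(V + 17.95) / 28.05) +
                    0.3343 * exp((V + 5.730) / 56.66));
    inf[3] = inf[1];                                          /* j   */
    tau[3] = 2.038 + 1.0 / (0.02136 * exp(-(V + 100.6) / 8.281) +
                            0.3052 * exp((V + 0.9941) / 38.45));
}

/* Steady-state and time-constant curves per ionic state. q points at the
 * ionic parameter block (parms + 17). */
static void ion_inf_tau(int kind, const double *q, double V,
                        double *inf, double *tau)
{
    switch (kind) {
    case 2:                      /* generic HH m3h sodium current */
        /* q: 0 g, 1 ENa, 2 Vhm, 3 km, 4 Vhh, 5 kh,
         *    6-10 tau_m curve, 11-15 tau_h curve */
        inf[0] = sigm((V - q[2]) / q[3]);
        tau[0] = tau_curve(V, q + 6);
        inf[1] = sigm((V - q[4]) / q[5]);
        tau[1] = tau_curve(V, q + 11);
        break;
    case 3:                      /* O'Hara-style INa: q: 0 g, 1 ENa */
        ohara_inf_tau(V, inf, tau);
        break;
    case 4:                      /* model cell: q: 0 Rm, 1 Rf, 2 Cf */
        inf[0] = V;
        tau[0] = q[1] * q[2];
        break;
    default:
        break;                   /* kinds 0 and 1 have no states */
    }
}

static double ion_current(int kind, const double *q, double V,
                          const double *ys)
{
    double m, h;
    switch (kind) {
    case 1:                      /* passive: q: 0 g, 1 E */
        return q[0] * (V - q[1]);
    case 2:
        m = ys[0]; h = ys[1];
        return q[0] * m * m * m * h * (V - q[1]);
    case 3:
        m = ys[0];
        h = 0.99 * ys[1] + 0.01 * ys[2];
        return q[0] * m * m * m * h * ys[3] * (V - q[1]);
    case 4:
        return V / q[0] + (V - ys[0]) / q[1];
    default:
        return 0.0;
    }
}

void clampsim_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double Rs = parms[0], Cm = parms[1], Cp = parms[2];
    const double g_leak = parms[3], E_leak = parms[4], Voff = parms[5];
    const double aR = parms[6], aP = parms[7];
    const double Rs_est = parms[8], Cm_est = parms[9], Cp_est = parms[10];
    const double tau_clamp = parms[11], tau_sum = parms[12], tau_z = parms[13];
    const double Vcmd = parms[14];
    const int kind = (int) parms[15];
    const int n_ion = (int) parms[16];
    const double *q = parms + 17;

    const double Vm = y[0], Vp = y[1], Vest = y[2], Vclamp = y[3];
    const double Iout = y[4];

    double inf[MAX_ION], tau[MAX_ION];

    /* (i) supercharging estimate voltage */
    double den = (1.0 - aP) * Rs_est * Cm_est;
    double dVest = (den > 0.0) ? (Vcmd - Vest) / den : 0.0;

    /* (ii) Rs-compensated command */
    double Vcmd_p = Vcmd + Rs_est * (aR * Iout + aP * Cm_est * dVest);

    /* (iii) compensation-summation delay, (iv) amplifier delay */
    double dVclamp = (Vcmd_p - Vclamp) / tau_sum;
    double dVp = (Vclamp - Vp) / tau_clamp;

    /* (v) ionic + leak current at the true membrane voltage */
    double Iion = ion_current(kind, q, Vm, y + 5);
    double Ileak = g_leak * (Vm - E_leak);

    /* (vi) membrane equation with offset error entering at the pipette */
    double dVm = (Vp + Voff - Vm) / (Rs * Cm) - (Iion + Ileak) / Cm;

    /* (vii) measured current before the recording filter */
    double Iin = Iion + Ileak + Cp * dVp - Cp_est * dVclamp
                 + Cm * dVm - Cm_est * dVest;

    /* (viii) first-order recording filter */
    double dIout = (Iin - Iout) / tau_z;

    ydot[0] = dVm;
    ydot[1] = dVp;
    ydot[2] = dVest;
    ydot[3] = dVclamp;
    ydot[4] = dIout;

    if (n_ion > 0) {
        ion_inf_tau(kind, q, Vm, inf, tau);
        for (int i = 0; i < n_ion; i++)
            ydot[5 + i] = (inf[i] - y[5 + i]) / tau[i];
    }

    if (ip[0] >= 2) {
        yout[0] = Iion;
        yout[1] = Iin;
    }
}

/* Ideal-clamp gating integration is done analytically in R (relaxation form
 * with piecewise-constant Vm), so no compiled ideal-mode RHS is needed. */

static const R_CMethodDef CEntries[] = {
    {"clampsim_init",   (DL_FUNC) &clampsim_init,   1},
    {"clampsim_derivs", (DL_FUNC) &clampsim_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_clampsim(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
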