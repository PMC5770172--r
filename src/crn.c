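/* Courtemanche-Ramirez-Nattel (1998) human atrial action potential model.
 *
 * 21 ordinary differential equations: membrane potential, 12 Hodgkin-Huxley
 * gating variables, 3 sarcoplasmic-reticulum release gates, and 5
 * concentration / compartment states.  Implemented from the original
 * publication's equation set.  Eleven current magnitudes (plus an optional
 * scaling of the I_Na h-gate time constant) are exposed as dimensionless
 * multipliers so populations of models can be built by conductance scaling.
 *
 * State vector layout (units):
 *   0  V      membrane potential (mV)
 *   1  m      I_Na activation
 *   2  h      I_Na fast inactivation
 *   3  j      I_Na slow inactivation
 *   4  oa     I_to activation
 *   5  oi     I_to inactivation
 *   6  ua     I_Kur activation
 *   7  ui     I_Kur inactivation
 *   8  xr     I_Kr activation
 *   9  xs     I_Ks activation
 *   10 d      I_CaL activation
 *   11 f      I_CaL voltage inactivation
 *   12 fCa    I_CaL calcium inactivation
 *   13 u      SR release activation
 *   14 v      SR release inactivation
 *   15 w      SR release voltage inactivation
 *   16 Nai    intracellular Na+ (mM)
 *   17 Ki     intracellular K+ (mM)
 *   18 Cai    intracellular Ca2+ (mM)
 *   19 Caup   network SR Ca2+ (mM)
 *   20 Carel  junctional SR Ca2+ (mM)
 *
 * Parameter vector layout (see R/crn.R):
 *   0..10  multipliers: gNa gto gKur gKr gKs gK1 gCaL INaK_max INaCa_max
 *          Iup_max krel
 *   11     tau_h_scale (multiplier on the h-gate time constant)
 *   12     Nao (mM)   13 Ko (mM)   14 Cao (mM)   15 temperature (K)
 *   16     stimulus current (pA; negative = inward, 0 when off)
 *   17     assign stimulus charge to K+ bookkeeping (0/1)
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_STATE 21
#define N_PARMS 18

static double crn_parms[N_PARMS];

/* physical constants and fixed model parameters (original published values) */
static const double Rgas = 8.3143;       /* J mol^-1 K^-1 */
static const double Frdy = 96.4867;      /* C mmol^-1 */
static const double Cm   = 100.0;        /* pF */
static const double Vi   = 13668.0;      /* um^3 */
static const double Vup  = 1109.52;      /* um^3 */
static const double Vrel = 96.48;        /* um^3 */

static const double gNa_b   = 7.8;          /* nS/pF */
static const double gK1_b   = 0.09;
static const double gto_b   = 0.1652;
static const double gKr_b   = 0.029411765;
static const double gKs_b   = 0.12941176;
static const double gCaL_b  = 0.12375;
static const double gbCa    = 0.001131;
static const double gbNa    = 0.0006744375;
static const double INaK_b  = 0.59933874;   /* pA/pF */
static const double INaCa_b = 1600.0;       /* pA/pF */
static const double IpCa_b  = 0.275;        /* pA/pF */
static const double Iup_b   = 0.005;        /* mM/ms */
static const double krel_b  = 30.0;         /* ms^-1 */

static const double KQ10    = 3.0;
static const double gam     = 0.35;
static const double KmNai   = 10.0;
static const double KmKo    = 1.5;
static const double KmNa    = 87.5;
static const double KmCa    = 1.38;
static const double ksat    = 0.1;
static const double Kup     = 0.00092;
static const double Caupmax = 15.0;
static const double Cmdnmax = 0.05;
static const double Trpnmax = 0.07;
static const double Csqnmax = 10.0;
static const double KmCmdn  = 0.00238;
static const double KmTrpn  = 0.0005;
static const double KmCsqn  = 0.8;
static const double tautr   = 180.0;
static const double taufCa  = 2.0;
static const double tauu    = 8.0;

/* a*x/(1 - exp(-x/s)) with its removable singularity at x = 0 */
static double sigl(double a, double x, double s)
{
    if (fabs(x) < 1e-10) return a * s;
    return a * x / (1.0 - exp(-x / s));
}

static void crn_rhs(double t, const double *y, double *ydot, const double *p)
{
    const double V = y[0], m = y[1], h = y[2], j = y[3];
    const double oa = y[4], oi = y[5], ua = y[6], ui = y[7];
    const double xr = y[8], xs = y[9], d = y[10], f = y[11], fCa = y[12];
    const double u = y[13], v = y[14], w = y[15];
    const double Nai = y[16], Ki = y[17], Cai = y[18];
    const double Caup = y[19], Carel = y[20];

    const double Nao = p[12], Ko = p[13], Cao = p[14], Temp = p[15];
    const double Ist = p[16];
    const double RTF = Rgas * Temp / Frdy;

    const double ENa = RTF * log(Nao / Nai);
    const double EK  = RTF * log(Ko / Ki);
    const double ECa = 0.5 * RTF * log(Cao / Cai);

    /* fast Na+ current */
    const double INa = Cm * p[0] * gNa_b * m * m * m * h * j * (V - ENa);

    /* inward rectifier */
    const double IK1 = Cm * p[5] * gK1_b * (V - EK) /
        (1.0 + exp(0.07 * (V + 80.0)));

    /* transient outward */
    const double Ito = Cm * p[1] * gto_b * oa * oa * oa * oi * (V - EK);

    /* ultrarapid delayed rectifier (voltage-dependent conductance) */
    const double gKur = 0.005 + 0.05 / (1.0 + exp(-(V - 15.0) / 13.0));
    const double IKur = Cm * p[2] * gKur * ua * ua * ua * ui * (V - EK);

    /* rapid delayed rectifier */
    const double IKr = Cm * p[3] * gKr_b * xr * (V - EK) /
        (1.0 + exp((V + 15.0) / 22.4));

    /* slow delayed rectifier */
    const double IKs = Cm * p[4] * gKs_b * xs * xs * (V - EK);

    /* L-type Ca2+ current */
    const double ICaL = Cm * p[6] * gCaL_b * d * f * fCa * (V - 65.0);

    /* Na+/K+ pump */
    const double sigma = (exp(Nao / 67.3) - 1.0) / 7.0;
    const double fNaK = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V / RTF) +
                               0.0365 * sigma * exp(-V / RTF));
    const double INaK = Cm * p[7] * INaK_b * fNaK *
        (1.0 / (1.0 + pow(KmNai / Nai, 1.5))) * (Ko / (Ko + KmKo));

    /* Na+/Ca2+ exchanger */
    const double eg  = exp(gam * V / RTF);
    const double eg1 = exp((gam - 1.0) * V / RTF);
    const double INaCa = Cm * p[8] * INaCa_b *
        (eg * Nai * Nai * Nai * Cao - eg1 * Nao * Nao * Nao * Cai) /
        ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) *
         (1.0 + ksat * eg1));

    /* background and pump currents */
    const double IbNa = Cm * gbNa * (V - ENa);
    const double IbCa = Cm * gbCa * (V - ECa);
    const double IpCa = Cm * IpCa_b * Cai / (0.0005 + Cai);

    /* SR fluxes */
    const double Irel = p[10] * krel_b * u * u * v * w * (Carel - Cai);
    const double Itr  = (Caup - Carel) / tautr;
    const double Iup  = p[9] * Iup_b / (1.0 + Kup / Cai);
    const double Iupleak = p[9] * Iup_b * Caup / Caupmax;

    /* --- gating kinetics --- */
    double am, bm, ah, bh, aj, bj, inf, tau;

    am = (fabs(V + 47.13) < 1e-10) ? 3.2
        : 0.32 * (V + 47.13) / (1.0 - exp(-0.1 * (V + 47.13)));
    bm = 0.08 * exp(-V / 11.0);
    ydot[1] = am * (1.0 - m) - bm * m;

    if (V >= -40.0) {
        ah = 0.0;
        bh = 1.0 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
        aj = 0.0;
        bj = 0.3 * exp(-2.535e-7 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    } else {
        ah = 0.135 * exp(-(V + 80.0) / 6.8);
        bh = 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V);
        aj = (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
            (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
        bj = 0.1212 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
    }
    /* tau_h scaling: h_inf untouched, time constant multiplied */
    {
        const double hinf = ah / (ah + bh);
        const double tauh = p[11] / (ah + bh);
        ydot[2] = (hinf - h) / tauh;
    }
    ydot[3] = aj * (1.0 - j) - bj * j;

    {
        const double a = 0.65 / (exp(-(V + 10.0) / 8.5) +
                                 exp(-(V - 30.0) / 59.0));
        const double b = 0.65 / (2.5 + exp((V + 82.0) / 17.0));
        tau = 1.0 / ((a + b) * KQ10);
        inf = 1.0 / (1.0 + exp(-(V + 20.47) / 17.54));
        ydot[4] = (inf - oa) / tau;
        /* ua shares oa's rate functions */
        inf = 1.0 / (1.0 + exp(-(V + 30.3) / 9.6));
        ydot[6] = (inf - ua) / tau;
    }
    {
        const double a = 1.0 / (18.53 + exp((V + 113.7) / 10.95));
        const double b = 1.0 / (35.56 + exp(-(V + 1.26) / 7.44));
        tau = 1.0 / ((a + b) * KQ10);
        inf = 1.0 / (1.0 + exp((V + 43.1) / 5.3));
        ydot[5] = (inf - oi) / tau;
    }
    {
        const double a = 1.0 / (21.0 + exp(-(V - 185.0) / 28.0));
        const double b = exp((V - 158.0) / 16.0);
        tau = 1.0 / ((a + b) * KQ10);
        inf = 1.0 / (1.0 + exp((V - 99.45) / 27.48));
        ydot[7] = (inf - ui) / tau;
    }
    {
        const double a = sigl(0.0003, V + 14.1, 5.0);
        const double b = sigl(7.3898e-5, -(V - 3.3328), 5.1237);
        tau = 1.0 / (a + b);
        inf = 1.0 / (1.0 + exp(-(V + 14.1) / 6.5));
        ydot[8] = (inf - xr) / tau;
    }
    {
        const double a = sigl(4e-5, V - 19.9, 17.0);
        const double b = sigl(3.5e-5, -(V - 19.9), 9.0);
        tau = 0.5 / (a + b);
        inf = 1.0 / sqrt(1.0 + exp(-(V - 19.9) / 12.7));
        ydot[9] = (inf - xs) / tau;
    }
    {
        const double z = (V + 10.0) / 6.24;
        const double ez = exp(-z);
        tau = (fabs(z) < 1e-8) ? 1.0 / (0.035 * 6.24 * 2.0)
            : (1.0 - ez) / (0.035 * (V + 10.0) * (1.0 + ez));
        inf = 1.0 / (1.0 + exp(-(V + 10.0) / 8.0));
        ydot[10] = (inf - d) / tau;
    }
    {
        const double e2 = 0.0337 * (V + 10.0);
        tau = 9.0 / (0.0197 * exp(-e2 * e2) + 0.02);
        inf = 1.0 / (1.0 + exp((V + 28.0) / 6.9));
        ydot[11] = (inf - f) / tau;
    }
    ydot[12] = (1.0 / (1.0 + Cai / 0.00035) - fCa) / taufCa;

    /* SR release gating driven by Fn */
    {
        const double Fn = 1e-12 * Vrel * Irel -
            (5e-13 / Frdy) * (0.5 * ICaL - 0.2 * INaCa);
        const double su = 1.0 / (1.0 + exp(-(Fn - 3.4175e-13) / 1.367e-15));
        ydot[13] = (su - u) / tauu;
        const double vinf = 1.0 - 1.0 /
            (1.0 + exp(-(Fn - 6.835e-14) / 1.367e-15));
        const double tauv = 1.91 + 2.09 * su;
        ydot[14] = (vinf - v) / tauv;
    }
    {
        const double z = (V - 7.9) / 5.0;
        const double ez = exp(-z);
        const double tw = (fabs(z) < 1e-8) ? 6.0 / (1.3 * 5.0)
            : 6.0 * (1.0 - ez) / ((1.0 + 0.3 * ez) * (V - 7.9));
        const double winf = 1.0 - 1.0 / (1.0 + exp(-(V - 40.0) / 17.0));
        ydot[15] = (winf - w) / tw;
    }

    /* --- membrane potential and concentrations --- */
    const double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL +
        IpCa + INaK + INaCa + IbNa + IbCa;
    ydot[0] = -(Iion + Ist) / Cm;

    ydot[16] = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) / (Frdy * Vi);
    {
        double IKsum = 2.0 * INaK - IK1 - Ito - IKur - IKr - IKs;
        if (p[17] > 0.5) IKsum -= Ist;  /* book stimulus charge as K+ */
        ydot[17] = IKsum / (Frdy * Vi);
    }
    {
        const double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) /
            (2.0 * Frdy * Vi) +
            (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
        const double tc = Cai + KmTrpn, cc = Cai + KmCmdn;
        const double B2 = 1.0 + Trpnmax * KmTrpn / (tc * tc) +
            Cmdnmax * KmCmdn / (cc * cc);
        ydot[18] = B1 / B2;
    }
    ydot[19] = Iup - Iupleak - Itr * Vrel / Vup;
    {
        const double sc = Carel + KmCsqn;
        ydot[20] = (Itr - Irel) /
            (1.0 + Csqnmax * KmCsqn / (sc * sc));
    }
    (void)t;
}

/* deSolve compiled-model interface */
void crn_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, crn_parms);
}

void crn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    (void)neq; (void)yout; (void)ip;
    crn_rhs(*t, y, ydot, crn_parms);
}

/* dV/dt evaluated from the model right-hand side for a matrix of states
 * (rows = time samples, 21 columns), used for upstroke-velocity extraction */
SEXP C_crn_vdot(SEXP states, SEXP parms)
{
    if (!isReal(states) || !isMatrix(states))
        error("'states' must be a numeric matrix");
    const int nr = nrows(states), nc = ncols(states);
    if (nc != N_STATE) error("'states' must have %d columns", N_STATE);
    if (LENGTH(parms) != N_PARMS) error("'parms' must have length %d", N_PARMS);
    const double *s = REAL(states);
    const double *p = REAL(parms);
    SEXP out = PROTECT(allocVector(REALSXP, nr));
    double y[N_STATE], ydot[N_STATE];
    for (int i = 0; i < nr; i++) {
        for (int k = 0; k < N_STATE; k++) y[k] = s[i + (R_xlen_t)nr * k];
        crn_rhs(0.0, y, ydot, p);
        REAL(out)[i] = ydot[0];
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef callMethods[] = {
    {"C_crn_vdot", (DL_FUNC) &C_crn_vdot, 2},
    {NULL, NULL, 0}
};

void R_init_pomcal(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    /* crn_derivs / crn_initmod stay dynamically visible for deSolve */
    R_useDynamicSymbols(info, TRUE);
}
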