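/* Compiled right-hand side of the branched Entner-Doudoroff pathway ODE
 * system, in the deSolve compiled-model interface.  Mirrors the R
 * reference implementation in R/model.R (.rates_from_parms); the two are
 * cross-checked in the test suite.
 *
 * Parameter vector layout (48 doubles):
 *   [0..24]  velocities, mM/min (enzymatic, cofactor-scaled) or 1/min
 *            (sinks, degradation), in the order of .ed_velocity_order()
 *   [25..44] Km values, mM, in the order of .ed_km_order()
 *   [45]     Ki of glycerate-kinase substrate inhibition (mM)
 *   [46]     Ki of the PGK effector inhibition (mM)
 *   [47]     1-based state index of the PGK effector (0 = none)
 *
 * State order: Glc DGat KDG KDPG GAP BPG PG3 PG2 PEP Pyr GA Gly.
 * Negative excursions of the stiff transients are clamped to zero when
 * evaluating rates.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[48];

void ed_init(void (*odeparms)(int *, double *))
{
    int n = 48;
    odeparms(&n, parms);
}

void ed_rhs(int *neq, double *t, double *y, double *ydot,
            double *yout, int *ip)
{
    double s[12];
    const double *p = parms;
    const double *km = parms + 25;
    double ki_gk = parms[45], ki_pgk = parms[46];
    int inh = (int) parms[47];
    double a, b, c, inhf;
    int i;

    for (i = 0; i < 12; i++) s[i] = y[i] > 0 ? y[i] : 0;

    double Glc = s[0], DGat = s[1], KDG = s[2], KDPG = s[3], GAP = s[4];
    double BPG = s[5], PG3 = s[6], PG2 = s[7], PEP = s[8], Pyr = s[9];
    double GA = s[10], Gly = s[11];

    double v_up   = p[0];
    double v_gdh  = p[1] * Glc / (km[0] + Glc);
    double v_gad  = p[2] * DGat / (km[1] + DGat);
    double v_kdgk = p[3] * KDG / (km[2] + KDG);
    double v_spa  = p[4] * KDPG / (km[3] + KDPG);

    a = KDG / km[4]; b = GA / km[5]; c = Pyr / km[6];
    double v_npa = (p[5] * a - p[6] * b * c) / (1 + a + b + c + b * c);

    a = GAP / km[7]; b = BPG / km[8];
    double v_gapdh = (p[7] * a - p[8] * b) / (1 + a + b);

    double v_gapn = p[9] * GAP / (km[9] + GAP);

    a = BPG / km[10]; b = PG3 / km[11];
    inhf = inh > 0 ? 1 / (1 + s[inh - 1] / ki_pgk) : 1;
    double v_pgk = (p[10] * a - p[11] * b) / (1 + a + b) * inhf;

    a = PG3 / km[12]; b = PG2 / km[13];
    double v_ipgam = (p[12] * a - p[13] * b) / (1 + a + b);

    double v_gaor = p[14] * GA / (km[14] + GA);
    double v_gk   = p[15] * Gly / (km[15] + Gly * (1 + Gly / ki_gk));

    a = PG2 / km[16]; b = PEP / km[17];
    double v_eno = (p[16] * a - p[17] * b) / (1 + a + b);

    double v_pk   = p[18] * PEP / (km[18] + PEP);
    double v_peps = p[19] * Pyr / (km[19] + Pyr);

    double v_skg  = p[20] * GAP;
    double v_skp  = p[21] * Pyr;
    double v_dg   = p[22] * GAP;
    double v_db   = p[23] * BPG;
    double v_dp   = p[24] * PEP;

    ydot[0]  = v_up - v_gdh;                                   /* Glc  */
    ydot[1]  = v_gdh - v_gad;                                  /* DGat */
    ydot[2]  = v_gad - v_kdgk - v_npa;                         /* KDG  */
    ydot[3]  = v_kdgk - v_spa;                                 /* KDPG */
    ydot[4]  = v_spa - v_gapdh - v_gapn - v_skg - v_dg;        /* GAP  */
    ydot[5]  = v_gapdh - v_pgk - v_db;                         /* BPG  */
    ydot[6]  = v_pgk + v_gapn - v_ipgam;                       /* PG3  */
    ydot[7]  = v_ipgam + v_gk - v_eno;                         /* PG2  */
    ydot[8]  = v_eno + v_peps - v_pk - v_dp;                   /* PEP  */
    ydot[9]  = v_spa + v_npa + v_pk - v_peps - v_skp;          /* Pyr  */
    ydot[10] = v_npa - v_gaor;                                 /* GA   */
    ydot[11] = v_gaor - v_gk;                                  /* Gly  */
}

void R_init_edflux(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
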