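/* Compiled right-hand side of the coupled patient-tube-dialyzer system.
 *
 * State layout (all concentrations uM, column-major species blocks):
 *   y[0..4]    plasma   T, D, P, PT, PD
 *   y[5..9]    interstitial  "
 *   y[10..11]  intracellular T, D
 *   y[12 + s*nt + i]                       tube, species s cell i
 *   y[12 + 5*nt + s*nd + i]                dialyzer plasma side
 *   y[12 + 5*nt + 5*nd + s*nd + i]         dialyzer dialysate side
 *   last 7: cumulative elimination (T, D) and dialysate outlet mass
 *           per species (umol)
 *
 * Parameters are passed once through the deSolve initfunc mechanism; the
 * axial flow profiles are linear in position and evaluated in place.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 36

static double parms[N_PARMS];

#define P_NT      parms[0]
#define P_ND      parms[1]
#define P_KONT    parms[2]
#define P_KOFFT   parms[3]
#define P_KOND    parms[4]
#define P_KOFFD   parms[5]
#define P_LAMT    parms[6]
#define P_LAMD    parms[7]
#define P_KIP     parms[8]   /* L/min */
#define P_KIC     parms[9]   /* L/min */
#define P_VPL     parms[10]  /* L */
#define P_VIS     parms[11]
#define P_VIC     parms[12]
#define P_QPL     parms[13]  /* mL/min */
#define P_QTUBE   parms[14]
#define P_QD      parms[15]
#define P_QDI     parms[16]
#define P_VT      parms[17]  /* mL per tube cell */
#define P_VP      parms[18]  /* mL per plasma-side cell */
#define P_VD      parms[19]  /* mL per dialysate-side cell */
#define P_CINF    parms[20]
#define P_SIGMA   (parms + 21) /* 5 */
#define P_KOA     (parms + 26) /* 5, mL/min */
#define P_PEF     (parms + 31) /* 5 */

void hdbind_init_session(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void hdbind_derivs_session(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    const int nt = (int) P_NT, nd = (int) P_ND;
    const double konT = P_KONT, koffT = P_KOFFT;
    const double konD = P_KOND, koffD = P_KOFFD;
    const int i_tube = 12, i_cp = 12 + 5 * nt, i_cd = 12 + 5 * nt + 5 * nd;
    const int i_aux = 12 + 5 * nt + 10 * nd;
    const double *pl = y, *is = y + 5, *ic = y + 10;
    double rT, rD, r[5], bc[5], up[5], down, gate;
    double qpl_L = P_QPL / 1000.0;
    int s, i;

    /* patient plasma + interstitial + intracellular */
    double C_out[5];
    for (s = 0; s < 5; s++) C_out[s] = y[i_cp + s * nd + nd - 1];

    rT = -konT * pl[2] * pl[0] + koffT * pl[3];
    rD = -konD * pl[2] * pl[1] + koffD * pl[4];
    r[0] = rT; r[1] = rD; r[2] = rT + rD; r[3] = -rT; r[4] = -rD;
    for (s = 0; s < 5; s++) {
        gate = (s < 2) ? 1.0 : 0.0;
        ydot[s] = gate * P_KIP * (is[s] - pl[s]) / P_VPL + r[s]
            + qpl_L * (C_out[s] - pl[s]) / P_VPL
            - gate * (s == 0 ? P_LAMT : P_LAMD) * pl[s];
    }
    rT = -konT * is[2] * is[0] + koffT * is[3];
    rD = -konD * is[2] * is[1] + koffD * is[4];
    r[0] = rT; r[1] = rD; r[2] = rT + rD; r[3] = -rT; r[4] = -rD;
    for (s = 0; s < 5; s++) {
        gate = (s < 2) ? 1.0 : 0.0;
        double cic = (s < 2) ? ic[s] : 0.0;
        ydot[5 + s] = (-gate * P_KIP * (is[s] - pl[s])
                       + gate * P_KIC * (cic - is[s])) / P_VIS + r[s];
    }
    ydot[10] = -P_KIC * (ic[0] - is[0]) / P_VIC;
    ydot[11] = -P_KIC * (ic[1] - is[1]) / P_VIC;

    /* tube inlet boundary: flow-weighted mixing with the infusion stream */
    for (s = 0; s < 5; s++) {
        double cinf = (s == 1) ? P_CINF : 0.0;
        bc[s] = (P_QPL * pl[s] + P_QD * cinf) / P_QTUBE;
    }

    /* tube segment: upwind advection + reactions */
    for (i = 0; i < nt; i++) {
        const double Tc = y[i_tube + 0 * nt + i], Dc = y[i_tube + 1 * nt + i];
        const double Pc = y[i_tube + 2 * nt + i];
        const double PTc = y[i_tube + 3 * nt + i], PDc = y[i_tube + 4 * nt + i];
        rT = -konT * Pc * Tc + koffT * PTc;
        rD = -konD * Pc * Dc + koffD * PDc;
        r[0] = rT; r[1] = rD; r[2] = rT + rD; r[3] = -rT; r[4] = -rD;
        for (s = 0; s < 5; s++) {
            double cu = (i == 0) ? bc[s] : y[i_tube + s * nt + i - 1];
            ydot[i_tube + s * nt + i] =
                P_QTUBE * (cu - y[i_tube + s * nt + i]) / P_VT + r[s];
        }
    }

    /* dialyzer: counter-current, linearly varying flows (uniform UF) */
    for (i = 0; i < nd; i++) {
        const double qpf_in = P_QTUBE - ((double) i / nd) * P_QD;
        const double qpf_out = P_QTUBE - ((double) (i + 1) / nd) * P_QD;
        const double qdf_in = P_QDI + (1.0 - (double) (i + 1) / nd) * P_QD;
        const double qdf_out = P_QDI + (1.0 - (double) i / nd) * P_QD;
        double rp[5], rd_[5];
        const double Tp = y[i_cp + 0 * nd + i], Dp = y[i_cp + 1 * nd + i];
        const double Pp = y[i_cp + 2 * nd + i];
        const double PTp = y[i_cp + 3 * nd + i], PDp = y[i_cp + 4 * nd + i];
        rT = -konT * Pp * Tp + koffT * PTp;
        rD = -konD * Pp * Dp + koffD * PDp;
        rp[0] = rT; rp[1] = rD; rp[2] = rT + rD; rp[3] = -rT; rp[4] = -rD;
        const double Td = y[i_cd + 0 * nd + i], Dd = y[i_cd + 1 * nd + i];
        const double Pd = y[i_cd + 2 * nd + i];
        const double PTd = y[i_cd + 3 * nd + i], PDd = y[i_cd + 4 * nd + i];
        rT = -konT * Pd * Td + koffT * PTd;
        rD = -konD * Pd * Dd + koffD * PDd;
        rd_[0] = rT; rd_[1] = rD; rd_[2] = rT + rD; rd_[3] = -rT; rd_[4] = -rD;
        for (s = 0; s < 5; s++) {
            const double cp = y[i_cp + s * nd + i];
            const double cd = y[i_cd + s * nd + i];
            up[s] = (i == 0) ? y[i_tube + s * nt + nt - 1]
                             : y[i_cp + s * nd + i - 1];
            down = (i == nd - 1) ? 0.0 : y[i_cd + s * nd + i + 1];
            const double diff = P_PEF[s] * (P_KOA[s] / nd) * (cp - cd);
            const double conv = (P_QD / nd) * (1.0 - P_SIGMA[s]) * cp;
            ydot[i_cp + s * nd + i] =
                (qpf_in * up[s] - qpf_out * cp) / P_VP
                - conv / P_VP - diff / P_VP + rp[s];
            ydot[i_cd + s * nd + i] =
                (qdf_in * down - qdf_out * cd) / P_VD
                + conv / P_VD + diff / P_VD + rd_[s];
        }
    }

    /* cumulative audits: endogenous elimination and dialysate outlet */
    ydot[i_aux] = P_LAMT * pl[0] * P_VPL;     /* umol/min (uM * L) */
    ydot[i_aux + 1] = P_LAMD * pl[1] * P_VPL;
    {
        const double qd_exit = P_QDI + P_QD;
        for (s = 0; s < 5; s++) {
            ydot[i_aux + 2 + s] = qd_exit * y[i_cd + s * nd] / 1000.0;
        }
    }
}

static const R_CMethodDef CEntries[] = {
    {"hdbind_init_session",   (DL_FUNC) &hdbind_init_session,   1},
    {"hdbind_derivs_session", (DL_FUNC) &hdbind_derivs_session, 6},
    {NULL, NULL, 0}
};

void R_init_hdbind(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
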