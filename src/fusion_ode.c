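/* Dimensionless vacuole-fusion signaling network.
 *
 * States (7): H, T, S, Y, C, X, FI where FI = cumulative integral of Y
 * (the instantaneous fusion rate, since the fusion rate constant is the
 * time scale and equals 1).
 *
 * Parameters (12): K1, K3, K4, K5, K6, K7, K8, K9, then the Boolean gates
 * pi3p, signal, hops_cytosol, sec17_cytosol as 0/1 doubles.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static double parms[12];

void fusion_init(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

static void fusion_rhs_core(const double *p, const double *y, double *ydot)
{
    double H = y[0], T = y[1], S = y[2], Y = y[3], C = y[4], X = y[5];
    double K1 = p[0], K3 = p[1], K4 = p[2], K5 = p[3];
    double K6 = p[4], K7 = p[5], K8 = p[6], K9 = p[7];
    double pi3p = p[8], sig = p[9], hc = p[10], xc = p[11];
    /* guard against tiny negative solver undershoot before the quartic */
    double Sc = S > 0 ? S : 0;
    double S4 = Sc * Sc * Sc * Sc;

    double chaperone = K3 * H * S4;      /* HOPS templating 4 SNAREs -> C */
    double reassoc   = K5 * H * T;       /* HOPS + trans-SNARE -> C       */
    double dissoc    = K4 * C;           /* C -> HOPS + trans-SNARE       */
    double displace  = K8 * X * C * sig; /* Sec17 displaces HOPS from C   */
    double assoc     = K9 * X * T;       /* Sec17 binds bare trans-SNARE  */

    ydot[0] = K1 * pi3p * hc + dissoc - reassoc - chaperone - K1 * H;
    ydot[1] = dissoc - reassoc - assoc;
    ydot[2] = 4.0 * Y - 4.0 * chaperone;
    ydot[3] = assoc + displace - Y;
    ydot[4] = chaperone + reassoc - dissoc - displace;
    ydot[5] = K6 * xc - K7 * X - displace - assoc;
    ydot[6] = Y;
}

/* deSolve derivative entry point */
void fusion_deriv(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    fusion_rhs_core(parms, y, ydot);
}

/* Direct evaluation of the right-hand side, for cross-checks from R.
 * y: numeric(6) or numeric(7); p: numeric(12). Returns numeric(7). */
SEXP C_fusion_rhs(SEXP y, SEXP p)
{
    if (LENGTH(p) != 12)
        error("C_fusion_rhs: parameter vector must have length 12");
    if (LENGTH(y) < 6)
        error("C_fusion_rhs: state vector must have at least 6 components");
    double yy[7] = {0, 0, 0, 0, 0, 0, 0};
    for (int i = 0; i < 6; i++) yy[i] = REAL(y)[i];
    SEXP out = PROTECT(allocVector(REALSXP, 7));
    fusion_rhs_core(REAL(p), yy, REAL(out));
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef callMethods[] = {
    {"C_fusion_rhs", (DL_FUNC) &C_fusion_rhs, 2},
    {NULL, NULL, 0}
};

static const R_CMethodDef cMethods[] = {
    {"fusion_deriv", (DL_FUNC) &fusion_deriv, 6},
    {NULL, NULL, 0}
};

void R_init_vacfusion(DllInfo *info)
{
    R_registerRoutines(info, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
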