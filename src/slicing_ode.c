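/* Single-turnover slicing kinetics, deSolve compiled-model interface.
 *
 * State layout: K independent reaction conditions stacked as 6-state blocks
 *   [E, S, ES, Ep, EpS, P] (nM), sharing one parameter set (kon, kslice,
 * kphase2).  Fa and Eall enter only through the initial conditions set on the
 * R side, so the RHS needs just the three rate constants.
 *
 * Scheme per block (mass action):
 *   E  + S -> ES   (kon)      ES  -> E  + P  (kslice)
 *   Ep + S -> EpS  (kon)      EpS -> Ep + P  (kphase2)
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[3];
#define KON     parms[0]
#define KSLICE  parms[1]
#define KPHASE2 parms[2]

void slicekin_initmod(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, parms);
}

void slicekin_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    int nblock = *neq / 6;
    for (int b = 0; b < nblock; b++) {
        double *yb = y + 6 * b;
        double *db = ydot + 6 * b;
        double E = yb[0], S = yb[1], ES = yb[2];
        double Ep = yb[3], EpS = yb[4];
        double bind1 = KON * E * S;
        double bind2 = KON * Ep * S;
        double cut1 = KSLICE * ES;
        double cut2 = KPHASE2 * EpS;
        db[0] = -bind1 + cut1;            /* E   */
        db[1] = -bind1 - bind2;           /* S   */
        db[2] = bind1 - cut1;             /* ES  */
        db[3] = -bind2 + cut2;            /* Ep  */
        db[4] = bind2 - cut2;             /* EpS */
        db[5] = cut1 + cut2;              /* P   */
    }
}

static const R_CMethodDef CEntries[] = {
    {"slicekin_initmod", (DL_FUNC) &slicekin_initmod, 1},
    {"slicekin_derivs",  (DL_FUNC) &slicekin_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_slicekin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
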