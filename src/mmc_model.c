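/* Compiled right-hand side of the MMC / tumor / effector ODE system for
 * deSolve.  Parameter order must match .mmc_param_names in R/parameters.R:
 * mu1, m, r, k, p1, a, p2, d0, gamma, mu2, p3.
 */
#include <R.h>

static double parms[11];
#define MU1   parms[0]
#define M_IN  parms[1]
#define R_T   parms[2]
#define CAP   parms[3]
#define P1    parms[4]
#define A_SAT parms[5]
#define P2    parms[6]
#define D0    parms[7]
#define GAM   parms[8]
#define MU2   parms[9]
#define P3    parms[10]

void mmc_initmod(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

void mmc_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double M = y[0], T = y[1], E = y[2];
    double sat = P1 * M / (M + A_SAT);   /* Michaelis-Menten drug kill */

    ydot[0] = -MU1 * M + M_IN;
    ydot[1] = -T * (sat + P2 * E) + R_T * T * (1.0 - T / CAP);
    ydot[2] = D0 + GAM * sat * T - E * (P3 * T + MU2);
}
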