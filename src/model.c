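/* Compiled right-hand side of the ten-species kinetic model, for use by
 * deSolve's integrators. Mirrors the R-level ode_rhs(); the Heaviside gate
 * on caspase activation is passed in as a frozen 0/1 per integration
 * segment so the solver never crosses the discontinuity.
 *
 * Parameter vector layout (see .model_parms() on the R side):
 *  0 k2    1 K2    2 k4    3 K4    4 k5    5 k_minus5  6 k6   7 k7
 *  8 k8    9 k10  10 K10  11 n    12 k11  13 k12      14 k13 15 k14
 * 16 K14  17 Ki14 18 k15  19 k16  20 K16  21 Ki16     22 k17 23 pges
 * 24 alpha 25 beta 26 k1  27 k3   28 k9   29 heaviside
 *
 * State layout: 0 c3star, 1 c7star, 2 nfkb, 3 ipla2, 4 ipla2star,
 * 5 cox2_mrna, 6 cox2, 7 aa, 8 pgh2, 9 pge2 (all micromolar).
 */
#include <R.h>
#include <math.h>

#define N_PARMS 30

static double parms[N_PARMS];

void pr_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double nonneg(double x)
{
    return x > 0.0 ? x : 0.0;
}

void pr_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double k2 = parms[0], K2 = parms[1], k4 = parms[2], K4 = parms[3];
    const double k5 = parms[4], km5 = parms[5], k6 = parms[6], k7 = parms[7];
    const double k8 = parms[8], k10 = parms[9], K10 = parms[10];
    const double n = parms[11], k11 = parms[12], k12 = parms[13];
    const double k13 = parms[14], k14 = parms[15], K14 = parms[16];
    const double Ki14 = parms[17], k15 = parms[18], k16 = parms[19];
    const double K16 = parms[20], Ki16 = parms[21], k17 = parms[22];
    const double pges = parms[23], alpha = parms[24], beta = parms[25];
    const double k1 = parms[26], k3 = parms[27], k9 = parms[28];
    const double H = parms[29];

    const double c3star = nonneg(y[0]), c7star = nonneg(y[1]);
    const double nfkb = nonneg(y[2]), ipla2 = nonneg(y[3]);
    const double ipla2star = nonneg(y[4]), cox2_mrna = nonneg(y[5]);
    const double cox2 = nonneg(y[6]), aa = nonneg(y[7]);
    const double pgh2 = nonneg(y[8]), pge2 = nonneg(y[9]);

    const double v2 = k2 * c3star * ipla2 / (K2 + ipla2);
    const double v4 = k4 * c7star * ipla2 / (K4 + ipla2);
    const double hilln = pow(nfkb, n);
    const double v10 = k10 * hilln / (pow(K10, n) + hilln);
    const double v14 = k14 * cox2 * aa /
        (K14 * (1.0 + pge2 / Ki14 + alpha) + aa);
    const double v16 = k16 * pges * pgh2 /
        (K16 * (1.0 + aa / Ki16) + pgh2);

    ydot[0] = k1 * H;                                  /* C3*       */
    ydot[1] = k3 * H;                                  /* C7*       */
    ydot[2] = k9;                                      /* NFkB      */
    ydot[3] = km5 - k5 * ipla2 - v2 - v4;              /* iPLA2     */
    ydot[4] = v2 + v4 - k7 * ipla2star;                /* iPLA2*    */
    ydot[5] = v10 - k11 * cox2_mrna;                   /* COX2 mRNA */
    ydot[6] = k12 * cox2_mrna - k13 * cox2;            /* COX2      */
    ydot[7] = k6 * ipla2star / beta - k8 * aa - v14;   /* AA        */
    ydot[8] = v14 - k15 * pgh2 - v16;                  /* PGH2      */
    ydot[9] = v16 / beta - k17 * pge2;                 /* PGE2      */
}
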