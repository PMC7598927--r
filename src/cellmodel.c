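/* Single-cell damage-accumulation dynamics for deSolve's compiled interface.
 *
 * State: y[0] = P (functional protein), y[1] = D (damaged protein).
 *   dP/dt = g*P*(1 - S) - k1*P + r(D)
 *   dD/dt = k1*P - r(D),          S = P + Q*D
 *   r(D)  = k2*R*sin(D/R), with the R -> Inf limit r(D) = k2*D.
 *
 * Roots (for lsodar): P - P_div (division), D - D_death (death),
 * D - D_health (health-span crossing, non-terminal at the R level).
 */
#include <R.h>
#include <math.h>

static double parms[8];
#define par_g       parms[0]
#define par_k1      parms[1]
#define par_k2      parms[2]
#define par_Q       parms[3]
#define par_R       parms[4]
#define par_Pdiv    parms[5]
#define par_Ddeath  parms[6]
#define par_Dhealth parms[7]

void cell_initmod(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, parms);
}

static double repair(double D)
{
    if (!R_FINITE(par_R))
        return par_k2 * D;       /* unlimited capacity: linear repair */
    return par_k2 * par_R * sin(D / par_R);
}

void cell_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double P = y[0], D = y[1];
    double r = repair(D);
    double S = P + par_Q * D;
    ydot[0] = par_g * P * (1.0 - S) - par_k1 * P + r;
    ydot[1] = par_k1 * P - r;
}

void cell_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *out, int *ip)
{
    gout[0] = y[0] - par_Pdiv;
    gout[1] = y[1] - par_Ddeath;
    gout[2] = y[1] - par_Dhealth;
}
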