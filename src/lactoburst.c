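/* Right-hand side of the three-variable lactotroph model in the form
 * expected by deSolve's compiled-code interface.  State: V (mV),
 * n (dimensionless), c (uM).  Time in ms.  Parameter order must match
 * .lacto_par_order in the R sources.
 */
#include <R.h>
#include <math.h>

static double parms[18];
#define Cm    parms[0]
#define gCa   parms[1]
#define VCa   parms[2]
#define vm    parms[3]
#define sm    parms[4]
#define gK    parms[5]
#define VK    parms[6]
#define vn    parms[7]
#define sn    parms[8]
#define taun  parms[9]
#define gKCa  parms[10]
#define Kd    parms[11]
#define gBK   parms[12]
#define vb    parms[13]
#define sb    parms[14]
#define fc    parms[15]
#define alpha parms[16]
#define kc    parms[17]

static double boltz(double V, double vh, double s)
{
    double a = (vh - V) / s;
    if (a > 500.0) a = 500.0;
    if (a < -500.0) a = -500.0;
    return 1.0 / (1.0 + exp(a));
}

void lacto_initmod(void (*odeparms)(int *, double *))
{
    int N = 18;
    odeparms(&N, parms);
}

void lacto_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double V = y[0], n = y[1], c = y[2];
    double minf = boltz(V, vm, sm);
    double binf = boltz(V, vb, sb);
    double ninf = boltz(V, vn, sn);
    double sinf = c * c / (c * c + Kd * Kd);
    double ica  = gCa * minf * (V - VCa);
    double f    = -(ica + gK * n * (V - VK) + gKCa * sinf * (V - VK)
                    + gBK * binf * (V - VK));
    ydot[0] = f / Cm;
    ydot[1] = (ninf - n) / taun;
    ydot[2] = -fc * (alpha * ica + kc * c);
}
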