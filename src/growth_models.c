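/* Compiled right-hand sides of the seven tumor growth ODEs for deSolve.
 * Parameter vector: id, a, b, c, c0 (chemotherapy kill rate), v_max
 * (divergence threshold for the root function). Model ids follow
 * growth_model_names(): 1 exponential, 2 mendelsohn, 3 logistic, 4 linear,
 * 5 surface, 6 gompertz, 7 bertalanffy. Volumes are clipped at 0 before
 * fractional powers are evaluated. */

#include <R.h>
#include <math.h>

static double parms[6];
#define MODEL_ID parms[0]
#define P_A parms[1]
#define P_B parms[2]
#define P_C parms[3]
#define KILL parms[4]
#define V_MAX parms[5]

void growth_init(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void growth_deriv(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double v = y[0] > 0 ? y[0] : 0;
    double g = 0;
    switch ((int) MODEL_ID) {
    case 1: g = P_A * v; break;
    case 2: g = P_A * pow(v, P_B); break;
    case 3: g = P_A * v * (1 - v / P_B); break;
    case 4: g = P_A * v / (v + P_B); break;
    case 5: g = P_A * v / pow(v + P_B, 1.0 / 3.0); break;
    case 6: g = (v + P_C > 0) ? P_A * v * log(P_B / (v + P_C)) : 0; break;
    case 7: g = P_A * pow(v, 2.0 / 3.0) - P_B * v; break;
    }
    ydot[0] = g - KILL * v;
}

void growth_root(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip)
{
    gout[0] = y[0] - V_MAX;
}
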