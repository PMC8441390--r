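/* Right-hand sides of the adaptation-motif ODEs, callable from deSolve.
 *
 * Parameter vector layout (13 doubles, set via motif_initpar):
 *   parms[0]  kind   : 0 = negative feedback, 1 = incoherent feedforward,
 *                      2 = state-dependent inactivation
 *   parms[1]  family : 0 = elementary mass action, 1 = Hill
 *   parms[2..6]  k1..k5
 *   parms[7..12] h1..h6 (ignored for the elementary family)
 *
 * One forcing function: the nuclear input N(t), linearly interpolated by
 * deSolve between the supplied profile points.
 *
 * State: (A, B) for feedback/feedforward, (Aon, Ain) for state-dependent
 * inactivation. Bases of fractional powers are clamped at zero so that
 * integrator overshoot below 0 or above 1 cannot produce NaNs.
 */

#include <R.h>
#include <math.h>

static double parms[13];
static double forc[1];

#define KIND   ((int) parms[0])
#define HILL   (((int) parms[1]) == 1)
#define K(i)   parms[1 + (i)]
#define H(i)   parms[6 + (i)]
#define INPUT  forc[0]

void motif_initpar(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, parms);
}

void motif_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

static double powc(double base, double e)
{
    if (base < 0.0) base = 0.0;
    return (e == 1.0) ? base : pow(base, e);
}

void motif_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double in = INPUT;
    if (in < 0.0) in = 0.0;

    if (KIND == 2) {                      /* state-dependent inactivation */
        double Aon = y[0], Ain = y[1];
        double act, inact;
        if (HILL) {
            act   = K(1) * powc(in, H(1)) * powc(1.0 - Aon - Ain, H(2));
            inact = K(2) * powc(Aon, H(3));
        } else {
            act   = K(1) * in * (1.0 - Aon - Ain);
            inact = K(2) * Aon;
        }
        ydot[0] = act - inact - K(3) * Aon;
        ydot[1] = inact - K(4) * Ain;
    } else {                              /* feedback / feedforward */
        double A = y[0], B = y[1];
        if (HILL) {
            ydot[0] = K(1) * powc(in, H(1)) * powc(1.0 - A, H(2))
                      - K(2) * powc(B, H(3)) * powc(A, H(4))
                      - K(3) * A;
            if (KIND == 0)
                ydot[1] = K(4) * powc(A, H(5)) * powc(1.0 - B, H(6))
                          - K(5) * B;
            else
                ydot[1] = K(4) * powc(in, H(5)) * powc(1.0 - B, H(6))
                          - K(5) * B;
        } else {
            ydot[0] = K(1) * in * (1.0 - A) - K(2) * B * A - K(3) * A;
            if (KIND == 0)
                ydot[1] = K(4) * A * (1.0 - B) - K(5) * B;
            else
                ydot[1] = K(4) * in * (1.0 - B) - K(5) * B;
        }
    }
}
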