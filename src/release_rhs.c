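/* Method-of-lines right-hand side and analytic banded Jacobian for the
 * coupled dissolution-diffusion system on the unit sphere:
 *
 *   d(phi)/dtau  = (1/eta) d2(eta phi)/deta2 + S
 *   d(phia)/dtau = -S,   S = G (phia/(1-K))^n (K - phi)  while solid remains
 *
 * State is interleaved, y = (phi_0, phia_0, phi_1, phia_1, ...) on the
 * uniform grid eta_i = i*h, h = 1/(N-1), so the Jacobian is banded with
 * half-bandwidth 2. Called by deSolve via dllname/initfunc.
 *
 * Near depletion the on/off source switch is regularized over the ramp
 * width RAMP_ (a C1 smoothstep) so it stays Lipschitz for the stiff
 * solver, and for phia < 0 a gentle restoring term at the natural
 * dissolution-rate scale G makes the depleted state an attracting
 * equilibrium: a flat dead zone would let BDF predictor history drift
 * across it unchecked. The power law is clamped at 0 because n < 1 makes
 * it singular there.
 */
#include <R.h>
#include <math.h>

static double parms[5];
#define K_    parms[0]
#define G_    parms[1]
#define NEXP_ parms[2]
#define RAMP_ parms[3]
#define NPT_  parms[4]

void release_initmod(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, parms);
}

/* source S and its partial derivatives wrt phia and phi */
static void source_terms(double phi, double phia, double *S,
                         double *dS_dphia, double *dS_dphi)
{
    const double oneK = 1.0 - K_;
    double A, dA;                 /* effective area factor and d/dphia */

    if (phia >= RAMP_) {
        A = (NEXP_ == 0.0) ? 1.0 : pow(phia / oneK, NEXP_);
        dA = (NEXP_ == 0.0) ? 0.0 : NEXP_ * A / phia;
    } else if (phia > 0.0) {
        double x = phia / RAMP_;
        double r = x * x * (3.0 - 2.0 * x);
        double dr = (6.0 * x - 6.0 * x * x) / RAMP_;
        double p = (NEXP_ == 0.0) ? 1.0 : pow(phia / oneK, NEXP_);
        double dp = (NEXP_ == 0.0) ? 0.0 : NEXP_ * p / phia;
        A = p * r;
        dA = dp * r + p * dr;
    } else {
        A = phia / oneK;
        dA = 1.0 / oneK;
    }
    *S = G_ * A * (K_ - phi);
    *dS_dphia = G_ * dA * (K_ - phi);
    *dS_dphi = -G_ * A;
}

void release_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const int N = (int) NPT_;
    const double h = 1.0 / (N - 1);
    const double h2 = h * h;
    int i;

    for (i = 0; i < N; i++) {
        double S, dSa, dSp;

        source_terms(y[2 * i], y[2 * i + 1], &S, &dSa, &dSp);
        ydot[2 * i + 1] = -S;

        if (i == 0) {
            /* symmetry limit of the spherical Laplacian: 3 phi'' */
            ydot[0] = 6.0 * (y[2] - y[0]) / h2 + S;
        } else if (i == N - 1) {
            /* perfect sink: phi pinned at 0 */
            ydot[2 * i] = 0.0;
        } else {
            double eta = i * h;
            double lap = ((eta + h) * y[2 * (i + 1)]
                          - 2.0 * eta * y[2 * i]
                          + (eta - h) * y[2 * (i - 1)]) / (h2 * eta);
            ydot[2 * i] = lap + S;
        }
    }
}

/* Banded Jacobian in LSODE/VODE storage: pd[(i - j + mu) + j*nrowpd] =
 * d f_i / d y_j (0-based); pd is preset to zero by the solver. */
void release_jac(int *neq, double *t, double *y, int *ml, int *mu,
                 double *pd, int *nrowpd, double *yout, int *ip)
{
    const int N = (int) NPT_;
    const double h = 1.0 / (N - 1);
    const double h2 = h * h;
    const int ld = *nrowpd;
    const int MU = *mu;
    int i;

#define PD(i, j) pd[((i) - (j) + MU) + (j) * ld]

    for (i = 0; i < N; i++) {
        const int ip_ = 2 * i;        /* phi index  */
        const int ia_ = 2 * i + 1;    /* phia index */
        double S, dSa, dSp;

        source_terms(y[ip_], y[ia_], &S, &dSa, &dSp);

        /* solid row: d(phia)/dtau = -S */
        PD(ia_, ip_) = -dSp;
        PD(ia_, ia_) = -dSa;

        if (i == N - 1)               /* pinned surface: f = 0 */
            continue;

        /* dissolved row */
        PD(ip_, ia_) = dSa;
        if (i == 0) {
            PD(0, 0) = -6.0 / h2 + dSp;
            PD(0, 2) = 6.0 / h2;
        } else {
            double eta = i * h;
            PD(ip_, ip_ - 2) = (eta - h) / (h2 * eta);
            PD(ip_, ip_) = -2.0 / h2 + dSp;
            PD(ip_, ip_ + 2) = (eta + h) / (h2 * eta);
        }
    }
#undef PD
}
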