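/* Compiled right-hand side for the transcription-regulation ODE system.
 *
 * The state vector holds n_rep independent replicates of an n-node network
 * (replicates share parameters but start from different initial conditions,
 * so one integrator call covers all initial-condition tests of a phase).
 *
 * Parameter vector layout (padded to PAVNET_PARMS_LEN doubles by the R side):
 *   p[0] = n (nodes per replicate)
 *   p[1] = n_rep
 *   p[2 .. 2+n-1]            per-node degradation rate eta
 *   next 5*n entries         per-node header:
 *                              n_act, n_inh, n_mult_sig, mult_const, add_const
 *   then, node by node:      n_act blocks (src, V, k, n)  activation edges
 *                            n_inh blocks (src, k, K, alpha, n) inhibition edges
 *
 * mult_const is the product of the signal activation terms that compose
 * multiplicatively at the node during the current phase (1 if the node has
 * activation edges but no such signal); add_const is the sum of additive
 * signal terms. A node with no activation edges, no multiplicative signal,
 * no inhibition edges and no additive signal has zero production.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define PAVNET_PARMS_LEN 512

static double parms[PAVNET_PARMS_LEN];

void pavnet_init(void (*odeparms)(int *, double *))
{
    int n = PAVNET_PARMS_LEN;
    odeparms(&n, parms);
}

void pavnet_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double *p = parms;
    int n = (int) p[0];
    int nrep = (int) p[1];
    const double *eta = p + 2;
    const double *hdr = p + 2 + n;
    const double *blk0 = hdr + 5 * n;

    for (int r = 0; r < nrep; r++) {
        const double *yr = y + r * n;
        double *dr = ydot + r * n;
        const double *blk = blk0;
        for (int j = 0; j < n; j++) {
            int na = (int) hdr[5 * j];
            int ni = (int) hdr[5 * j + 1];
            int nms = (int) hdr[5 * j + 2];
            double prod = hdr[5 * j + 3];
            double addc = hdr[5 * j + 4];
            for (int e = 0; e < na; e++) {
                int i = (int) blk[0];
                double V = blk[1], k = blk[2], nn = blk[3];
                double A = yr[i] > 0 ? yr[i] : 0.0;
                double xn = pow(A, nn);
                prod *= V * xn / (xn + pow(k, nn));
                blk += 4;
            }
            double inh = 0.0;
            for (int e = 0; e < ni; e++) {
                int i = (int) blk[0];
                double k = blk[1], K = blk[2], al = blk[3], nn = blk[4];
                double A = yr[i] > 0 ? yr[i] : 0.0;
                double Kn = pow(K, nn);
                inh += k * Kn / (Kn + al * pow(A, nn));
                blk += 5;
            }
            double prodterm = (na + nms > 0) ? prod : 0.0;
            dr[j] = prodterm + inh + addc - eta[j] * yr[j];
        }
    }
}

static const R_CMethodDef CEntries[] = {
    {"pavnet_derivs", (DL_FUNC) &pavnet_derivs, 6},
    {"pavnet_init",   (DL_FUNC) &pavnet_init,   1},
    {NULL, NULL, 0}
};

void R_init_pavnet(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
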