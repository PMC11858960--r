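/* Compiled right-hand side of the whole-body PBPK system.
 *
 * State layout (amounts, umol):
 *   y[0 .. 12*nc-1]        organ amounts, column-major per compound with rows
 *                          0 art, 1 ven, 2 lung, 3 gut lumen (dissolved),
 *                          4 gut tissue, 5 liver, 6 kidney, 7 muscle, 8 skin,
 *                          9 fat, 10 bone, 11 rest
 *   y[12*nc .. 12*nc+nc-1] cumulative urine per compound
 *   y[.. +nproc]           cumulative metabolized amount per process
 *
 * Parameter vector (doubles), packed by the R wrapper:
 *   0  total length          1  nc (compounds)     2  nproc
 *   3  ndose                 4  ninh               5  cardiac output L/min
 *   6  gut lumen volume L
 *   7..18   organ volumes V[12] (L)
 *   19..26  tissue blood flows Q[8] (L/min): gut, liver(arterial), kidney,
 *           muscle, skin, fat, bone, rest
 *   then per-compound vectors (nc each): fu, ka (1/min), CLrenal (L/min),
 *        lumen solubility cap (uM; <=0 disables)
 *   then Kp, 8*nc (tissue rows gut..rest, column-major per compound)
 *   then nproc * 5: substrate idx (1-based), product idx (0 = sink),
 *        vmax (umol/min), km (uM; <=0 flags linear kinetics v = vmax*Cu),
 *        inhibition group (0 none, 1 CYP2D6 pool, 2 CYP3A4 pool)
 *   then ninh * 3: inhibitor compound idx (1-based), ki (uM), group
 *   then ndose * 6: compound idx, amount (umol), time (min),
 *        t_diss50 (min), shape b, t_lag (min)
 *
 * Time unit: minutes.  Concentrations: uM (plasma).  Flow-limited organs;
 * metabolism and inhibition act on unbound plasma concentration at the
 * liver outflow; renal elimination on unbound kidney outflow.
 */

#include <R.h>
#include <math.h>

#define MAXPAR 16384
#define MAXC 16

static double parms[MAXPAR];

/* called from R via .C() before each solve; the vector length varies with
 * the number of compounds, processes and dose events, so the deSolve
 * initfunc mechanism (fixed length) is not used */
void venbup_set_parms(int *n, double *p)
{
    int i;
    if (*n > MAXPAR)
        error("PBPK parameter vector too long (%d > %d)", *n, MAXPAR);
    for (i = 0; i < *n; i++)
        parms[i] = p[i];
}

void venbup_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double *p = parms;
    const int nc    = (int) p[1];
    const int nproc = (int) p[2];
    const int ndose = (int) p[3];
    const int ninh  = (int) p[4];
    const double CO = p[5];
    const double *V = p + 7;        /* 12 organ volumes */
    const double *Q = p + 19;       /* 8 tissue flows   */
    const double *fu  = p + 27;
    const double *ka  = p + 27 + nc;
    const double *clr = p + 27 + 2 * nc;
    const double *sol = p + 27 + 3 * nc;
    const double *Kp  = p + 27 + 4 * nc;
    const double *prc = Kp + 8 * nc;
    const double *inh = prc + 5 * nproc;
    const double *dos = inh + 3 * ninh;
    const double ln2 = 0.6931471805599453;

    double Cart[MAXC], Cven[MAXC], Clng[MAXC], Cout[8][MAXC];
    double din[MAXC], dliv[MAXC];
    int j, i, k;

    for (j = 0; j < nc; j++) {
        const double *a = y + 12 * j;
        Cart[j] = a[0] / V[0];
        Cven[j] = a[1] / V[1];
        Clng[j] = a[2] / V[2];
        for (i = 0; i < 8; i++)
            Cout[i][j] = a[4 + i] / (V[4 + i] * Kp[8 * j + i]);
        din[j] = 0.0;
        dliv[j] = 0.0;
    }

    /* Weibull dissolution input into the gut lumen */
    for (k = 0; k < ndose; k++) {
        const double *d = dos + 6 * k;
        double dt = *t - d[2] - d[5];
        if (dt > 0.0) {
            double x = dt / d[3];
            double b = d[4];
            if (x < 1e-12) x = 1e-12;
            double xb = pow(x, b);
            if (xb < 60.0 / ln2) {
                int c = (int) d[0] - 1;
                din[c] += d[1] * ln2 * b / d[3] * pow(x, b - 1.0) *
                          exp(-ln2 * xb);
            }
        }
    }
    /* solubility cap: dissolution stalls while the lumen is saturated */
    for (j = 0; j < nc; j++)
        if (sol[j] > 0.0 && y[12 * j + 3] / V[3] >= sol[j])
            din[j] = 0.0;

    /* competitive inhibition pools (unbound liver outflow concentrations) */
    double gsum[3] = {0.0, 0.0, 0.0};
    for (k = 0; k < ninh; k++) {
        int c = (int) inh[3 * k] - 1;
        int g = (int) inh[3 * k + 2];
        if (g >= 1 && g <= 2)
            gsum[g] += fu[c] * Cout[1][c] / inh[3 * k + 1];
    }

    /* metabolic process rates */
    for (k = 0; k < nproc; k++) {
        const double *pr = prc + 5 * k;
        int s = (int) pr[0] - 1;
        int q = (int) pr[1] - 1;
        double cu = fu[s] * Cout[1][s];
        double v;
        if (pr[3] <= 0.0) {
            v = pr[2] * cu;                          /* linear clearance */
        } else {
            int g = (int) pr[4];
            double fac = (g >= 1 && g <= 2) ? 1.0 + gsum[g] : 1.0;
            v = pr[2] * cu / (pr[3] * fac + cu);     /* MM, competitive */
        }
        dliv[s] -= v;
        if (q >= 0) dliv[q] += v;
        ydot[13 * nc + k] = v;                       /* cumulative per process */
    }

    for (j = 0; j < nc; j++) {
        double *dy = ydot + 12 * j;
        double qc = 0.0, vsum = 0.0;
        /* gut lumen */
        dy[3] = din[j] - ka[j] * y[12 * j + 3];
        /* gut tissue: arterial inflow + absorbed drug, portal outflow */
        dy[4] = Q[0] * (Cart[j] - Cout[0][j]) + ka[j] * y[12 * j + 3];
        /* liver: hepatic artery + portal vein, metabolism */
        dy[5] = Q[1] * Cart[j] + Q[0] * Cout[0][j] -
                (Q[0] + Q[1]) * Cout[1][j] + dliv[j];
        /* kidney with renal elimination of unbound drug */
        {
            double ren = clr[j] * fu[j] * Cout[2][j];
            dy[6] = Q[2] * (Cart[j] - Cout[2][j]) - ren;
            ydot[12 * nc + j] = ren;                 /* urine accumulator */
        }
        /* remaining flow-limited tissues */
        for (i = 3; i < 8; i++)
            dy[7 + i - 3] = Q[i] * (Cart[j] - Cout[i][j]);
        /* venous pool collects everything except gut (drains to liver) */
        for (i = 2; i < 8; i++) vsum += Q[i] * Cout[i][j];
        vsum += (Q[0] + Q[1]) * Cout[1][j];
        dy[1] = vsum - CO * Cven[j];
        /* lung and arterial pool */
        dy[2] = CO * (Cven[j] - Clng[j]);
        qc = 0.0;
        for (i = 0; i < 8; i++) qc += Q[i];
        dy[0] = CO * Clng[j] - qc * Cart[j];
    }
}
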