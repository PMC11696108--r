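/* Host-aware cell + batch-culture ODE right-hand side, in the compiled-model
 * form expected by deSolve (initfunc/derivs/root).
 *
 * State vector (length 29):
 *   y[0..3]   B, S_x, P_x, I_x        (culture: cells, molecules)
 *   y[4..7]   s_i, e, p_i, i_i        (per-cell pools, molecules/cell)
 *   y[8..14]  m_x   for x = T,E,Ep,Tp,TF,X,R   (mRNA/cell)
 *   y[15..21] c_x   translating ribosome-mRNA complexes/cell
 *   y[22..28] prot_x free protein/cell (prot_R = free ribosomes)
 *
 * Parameter vector layout must match .par_layout in R/params.R.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 66
static double p[NPAR];

#define MODE        p[0]   /* 0 = cell only (env clamped), 1 = batch        */
#define DRAIN       p[1]   /* 0 = Ep drains s_i, 1 = Ep drains e            */
#define M0          p[2]
#define GAMMA_MAX   p[3]
#define K_GAMMA     p[4]
#define NS          p[5]   /* precursor units per catabolised s_i           */
#define DM          p[6]   /* mRNA decay, 1/min                             */
#define DP          p[7]   /* protein decay, 1/min                          */
#define KB          p[8]   /* ribosome-mRNA binding, 1/(molecule min)       */
#define KU          p[9]   /* unbinding, 1/min                              */
#define W(i)        p[10 + (i)]   /* max transcription, transcripts/min     */
#define THETA(i)    p[17 + (i)]   /* transcription half-saturation in e     */
#define NLEN(i)     p[24 + (i)]   /* gene length, codons                    */
#define KCAT_T      p[31]
#define KM_T        p[32]  /* external substrate scale (culture units)      */
#define KCAT_E      p[33]
#define KM_E        p[34]
#define KCAT_EP     p[35]
#define KM_EP       p[36]
#define KCAT_TP     p[37]
#define KM_TP       p[38]
#define KCAT_X      p[39]
#define KM_X        p[40]
#define V_IND       p[41]  /* max inducer uptake, molecules/min/cell        */
#define KM_IND      p[42]  /* external inducer half-saturation              */
#define K_IND_TF    p[43]  /* inducer level halving active TF               */
#define KQ_X        p[44]  /* X autoregulation threshold                    */
#define HQ_X        p[45]  /* X autoregulation Hill coefficient             */
#define GCT(i)      p[46 + (i)]   /* topology g for T,E,Ep,Tp,TF            */
#define STX(i)      p[51 + (i)]   /* transcription scalings                 */
#define KCTRL(i)    p[56 + (i)]   /* control strengths                      */
#define LEAK        p[61]
#define S_CLAMP     p[62]  /* external substrate when MODE = 0              */
#define I_CLAMP     p[63]  /* external inducer when MODE = 0                */
#define EPS_S       p[64]  /* exhaustion threshold for the root function    */
#define RES65       p[65]

static double pos(double x) { return x > 0.0 ? x : 0.0; }

void init_cellbatch(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

/* Hill-1 regulation of gene i (i < 5; X and R are not circuit-controllable)
 * by the active TF concentration. g = +1: activation, -1: repression,
 * 0: untouched. Both directions share a basal leak so that activated genes
 * are expressible at zero TF (needed for positive TF autoregulation). */
static double regulation(int i, double tf_active)
{
    double g = GCT(i), k, occ;
    if (g == 0.0) return 1.0;
    k = KCTRL(i);
    occ = k * tf_active / (1.0 + k * tf_active); /* bound fraction */
    if (g > 0.0) return LEAK + (1.0 - LEAK) * occ;
    return LEAK + (1.0 - LEAK) * (1.0 - occ);
}

void derivs_cellbatch(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    int i;
    double B = y[0];
    double S_ext = (MODE > 0.5) ? pos(y[1]) : S_CLAMP;
    double I_ext = (MODE > 0.5) ? pos(y[3]) : I_CLAMP;
    double s_i = pos(y[4]), e = pos(y[5]), p_i = pos(y[6]), i_i = pos(y[7]);
    const double *m = y + 8, *c = y + 15, *pr = y + 22;
    double prT  = pos(pr[0]), prE = pos(pr[1]), prEp = pos(pr[2]);
    double prTp = pos(pr[3]), prTF = pos(pr[4]), prX = pos(pr[5]);
    double R    = pos(pr[6]);

    double gam = GAMMA_MAX * e / (K_GAMMA + e);      /* aa/min/ribosome */
    double sum_c = 0.0;
    for (i = 0; i < 7; i++) sum_c += pos(c[i]);
    double lambda = gam * sum_c / M0;

    /* metabolic and transport fluxes, molecules/min/cell */
    double v_T  = KCAT_T  * prT  * S_ext / (KM_T  + S_ext);
    double v_E  = KCAT_E  * prE  * s_i   / (KM_E  + s_i);
    double sub  = (DRAIN > 0.5) ? e : s_i;
    double v_Ep = KCAT_EP * prEp * sub   / (KM_EP + sub);
    double v_Tp = KCAT_TP * prTp * p_i   / (KM_TP + p_i);
    double v_X  = KCAT_X  * prX  * p_i   / (KM_X  + p_i);
    double r_uInd = V_IND * I_ext / (KM_IND + I_ext);

    /* the TF is active when inducer-free; uptake of inducer deactivates it */
    double tf_active = prTF * K_IND_TF / (K_IND_TF + i_i);

    /* transcription, transcripts/min: circuit genes then X (housekeeping
     * autorepression) and R (constitutive in e) */
    double tx[7];
    double e_act;
    for (i = 0; i < 5; i++) {
        e_act = e / (THETA(i) + e);
        tx[i] = STX(i) * W(i) * e_act * regulation(i, tf_active);
    }
    tx[5] = W(5) * (e / (THETA(5) + e)) /
            (1.0 + pow(prX / KQ_X, HQ_X));
    tx[6] = W(6) * (e / (THETA(6) + e));

    /* mRNA, complex and protein balances */
    double rel_sum = 0.0, bind_sum = 0.0;
    for (i = 0; i < 7; i++) {
        double bind = KB * R * pos(m[i]);
        double fin  = (gam / NLEN(i)) * pos(c[i]);   /* completions/min */
        double rel  = KU * pos(c[i]);
        ydot[8 + i]  = tx[i] - (DM + lambda) * pos(m[i]) - bind + rel + fin;
        ydot[15 + i] = bind - rel - fin - lambda * pos(c[i]);
        if (i < 6)
            ydot[22 + i] = fin - (lambda + DP) * pos(pr[i]);
        rel_sum  += rel + fin;
        bind_sum += bind;
    }
    /* free ribosomes: own synthesis + every release/completion - binding */
    ydot[28] = (gam / NLEN(6)) * pos(c[6]) - (lambda + DP) * R
               + rel_sum - bind_sum;

    /* internal pools */
    ydot[4] = v_T - v_E - lambda * s_i - ((DRAIN > 0.5) ? 0.0 : v_Ep);
    ydot[5] = NS * v_E - gam * sum_c - lambda * e
              - ((DRAIN > 0.5) ? v_Ep : 0.0);
    ydot[6] = v_Ep - v_Tp - v_X - lambda * p_i;
    ydot[7] = r_uInd - lambda * i_i;

    /* culture */
    if (MODE > 0.5) {
        ydot[0] = lambda * B;
        ydot[1] = -v_T * B;
        ydot[2] = (v_Tp + v_X) * B;
        ydot[3] = -r_uInd * B;
    } else {
        ydot[0] = ydot[1] = ydot[2] = ydot[3] = 0.0;
    }

    if (ip[0] >= 8) {
        yout[0] = lambda;
        yout[1] = v_T;
        yout[2] = v_E;
        yout[3] = v_Ep;
        yout[4] = v_Tp;
        yout[5] = v_X;
        yout[6] = r_uInd;
        yout[7] = tf_active;
    }
}

/* root: substrate exhausted */
void root_cellbatch(int *neq, double *t, double *y, int *ng, double *gout)
{
    gout[0] = y[1] - EPS_S;
}

static const R_CMethodDef CEntries[] = {
    {"init_cellbatch",   (DL_FUNC) &init_cellbatch,   1},
    {"derivs_cellbatch", (DL_FUNC) &derivs_cellbatch, 6},
    {"root_cellbatch",   (DL_FUNC) &root_cellbatch,   5},
    {NULL, NULL, 0}
};

void R_init_hostfactory(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
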