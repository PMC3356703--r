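/* Compiled right-hand side of the manganese PBPK model.
 *
 * State vector (length 31):
 *   y[0..13]   free Mn amount per compartment (ug)
 *   y[14..27]  bound Mn amount per compartment (ug)
 *   y[28]      cumulative intake (ug)
 *   y[29]      cumulative fecal excretion (ug)
 *   y[30]      cumulative biliary output to the gut lumen (ug)
 *
 * Compartment order (fixed, shared with R/params.R):
 *   0 blood, 1 liver, 2 gut_lumen, 3 gut_epithelium, 4 lung_epithelium,
 *   5 olfactory_epithelium, 6 respiratory_epithelium, 7 olfactory_bulb,
 *   8 brain target (striatum / globus pallidus), 9 cerebellum,
 *   10 pituitary, 11 bone, 12 kidney, 13 rest_of_body
 *
 * Parameter vector layout (length 118, shared with R/params.R):
 *   0 q_c (L/h)        1 q_p (L/h)       2 air (ug/L)      3 exposure_on
 *   4 diet (ug/h)      5 f_olf           6 f_resp          7 f_pulm
 *   8 k_olf (1/h)      9 k_gabs (1/h)   10 k_fec (1/h)    11 K_inh (ug)
 *  12 n_inh           13 k_slough (1/h) 14 kbile_p (g/h)  15 i_max
 *  16 c50_ind (ug/g)  17 n_ind          18 ehr (0/1)      19 (reserved)
 *  20+i   mass[i]   (g)
 *  34+i   kin_p[i]  (g/h, = 1000*min(k_in, q_blood) for perfused tissues)
 *  48+i   kout_p[i] (g/h, = 1000*k_out)
 *  62+i   btot[i]   (ug,  = b_max*mass)
 *  76+i   ka[i]     (g/ug/h)
 *  90+i   kd[i]     (1/h)
 * 104+i   kabs[i]   (1/h, epithelium -> blood)
 *
 * Concentrations are ug/g with tissue density 1 g/mL, so a flow k (L/h)
 * moves k*1000*C(ug/g) = kp*C ug/h with kp in g/h.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define N_PAR 118
#define N_CMT 14

static double p[N_PAR];

void mnpbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PAR;
    odeparms(&n, p);
}

static void rhs_core(double t, const double *y, double *ydot)
{
    const double *mass  = p + 20;
    const double *kin   = p + 34;
    const double *kout  = p + 48;
    const double *btot  = p + 62;
    const double *ka    = p + 76;
    const double *kd    = p + 90;
    const double *kabs  = p + 104;

    double cf[N_CMT], bind[N_CMT];
    int i;

    for (i = 0; i < N_CMT; i++) {
        cf[i]   = y[i] / mass[i];
        bind[i] = ka[i] * cf[i] * (btot[i] - y[N_CMT + i]) -
                  kd[i] * y[N_CMT + i];
        ydot[N_CMT + i] = bind[i];
        ydot[i] = -bind[i];
    }

    double cbl = cf[0];

    /* diffusional exchange with blood for every non-blood, non-lumen
       compartment (epithelia normally have kin = kout = 0) */
    double to_blood = 0.0;
    for (i = 1; i < N_CMT; i++) {
        if (i == 2) continue;           /* gut lumen: no perfusion */
        double ex = kin[i] * cbl - kout[i] * cf[i];
        ydot[i]  += ex;
        to_blood -= ex;
    }

    /* epithelial absorption to systemic blood */
    for (i = 3; i <= 6; i++) {
        double fab = kabs[i] * y[i];
        ydot[i]  -= fab;
        to_blood += fab;
    }
    ydot[0] += to_blood;

    /* inhalation: deposition on lung and nasal epithelia */
    double inhaled = 0.0;
    if (p[3] > 0.0 && p[2] > 0.0) {
        double d = p[2] * p[1];         /* air (ug/L) * q_p (L/h) */
        ydot[4] += p[7] * d;            /* lung        */
        ydot[5] += p[5] * d;            /* nasal olf.  */
        ydot[6] += p[6] * d;            /* nasal resp. */
        inhaled  = (p[5] + p[6] + p[7]) * d;
    }

    /* direct olfactory transport: olfactory epithelium -> olfactory bulb */
    double folf = p[8] * y[5];
    ydot[5] -= folf;
    ydot[7] += folf;

    /* diet into the gut lumen; saturable lumen -> epithelium uptake */
    double alum = y[2];
    double hill = (p[11] > 0.0) ? 1.0 + pow(alum / p[11], p[12]) : 1.0;
    double gabs = p[9] * alum / hill;
    double ffec = p[10] * alum;
    ydot[2] += p[4] - gabs - ffec;
    ydot[3] += gabs;

    /* enterocyte sloughing to feces */
    double fslough = p[13] * y[3];
    ydot[3] -= fslough;

    /* inducible biliary excretion from liver free Mn */
    double cfl  = cf[1];
    double find = 1.0;
    if (p[15] > 0.0 && cfl > 0.0) {
        double hn = pow(cfl / p[16], p[17]);
        if (!R_FINITE(hn) || hn > 1e15)
            find += p[15];              /* fully induced */
        else
            find += p[15] * hn / (1.0 + hn);
    }
    double fbile = p[14] * find * cfl;
    ydot[1] -= fbile;
    if (p[18] > 0.0)
        ydot[2] += fbile;               /* enterohepatic recirculation */

    /* cumulative counters */
    ydot[28] = p[4] + inhaled;
    ydot[29] = ffec + fslough + (p[18] > 0.0 ? 0.0 : fbile);
    ydot[30] = fbile;
}

void mnpbpk_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    rhs_core(*t, y, ydot);
}

/* direct evaluation from R, for tests and the Newton steady-state solver */
SEXP mnpbpk_rhs_call(SEXP state, SEXP parms)
{
    if (LENGTH(parms) != N_PAR)
        error("parameter vector must have length %d", N_PAR);
    if (LENGTH(state) != 2 * N_CMT + 3)
        error("state vector must have length %d", 2 * N_CMT + 3);
    memcpy(p, REAL(parms), N_PAR * sizeof(double));
    SEXP out = PROTECT(allocVector(REALSXP, LENGTH(state)));
    rhs_core(0.0, REAL(state), REAL(out));
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef callMethods[] = {
    {"mnpbpk_rhs_call", (DL_FUNC) &mnpbpk_rhs_call, 2},
    {NULL, NULL, 0}
};

void R_init_mnpbpk(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
    R_RegisterCCallable("mnpbpk", "mnpbpk_derivs", (DL_FUNC) &mnpbpk_derivs);
}
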