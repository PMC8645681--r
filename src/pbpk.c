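/* Compiled right-hand side of the whole-body PBPK system.
 *
 * State layout (0-based):
 *   0..8    gut solid amounts per segment (mg)
 *   9..17   gut dissolved amounts per segment (mg)
 *   18..29  tissue amounts: adipose, bone, brain, gut, heart, kidney, liver,
 *           lung, muscle, skin, spleen, pancreas (mg)
 *   30      arterial blood amount, 31 venous blood amount (mg)
 *   32..35  relative enzyme amounts: liver CYP3A4/3A5/2D6, gut CYP3A4
 *   36..40  cumulative ledgers: absorbed, gut metabolized, fecal,
 *           hepatic metabolized, renal (mg)
 *
 * Parameter vector layout mirrors pack_params() in R/engine.R.
 */
#include <R.h>
#include <math.h>

#define NPARMS 200

static double parms[NPARMS];

void init_pbpk(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void derivs_pbpk(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double *p = parms;
    const double mw = p[0], bp = p[1], fu = p[2], co = p[3];
    const double v_art = p[4], v_ven = p[5];
    const double clint_gut = p[6], q_villi = p[7], ki_gut = p[8];
    const double clr = p[9];
    const int force_linear = (int) p[10];
    const double q_liver_out = p[11];
    const double *v = p + 12, *q = p + 24, *kp = p + 36;
    const double *vmax = p + 48, *km = p + 51, *ki = p + 54;
    const double *kdeg = p + 57, *indmax = p + 61, *indc50 = p + 65;
    const double *kinact = p + 69, *k_i = p + 73;
    const double *gv = p + 77, *gkt = p + 86, *gka = p + 95, *gss = p + 104;
    const double kd = p[113];
    const int has_perp = (int) p[114];
    const double pcoef = p[115], pke = p[116], pka = p[117], pfu = p[118];
    const int n_dose = (int) p[119];
    const double inf_rate = p[120], inf_t0 = p[121], inf_t1 = p[122];
    const double *dose_t = p + 123;

    /* unbound perpetrator concentration (uM) */
    double iu = 0.0;
    if (has_perp) {
        double s = 0.0;
        for (int i = 0; i < n_dose; i++) {
            double dt = *t - dose_t[i];
            if (dt > 0.0)
                s += exp(-pke * dt) - exp(-pka * dt);
        }
        iu = pcoef * s * pfu;
        if (iu < 0.0) iu = 0.0;
    }

    /* gut subsystem */
    double abs_flux = 0.0, fecal = 0.0;
    double out_s_prev = 0.0, out_d_prev = 0.0;
    for (int i = 0; i < 9; i++) {
        double sol = y[i] > 0.0 ? y[i] : 0.0;
        double dis = y[9 + i] > 0.0 ? y[9 + i] : 0.0;
        double drive = 1.0 - (dis / gv[i]) / gss[i];
        if (drive < 0.0) drive = 0.0;
        double diss = kd * pow(sol, 2.0 / 3.0) * drive;
        double out_s = gkt[i] * sol, out_d = gkt[i] * dis;
        double a = gka[i] * dis;
        ydot[i] = out_s_prev - out_s - diss;
        ydot[9 + i] = out_d_prev - out_d + diss - a;
        abs_flux += a;
        out_s_prev = out_s;
        out_d_prev = out_d;
        if (i == 8) fecal = out_s + out_d;
    }

    /* enterocyte first pass */
    double E_gut = y[35];
    double clg = clint_gut * E_gut / (1.0 + iu / ki_gut);
    double e_frac = clg > 0.0 ? clg / (clg + q_villi) : 0.0;
    double gut_met = abs_flux * e_frac;
    double portal = abs_flux - gut_met;

    /* circulation */
    double ct[12], cout[12];
    for (int i = 0; i < 12; i++) {
        ct[i] = y[18 + i] / v[i];
        cout[i] = ct[i] * bp / kp[i];
    }
    double cart = y[30] / v_art, cven = y[31] / v_ven;

    double cu = ct[6] * fu / kp[6] * 1000.0 / mw;   /* liver unbound, uM */
    double met = 0.0;
    for (int j = 0; j < 3; j++) {
        double km_app = km[j] * (1.0 + iu / ki[j]);
        if (force_linear)
            met += y[32 + j] * vmax[j] / km_app * cu;
        else
            met += y[32 + j] * vmax[j] * cu / (km_app + cu);
    }
    double renal = clr * cart / bp;

    for (int i = 0; i < 12; i++)
        ydot[18 + i] = q[i] * (cart - cout[i]);
    ydot[18 + 3] += portal;                          /* gut tissue */
    ydot[18 + 5] -= renal;                           /* kidney */
    ydot[18 + 6] = q[6] * cart + q[3] * cout[3] + q[10] * cout[10] +
        q[11] * cout[11] - q_liver_out * cout[6] - met;   /* liver */
    ydot[18 + 7] = co * (cven - cout[7]);            /* lung */

    ydot[30] = co * cout[7] - co * cart;
    double ven_in = q_liver_out * cout[6];
    static const int direct[7] = {0, 1, 2, 4, 5, 8, 9};
    for (int k = 0; k < 7; k++)
        ven_in += q[direct[k]] * cout[direct[k]];
    ydot[31] = ven_in - co * cven;
    if (inf_rate > 0.0 && *t >= inf_t0 && *t <= inf_t1)
        ydot[31] += inf_rate;

    /* enzyme turnover */
    for (int j = 0; j < 4; j++) {
        double ind = indmax[j] > 0.0 && iu > 0.0 ?
            indmax[j] * iu / (indc50[j] + iu) : 0.0;
        double ina = kinact[j] > 0.0 && iu > 0.0 ?
            kinact[j] * iu / (k_i[j] + iu) : 0.0;
        ydot[32 + j] = kdeg[j] * (1.0 + ind) - kdeg[j] * y[32 + j] -
            ina * y[32 + j];
    }

    /* ledgers */
    ydot[36] = abs_flux;
    ydot[37] = gut_met;
    ydot[38] = fecal;
    ydot[39] = met;
    ydot[40] = renal;
}
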