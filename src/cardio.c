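/* Closed-loop 0D cardiovascular model: four elastance chambers, four
 * dynamic valves (second-order opening-angle ODE), systemic and pulmonary
 * windkessel/inertance segments.  Compiled right-hand side for deSolve.
 *
 * State vector (22):
 *  0 V_la  1 V_lv  2 V_ra  3 V_rv
 *  4 th_mi 5 om_mi 6 th_ao 7 om_ao 8 th_ti 9 om_ti 10 th_po 11 om_po
 * 12 P_sas 13 Q_sas 14 P_sat 15 Q_sat 16 P_svn
 * 17 P_pas 18 Q_pas 19 P_pat 20 Q_pat 21 P_pvn
 *
 * Parameter vector layout (see params.R, pack_parms()):
 *  0..11  per-chamber (E_min, E_max, V_un) for la, lv, ra, rv
 * 12..35  per-valve (CQ, Kp, Kf, Kb, Kv, theta_max) for mi, ao, ti, po
 * 36..45  systemic:  C_sas R_sas L_sas C_sat R_sat L_sat R_sar R_scp C_svn R_svn
 * 46..55  pulmonary: C_pas R_pas L_pas C_pat R_pat L_pat R_par R_pcp C_pvn R_pvn
 * 56..60  ts1_frac ts2_frac tpwb_frac tpww_frac rr_ref
 * 61      atria_passive
 * 62      n_beats in this integration chunk
 * 63..    beat boundary times t0[0..n_beats] (chunk-local, increasing)
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define AFCIRC_MAXBEATS 400
#define AFCIRC_NPARMS (63 + AFCIRC_MAXBEATS + 1)

static double p[AFCIRC_NPARMS];

void cardio_initmod(void (*odeparms)(int *, double *))
{
    int n = AFCIRC_NPARMS;
    odeparms(&n, p);
}

/* piecewise-cosine ventricular activation, C1, e in [0,1]; systolic
 * durations scale with sqrt(rr * rr_ref) (Bazett-type rate correction,
 * anchored so that fractions ts1f/ts2f hold exactly at rr == rr_ref) */
static double act_ventricle(double tb, double rr, double ts1f, double ts2f,
                            double rr_ref)
{
    double b = sqrt(rr * rr_ref);
    double ts2 = ts2f * b;
    if (ts2 > 0.9 * rr) ts2 = 0.9 * rr;
    double ts1 = ts1f / ts2f * ts2;
    if (tb < ts1)
        return 0.5 * (1.0 - cos(M_PI * tb / ts1));
    if (tb < ts2)
        return 0.5 * (1.0 + cos(M_PI * (tb - ts1) / (ts2 - ts1)));
    return 0.0;
}

/* atrial activation: cosine bump starting at tpwb, wrapping past beat end */
static double act_atrium(double tb, double rr, double tpwbf, double tpwwf)
{
    double tpwb = tpwbf * rr, tpww = tpwwf * rr;
    double u = tb - tpwb;
    if (u < 0.0) u += rr;
    if (u >= 0.0 && u < tpww)
        return 0.5 * (1.0 - cos(2.0 * M_PI * u / tpww));
    return 0.0;
}

static double clampd(double x, double lo, double hi)
{
    return x < lo ? lo : (x > hi ? hi : x);
}

/* orifice area ratio of the leaflet model, 0 closed .. 1 fully open */
static double area_ratio(double th, double thmax)
{
    double c = (1.0 - cos(clampd(th, 0.0, thmax))) / (1.0 - cos(thmax));
    return c * c;
}

static double valve_q(double dp, double th, double cq, double thmax)
{
    double ar = area_ratio(th, thmax);
    return cq * ar * (dp >= 0.0 ? sqrt(dp) : -sqrt(-dp));
}

/* second-order leaflet dynamics; the stops at 0 and theta_max are smooth
 * stiff contacts (restoring spring + one-way damper), keeping the rhs
 * continuous for the multistep solver */
#define AFCIRC_KSTOP 1e6
#define AFCIRC_DSTOP 2e3

static void valve_dyn(double th, double om, double dp, double q,
                      const double *vp, double *dth, double *dom)
{
    double kp = vp[1], kf = vp[2], kb = vp[3], kv = vp[4], thmax = vp[5];
    double thc = clampd(th, 0.0, thmax);
    double torque = kp * dp * cos(thc) - kf * om + kb * q * cos(thc)
        - kv * q * sin(2.0 * thc);
    if (th > thmax) {
        torque += -AFCIRC_KSTOP * (th - thmax);
        if (om > 0.0) torque += -AFCIRC_DSTOP * om;
    } else if (th < 0.0) {
        torque += -AFCIRC_KSTOP * th;
        if (om < 0.0) torque += -AFCIRC_DSTOP * om;
    }
    *dth = om;
    *dom = torque;
}

void cardio_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    int nb = (int) p[62];
    const double *t0 = p + 63;
    double tt = *t;
    int lo = 0, hi = nb - 1, ib;

    if (tt <= t0[0]) tt = t0[0];
    if (tt >= t0[nb]) tt = t0[nb] - 1e-12;
    while (lo < hi) {               /* binary search for the current beat */
        int mid = (lo + hi + 1) / 2;
        if (tt >= t0[mid]) lo = mid; else hi = mid - 1;
    }
    ib = lo;
    {
    double rr = t0[ib + 1] - t0[ib];
    double tb = tt - t0[ib];

    double ev = act_ventricle(tb, rr, p[56], p[57], p[60]);
    double ea = (p[61] > 0.5) ? 0.0 : act_atrium(tb, rr, p[58], p[59]);

    double E_la = p[0] + ea * (p[1] - p[0]);
    double E_lv = p[3] + ev * (p[4] - p[3]);
    double E_ra = p[6] + ea * (p[7] - p[6]);
    double E_rv = p[9] + ev * (p[10] - p[9]);

    double P_la = E_la * (y[0] - p[2]);
    double P_lv = E_lv * (y[1] - p[5]);
    double P_ra = E_ra * (y[2] - p[8]);
    double P_rv = E_rv * (y[3] - p[11]);

    double P_sas = y[12], Q_sas = y[13], P_sat = y[14], Q_sat = y[15],
        P_svn = y[16];
    double P_pas = y[17], Q_pas = y[18], P_pat = y[19], Q_pat = y[20],
        P_pvn = y[21];

    const double *vmi = p + 12, *vao = p + 18, *vti = p + 24, *vpo = p + 30;

    double Q_mi = valve_q(P_la - P_lv, y[4], vmi[0], vmi[5]);
    double Q_ao = valve_q(P_lv - P_sas, y[6], vao[0], vao[5]);
    double Q_ti = valve_q(P_ra - P_rv, y[8], vti[0], vti[5]);
    double Q_po = valve_q(P_rv - P_pas, y[10], vpo[0], vpo[5]);

    double Q_svn = (P_svn - P_ra) / p[45];
    double Q_pvn = (P_pvn - P_la) / p[55];

    ydot[0] = Q_pvn - Q_mi;
    ydot[1] = Q_mi - Q_ao;
    ydot[2] = Q_svn - Q_ti;
    ydot[3] = Q_ti - Q_po;

    valve_dyn(y[4], y[5], P_la - P_lv, Q_mi, vmi, ydot + 4, ydot + 5);
    valve_dyn(y[6], y[7], P_lv - P_sas, Q_ao, vao, ydot + 6, ydot + 7);
    valve_dyn(y[8], y[9], P_ra - P_rv, Q_ti, vti, ydot + 8, ydot + 9);
    valve_dyn(y[10], y[11], P_rv - P_pas, Q_po, vpo, ydot + 10, ydot + 11);

    ydot[12] = (Q_ao - Q_sas) / p[36];
    ydot[13] = (P_sas - P_sat - p[37] * Q_sas) / p[38];
    ydot[14] = (Q_sas - Q_sat) / p[39];
    ydot[15] = (P_sat - P_svn - (p[40] + p[42] + p[43]) * Q_sat) / p[41];
    ydot[16] = (Q_sat - Q_svn) / p[44];

    ydot[17] = (Q_po - Q_pas) / p[46];
    ydot[18] = (P_pas - P_pat - p[47] * Q_pas) / p[48];
    ydot[19] = (Q_pas - Q_pat) / p[49];
    ydot[20] = (P_pat - P_pvn - (p[50] + p[52] + p[53]) * Q_pat) / p[51];
    ydot[21] = (Q_pat - Q_pvn) / p[54];

    if (ip[0] >= 10) {
        yout[0] = P_la; yout[1] = P_lv; yout[2] = P_ra; yout[3] = P_rv;
        yout[4] = Q_mi; yout[5] = Q_ao; yout[6] = Q_ti; yout[7] = Q_po;
        yout[8] = ev;   yout[9] = ea;
    }
    }
}

static const R_CMethodDef cMethods[] = {
    {"cardio_initmod", (DL_FUNC) &cardio_initmod, 1},
    {"cardio_derivs",  (DL_FUNC) &cardio_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_afcirc(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
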