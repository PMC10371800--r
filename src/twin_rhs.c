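/* Compiled right-hand side of the fed-batch digital twin, for deSolve.
 *
 * State y (neq = 11):
 *   0 V, 1 Xv, 2 Xd, 3 glc, 4 gln, 5 asn, 6 lac, 7 nh4, 8 ala, 9 P,
 *   10 glc_fed (cumulative glucose fed, mmol)
 * Parameters (31): the 25 kinetic parameters in kinetic_parameters()
 * field order, then the 6 feed-medium concentrations (glc slot unused).
 * Forcings (3): C_feed_glc, F_in, F_out, linearly interpolated by
 * deSolve from the policy knots.
 *
 * Must stay in lockstep with rhs_core() in R/twin.R, which is the
 * reference implementation used by the public API and the tests.
 */

#include <R.h>
#include <math.h>

static double p[31];
static double forc[3];

void twin_init(void (*odeparms)(int *, double *))
{
    int n = 31;
    odeparms(&n, p);
}

void twin_forc(void (*odeforcs)(int *, double *))
{
    int n = 3;
    odeforcs(&n, forc);
}

void twin_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double V = y[0], Xv = y[1], Xd = y[2], P = y[9];
    double C[6];
    int i;
    for (i = 0; i < 6; i++)
        C[i] = y[3 + i] > 0 ? y[3 + i] : 0;
    double glc = C[0], gln = C[1], asn = C[2], lac = C[3], nh4 = C[4];

    double mu_max = p[0], K_glc = p[1], K_gln = p[2], K_asn = p[3];
    double KI_lac = p[4], KI_amm = p[5], kd0 = p[6], kd_amm = p[7];
    double Y_xg = p[8], m_glc = p[9], K_mglc = p[10];
    double Y_lg = p[11], q_lac_max = p[12], K_lac = p[13];
    double glc_switch = p[14], switch_width = p[15];
    double Y_xgln = p[16], m_gln = p[17], K_mgln = p[18], Y_ag = p[19];
    double q_asn_max = p[20], K_asn_up = p[21], Y_ala = p[22];
    double alpha = p[23], beta = p[24];

    double mu = mu_max * (glc / (K_glc + glc)) * (gln / (K_gln + gln)) *
                (asn / (K_asn + asn)) * (KI_lac / (KI_lac + lac)) *
                (KI_amm / (KI_amm + nh4));
    double mud = kd0 + kd_amm * nh4;
    double q_glc_up = mu / Y_xg + m_glc * glc / (K_mglc + glc);
    double q_gln_up = mu / Y_xgln + m_gln * gln / (K_mgln + gln);
    double s = 1.0 / (1.0 + exp(-(glc - glc_switch) / switch_width));

    double q[6];
    q[0] = -q_glc_up;
    q[1] = -q_gln_up;
    q[2] = -q_asn_max * asn / (K_asn_up + asn);
    q[3] = s * Y_lg * q_glc_up - (1.0 - s) * q_lac_max * lac / (K_lac + lac);
    q[4] = Y_ag * q_gln_up;
    q[5] = Y_ala * q_gln_up;
    double qP = alpha * mu + beta * glc / (K_glc + glc);

    double cglc = forc[0], F_in = forc[1], F_out = forc[2];
    double dil = F_in / V;

    ydot[0] = F_in - F_out;
    ydot[1] = (mu - mud) * Xv - dil * Xv;
    ydot[2] = mud * Xv - dil * Xd;
    for (i = 0; i < 6; i++) {
        double Cf = (i == 0) ? cglc : p[25 + i];
        ydot[3 + i] = dil * (Cf - C[i]) + q[i] * Xv;
    }
    ydot[9] = qP * Xv - dil * P;
    ydot[10] = F_in * cglc;
}
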