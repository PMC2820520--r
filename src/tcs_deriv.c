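/* Time derivative of the two-component-system reaction network, in the
 * deSolve compiled-model convention (initializer + derivative callback).
 *
 * State order (must match .TCS_SPECIES in R/network.R):
 *   0 mRNA_tcs, 1 mRNA_ds, 2 SHK, 3 SHKP, 4 RR, 5 RRP,
 *   6 C_t (SHK.RRP), 7 C_p (SHKP.RR), 8 RRP2, 9 DS
 *
 * Parameter order (must match .parmVector in R/network.R):
 *   0 k_ap, 1 k_ad, 2 k_ph, 3 k_b, 4 k_d, 5 k_b1, 6 k_d1, 7 k_pt, 8 k_tp,
 *   9 k_RRPdm, 10 k_RRPmd, 11 k_txn, 12 k_txnbasal, 13 K_m, 14 K_mDS,
 *   15 k_SKtsn, 16 tsn_mult, 17 k_mRNAdeg, 18 k_exp, 19 K_mexp,
 *   20 k_exd, 21 K_mexd, 22 k_dil,
 *   23 variant (0 wild_type, 1 open_loop, 2 no_feedback, 3 circuit_I,
 *               4 circuit_II),
 *   24 R0, 25 const_tcs_txn, 26 const_shk_txn, 27 const_rr_txn
 */

#include <R.h>

#define N_PARMS 28

static double p[N_PARMS];

void tcs_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

/* saturating (Michaelis-Menten) term with the substrate clamped at zero so
 * that transient tiny negative excursions of the integrator cannot flip the
 * sign of a production flux */
static double mm(double vmax, double km, double s)
{
    if (s < 0.0) s = 0.0;
    return vmax * s / (km + s);
}

void tcs_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double mT = y[0], mD = y[1], SHK = y[2], SHKP = y[3], RR = y[4],
           RRP = y[5], Ct = y[6], Cp = y[7], R2 = y[8], DS = y[9];
    int variant = (int) p[23];

    double A1 = (variant == 1) ? p[24] : R2;            /* open loop: R0 */
    double v1 = (variant == 2) ? p[25] : mm(p[11], p[13], A1);
    double v3 = (variant == 2) ? 0.0 : p[12];
    double v2 = mm(p[11], p[14], R2);
    double v4 = p[12];
    double v6 = (variant == 3) ? p[26] : p[15] * mT;
    double v7 = (variant == 4) ? p[27] : p[16] * p[15] * mT;
    double v8 = p[15] * mD;
    double v10 = p[0] * SHK;
    double v11 = p[1] * SHKP;
    double v12 = p[3] * SHK * RRP;
    double v13 = p[5] * SHKP * RR;
    double v14 = p[7] * Cp;
    double v15 = p[8] * Ct;
    double v16 = p[4] * Ct;
    double v17 = p[6] * Cp;
    double v18 = p[2] * Ct;
    double v19 = mm(p[18], p[19], RR);
    double v20 = mm(p[20], p[21], RRP);
    double v21 = p[9] * RRP * RRP;
    double v22 = p[10] * R2;
    double kdil = p[22], kmd = p[17];

    ydot[0] = v1 + v3 - kmd * mT;
    ydot[1] = v2 + v4 - kmd * mD;
    ydot[2] = v6 - v10 + v11 - v12 + v16 + v18 - kdil * SHK;
    ydot[3] = v10 - v11 - v13 + v17 - kdil * SHKP;
    ydot[4] = v7 - v13 + v17 + v18 - v19 + v20 - kdil * RR;
    ydot[5] = -v12 + v16 + v19 - v20 - 2.0 * v21 + 2.0 * v22 - kdil * RRP;
    ydot[6] = v12 + v14 - v15 - v16 - v18 - kdil * Ct;
    ydot[7] = v13 - v14 + v15 - v17 - kdil * Cp;
    ydot[8] = v21 - v22 - kdil * R2;
    ydot[9] = v8 - kdil * DS;
}
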