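/* Compiled right-hand side of the 16-variable mammalian circadian clock
 * model, in the deSolve compiled-code interface.  The parameter vector is
 * laid out by clock_parms_vector() on the R side:
 *
 *   [0..51]   52 kinetic parameters (fixed order, see R/clock.R)
 *   [52]      light multiplier applied to v_sP during the light phase
 *   [53]      forcing period in hours (<= 0 disables forcing)
 *   [54]      light-phase duration in hours
 *   [55..130] 76 process masks (1 = keep, 0 = drop), ordered f_1,1..f_16,4
 *
 * Each of the 76 signed process terms is computed individually and then
 * masked, so reduced sub-models use the same code path as the full model.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 131
static double p[N_PARMS];

void clock_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

/* kinetic parameter accessors, indices match clock_parms_vector() */
#define k1    p[0]
#define k2    p[1]
#define k3    p[2]
#define k4    p[3]
#define k5    p[4]
#define k6    p[5]
#define k7    p[6]
#define k8    p[7]
#define K_AP  p[8]
#define K_AC  p[9]
#define K_IB  p[10]
#define k_dmb p[11]
#define k_dmc p[12]
#define k_dmp p[13]
#define k_dnc p[14]
#define k_dn  p[15]
#define K_d   p[16]
#define K_dp  p[17]
#define K_p   p[18]
#define K_mB  p[19]
#define K_mC  p[20]
#define K_mP  p[21]
#define k_sB  p[22]
#define k_sC  p[23]
#define k_sP  p[24]
#define HILLN p[25]
#define HILLM p[26]
#define V_1B  p[27]
#define V_1C  p[28]
#define V_1P  p[29]
#define V_1PC p[30]
#define V_2B  p[31]
#define V_2C  p[32]
#define V_2P  p[33]
#define V_2PC p[34]
#define V_3B  p[35]
#define V_3PC p[36]
#define V_4B  p[37]
#define V_4PC p[38]
#define v_dBC p[39]
#define v_dBN p[40]
#define v_dCC p[41]
#define v_dIN p[42]
#define v_dPC p[43]
#define v_dPCC p[44]
#define v_dPCN p[45]
#define v_mB  p[46]
#define v_mC  p[47]
#define v_mP  p[48]
#define v_sB  p[49]
#define v_sC  p[50]
#define v_sP  p[51]
#define LIGHT_SCALE p[52]
#define PERIOD      p[53]
#define DAY_LEN     p[54]
#define MASK(i)     p[55 + (i)]

void clock_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double M_P = y[0],  M_C = y[1],  M_B = y[2],  P_C = y[3];
    const double C_C = y[4],  P_CP = y[5], C_CP = y[6], PC_C = y[7];
    const double PC_N = y[8], PC_CP = y[9], PC_NP = y[10], B_C = y[11];
    const double B_CP = y[12], B_N = y[13], B_NP = y[14], I_N = y[15];

    double vsP_eff = v_sP;
    if (PERIOD > 0) {
        double tau = fmod(*t, PERIOD);
        if (tau < 0) tau += PERIOD;
        if (tau == 0.0 && *t > 0) tau = PERIOD;  /* left-continuous */
        if (tau < DAY_LEN) vsP_eff = v_sP * LIGHT_SCALE;
    }

    const double BNn  = pow(B_N, HILLN);
    const double BNm  = pow(B_N, HILLM);
    double f[76];

    /* M_P: Per mRNA */
    f[0] =  vsP_eff * BNn / (pow(K_AP, HILLN) + BNn);
    f[1] = -v_mP * M_P / (K_mP + M_P);
    f[2] = -k_dmp * M_P;
    /* M_C: Cry mRNA */
    f[3] =  v_sC * BNn / (pow(K_AC, HILLN) + BNn);
    f[4] = -v_mC * M_C / (K_mC + M_C);
    f[5] = -k_dmc * M_C;
    /* M_B: Bmal1 mRNA (repression cooperativity m) */
    f[6] =  v_sB * pow(K_IB, HILLM) / (pow(K_IB, HILLM) + BNm);
    f[7] = -v_mB * M_B / (K_mB + M_B);
    f[8] = -k_dmb * M_B;
    /* P_C: cytosolic PER */
    f[9]  =  k_sP * M_P;
    f[10] = -V_1P * P_C / (K_p + P_C);
    f[11] =  V_2P * P_CP / (K_dp + P_CP);
    f[12] =  k4 * PC_C;
    f[13] = -k3 * P_C * C_C;
    f[14] = -k_dn * P_C;
    /* C_C: cytosolic CRY */
    f[15] =  k_sC * M_C;
    f[16] = -V_1C * C_C / (K_p + C_C);
    f[17] =  V_2C * C_CP / (K_dp + C_CP);
    f[18] =  k4 * PC_C;
    f[19] = -k3 * P_C * C_C;
    f[20] = -k_dnc * C_C;
    /* P_CP */
    f[21] =  V_1P * P_C / (K_p + P_C);
    f[22] = -V_2P * P_CP / (K_dp + P_CP);
    f[23] = -v_dPC * P_CP / (K_d + P_CP);
    f[24] = -k_dn * P_CP;
    /* C_CP */
    f[25] =  V_1C * C_C / (K_p + C_C);
    f[26] = -V_2C * C_CP / (K_dp + C_CP);
    f[27] = -v_dCC * C_CP / (K_d + C_CP);
    f[28] = -k_dn * C_CP;
    /* PC_C: cytosolic PER-CRY */
    f[29] = -V_1PC * PC_C / (K_p + PC_C);
    f[30] =  V_2PC * PC_CP / (K_dp + PC_CP);
    f[31] = -k4 * PC_C;
    f[32] =  k3 * P_C * C_C;
    f[33] =  k2 * PC_N;
    f[34] = -k1 * PC_C;
    f[35] = -k_dn * PC_C;
    /* PC_N: nuclear PER-CRY */
    f[36] = -V_3PC * PC_N / (K_p + PC_N);
    f[37] =  V_4PC * PC_NP / (K_dp + PC_NP);
    f[38] = -k2 * PC_N;
    f[39] =  k1 * PC_C;
    f[40] = -k7 * B_N * PC_N;
    f[41] =  k8 * I_N;
    f[42] = -k_dn * PC_N;
    /* PC_CP */
    f[43] =  V_1PC * PC_C / (K_p + PC_C);
    f[44] = -V_2PC * PC_CP / (K_dp + PC_CP);
    f[45] = -v_dPCC * PC_CP / (K_d + PC_CP);
    f[46] = -k_dn * PC_CP;
    /* PC_NP */
    f[47] =  V_3PC * PC_N / (K_p + PC_N);
    f[48] = -V_4PC * PC_NP / (K_dp + PC_NP);
    f[49] = -v_dPCN * PC_NP / (K_d + PC_NP);
    f[50] = -k_dn * PC_NP;
    /* B_C: cytosolic BMAL1 */
    f[51] =  k_sB * M_B;
    f[52] = -V_1B * B_C / (K_p + B_C);
    f[53] =  V_2B * B_CP / (K_dp + B_CP);
    f[54] = -k5 * B_C;
    f[55] =  k6 * B_N;
    f[56] = -k_dn * B_C;
    /* B_CP */
    f[57] =  V_1B * B_C / (K_p + B_C);
    f[58] = -V_2B * B_CP / (K_dp + B_CP);
    f[59] = -v_dBC * B_CP / (K_d + B_CP);
    f[60] = -k_dn * B_CP;
    /* B_N: nuclear BMAL1 */
    f[61] = -V_3B * B_N / (K_p + B_N);
    f[62] =  V_4B * B_NP / (K_dp + B_NP);
    f[63] =  k5 * B_C;
    f[64] = -k6 * B_N;
    f[65] = -k7 * B_N * PC_N;
    f[66] =  k8 * I_N;
    f[67] = -k_dn * B_N;
    /* B_NP */
    f[68] =  V_3B * B_N / (K_p + B_N);
    f[69] = -V_4B * B_NP / (K_dp + B_NP);
    f[70] = -v_dBN * B_NP / (K_d + B_NP);
    f[71] = -k_dn * B_NP;
    /* I_N: PER-CRY:CLOCK-BMAL1 complex */
    f[72] = -k8 * I_N;
    f[73] =  k7 * B_N * PC_N;
    f[74] = -v_dIN * I_N / (K_d + I_N);
    f[75] = -k_dn * I_N;

    static const int nterm[16] = {3,3,3,6,6,4,4,7,7,4,4,6,4,7,4,4};
    int idx = 0;
    for (int i = 0; i < 16; i++) {
        double s = 0.0;
        for (int j = 0; j < nterm[i]; j++, idx++)
            if (MASK(idx) != 0.0) s += f[idx];
        ydot[i] = s;
    }
}
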