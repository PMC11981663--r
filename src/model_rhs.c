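/* Compiled right-hand sides for the multi-layer CAR-T / tumour /
 * macrophage / IL-6 model, in deSolve's compiled-code convention.
 *
 * Parameter vector layout (26 doubles, see .parms_vector in R/):
 *  0 eta      1 mu_I    2 kappa   3 mu_E    4 epsilon  5 theta
 *  6 mu_P     7 rho     8 K       9 gamma  10 A       11 B      12 g0
 * 13 sigma_M 14 delta_M 15 sigma_I 16 delta_I 17 alpha
 * 18 beta_B  19 beta_K  20 beta_C 21 C
 * 22 gate flag (0/1)
 * 23 beta scale damp  24 beta scale antigen  25 beta scale cd40
 *
 * Full-system state: C_I, C_E, C_P, T_P, T_N [, M_i, M_a, IL6,
 *   Ma_damp, Ma_antigen, Ma_cd40, J_damp, J_antigen, J_cd40]
 * (neq = 5 without the cytokine layer, 14 with it).
 */

#include <R.h>

static double parms[26];

#define P_ETA     parms[0]
#define P_MU_I    parms[1]
#define P_KAPPA   parms[2]
#define P_MU_E    parms[3]
#define P_EPS     parms[4]
#define P_THETA   parms[5]
#define P_MU_P    parms[6]
#define P_RHO     parms[7]
#define P_K       parms[8]
#define P_GAMMA   parms[9]
#define P_A       parms[10]
#define P_B       parms[11]
#define P_G0      parms[12]
#define P_SIGMA_M parms[13]
#define P_DELTA_M parms[14]
#define P_SIGMA_I parms[15]
#define P_DELTA_I parms[16]
#define P_ALPHA   parms[17]
#define P_BETA_B  parms[18]
#define P_BETA_K  parms[19]
#define P_BETA_C  parms[20]
#define P_C       parms[21]
#define P_GATE    parms[22]
#define P_BS_D    parms[23]
#define P_BS_A    parms[24]
#define P_BS_C    parms[25]

void initmod_cartcrs(void (*odeparms)(int *, double *))
{
    int n = 26;
    odeparms(&n, parms);
}

/* proliferation gate: linear ramp on [0.5, 1] cells */
static double grow_gate(double x)
{
    double g = 2.0 * (x - 0.5);
    if (g < 0.0) g = 0.0;
    if (g > 1.0) g = 1.0;
    return g;
}

static double clamp0(double x) { return x < 0.0 ? 0.0 : x; }

void derivs_cartcrs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double C_I = clamp0(y[0]), C_E = clamp0(y[1]), C_P = clamp0(y[2]);
    double T_P = clamp0(y[3]), T_N = clamp0(y[4]);
    double F = T_P / (P_A + T_P);
    double kill = P_GAMMA * C_E / (P_B + C_E);
    double gate = P_GATE != 0.0;
    double gE = gate ? grow_gate(C_E) : 1.0;
    double gTP = gate ? grow_gate(T_P) : 1.0;
    double gTN = gate ? grow_gate(T_N) : 1.0;
    double crowd = 1.0 - (T_P + T_N) / P_K;

    ydot[0] = -P_ETA * F * C_I - P_MU_I * C_I;
    ydot[1] = P_ETA * F * C_I + gE * P_KAPPA * F * C_E
              - P_EPS * (1.0 - F) * C_E + P_THETA * F * C_P - P_MU_E * C_E;
    ydot[2] = P_EPS * (1.0 - F) * C_E - P_THETA * F * C_P - P_MU_P * C_P;
    ydot[3] = gTP * P_RHO * T_P * crowd - kill * T_P;
    ydot[4] = gTN * P_RHO * T_N * crowd - P_G0 * kill * T_N;

    if (*neq == 5) return;

    {
        double M_i = clamp0(y[5]), M_a = clamp0(y[6]), IL6 = clamp0(y[7]);
        double Ma1 = clamp0(y[8]), Ma2 = clamp0(y[9]), Ma3 = clamp0(y[10]);
        double h1 = P_BS_D * P_BETA_K * C_E / (P_B + C_E)
                    * (T_P + P_G0 * T_N);
        double h2 = P_BS_A * P_BETA_B * F * C_E;
        double h3 = P_BS_C * P_BETA_C * M_a / (P_C + M_a) * C_E;
        double h = h1 + h2 + h3;

        ydot[5] = P_SIGMA_M - h * M_i - P_DELTA_M * M_i;
        ydot[6] = h * M_i - P_DELTA_M * M_a;
        ydot[7] = P_SIGMA_I + P_ALPHA * M_a - P_DELTA_I * IL6;
        ydot[8] = h1 * M_i - P_DELTA_M * Ma1;
        ydot[9] = h2 * M_i - P_DELTA_M * Ma2;
        ydot[10] = h3 * M_i - P_DELTA_M * Ma3;
        ydot[11] = h1 * M_i;
        ydot[12] = h2 * M_i;
        ydot[13] = h3 * M_i;
    }
}

/* cytokine layer alone, driven by interpolated layer-1 trajectories
 * (forcings: C_E, T_P, T_N); state: M_i, M_a, IL6 */

static double forc[3];
#define F_CE forc[0]
#define F_TP forc[1]
#define F_TN forc[2]

void initforc_cartcrs(void (*odeforcs)(int *, double *))
{
    int n = 3;
    odeforcs(&n, forc);
}

void derivs_cyto_cartcrs(int *neq, double *t, double *y, double *ydot,
                         double *yout, int *ip)
{
    double M_i = clamp0(y[0]), M_a = clamp0(y[1]), IL6 = clamp0(y[2]);
    double C_E = clamp0(F_CE), T_P = clamp0(F_TP), T_N = clamp0(F_TN);
    double F = T_P / (P_A + T_P);
    double h1 = P_BS_D * P_BETA_K * C_E / (P_B + C_E) * (T_P + P_G0 * T_N);
    double h2 = P_BS_A * P_BETA_B * F * C_E;
    double h3 = P_BS_C * P_BETA_C * M_a / (P_C + M_a) * C_E;
    double h = h1 + h2 + h3;

    ydot[0] = P_SIGMA_M - h * M_i - P_DELTA_M * M_i;
    ydot[1] = h * M_i - P_DELTA_M * M_a;
    ydot[2] = P_SIGMA_I + P_ALPHA * M_a - P_DELTA_I * IL6;
}
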