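/* Right-hand sides of the oxygen/MMP ODE system, all model variants,
 * together with the forward sensitivity equations, in the standard
 * deSolve compiled-model form.
 *
 * Parameter block layout (filled by mmp_init via deSolve):
 *   0 supply  1 KE  2 KEi  3 Cf  4 VA  5 KA  6 KAi  7 VU  8 KU
 *   9 r  10 alpha  11 psio  12 D0  13 gamma
 *   14 leakage flag (0/1)
 *   15 target class (1 = ETC inhibitor, 2 = ATP-synthase inhibitor,
 *                    3 = uncoupler)
 *   16 nsens (number of sensitivity parameters)
 *   17.. sensitivity parameter ids:
 *        1 VA  2 KA  3 KAi  4 Cf  5 KE  6 KEi  7 r  8 gamma
 *        9 alpha  10 D0
 *
 * State layout: y[0] = O, y[1] = Psi, then (sO, sPsi) pairs for each
 * sensitivity parameter.
 *
 * Integration always starts at t = 0 with the post-exposure vector
 * field, so the Heaviside gate of the effective-concentration and
 * leakage terms is identically 1 here; pre-exposure evaluation is
 * handled at the R level.
 */

#include <R.h>
#include <math.h>

#define NPARMS 32
static double parms[NPARMS];

void mmp_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void mmp_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double supply = parms[0], KE = parms[1], KEi = parms[2],
        Cf = parms[3], VA = parms[4], KA = parms[5], KAi = parms[6],
        VU = parms[7], KU = parms[8], r = parms[9], alpha = parms[10],
        psio = parms[11], D0 = parms[12], gam = parms[13];
    const int leak = (int) parms[14];
    const int target = (int) parms[15];
    const int nsens = (int) parms[16];

    const double O = y[0], Psi = y[1];
    const double expg = exp(-gam * (*t));
    const double D = D0 * expg;
    const double DE = (target == 1) ? D : 0.0;
    const double DA = (target == 2) ? D : 0.0;
    const double DU = (target == 3) ? D : 0.0;

    const double wE = KEi / (KEi + DE);
    const double wA = KAi / (KAi + DA);
    const double ocr = KE * O * wE;
    const double mmA = Psi / (KA + Psi);
    const double dep = VA * mmA * wA;       /* ATP-synthesis depletion */
    const double unc = VU * DU / (KU + DU); /* uncoupler-mediated flux */
    const double KAP2 = (KA + Psi) * (KA + Psi);

    double fO, fPsi, J00, J10, J11;
    if (leak) {
        /* oxygen stays uninhibited; oxygen term in the Psi equation is
         * the constant supply*Cf, plus linear leakage toward psio */
        fO   = r * (supply - KE * O);
        fPsi = r * (supply * Cf - dep - alpha * (Psi - psio));
        J00  = -r * KE;
        J10  = 0.0;
        J11  = r * (-VA * wA * KA / KAP2 - alpha);
    } else {
        fO   = r * (supply - ocr);
        fPsi = r * (Cf * ocr - dep - unc * Psi);
        J00  = -r * KE * wE;
        J10  = r * Cf * KE * wE;
        J11  = r * (-VA * wA * KA / KAP2 - unc);
    }
    ydot[0] = fO;
    ydot[1] = fPsi;

    if (nsens > 0) {
        /* partials of (fO, fPsi) w.r.t. the active effective dose */
        double dfO_dD = 0.0, dfPsi_dD = 0.0;
        if (target == 1 && !leak) {
            const double q = KE * O * KEi / ((KEi + DE) * (KEi + DE));
            dfO_dD   =  r * q;
            dfPsi_dD = -r * Cf * q;
        } else if (target == 2) {
            dfPsi_dD = r * VA * mmA * KAi / ((KAi + DA) * (KAi + DA));
        } else if (target == 3 && !leak) {
            dfPsi_dD = -r * VU * Psi * KU / ((KU + DU) * (KU + DU));
        }
        const double den = VA - supply * Cf; /* > 0 for a valid model */

        for (int k = 0; k < nsens; k++) {
            const int id = (int) parms[17 + k];
            double dfO = 0.0, dfPsi = 0.0;
            switch (id) {
            case 1: /* VA */
                dfPsi = -r * mmA * wA;
                if (leak) /* chain through psio */
                    dfPsi += -r * alpha * supply * Cf * KA / (den * den);
                break;
            case 2: /* KA */
                dfPsi = r * VA * Psi * wA / KAP2;
                if (leak)
                    dfPsi += r * alpha * supply * Cf / den;
                break;
            case 3: /* KAi */
                dfPsi = -r * VA * mmA * DA / ((KAi + DA) * (KAi + DA));
                break;
            case 4: /* Cf */
                if (leak) {
                    dfPsi = r * supply
                        + r * alpha * supply * KA * VA / (den * den);
                } else {
                    dfPsi = r * ocr;
                }
                break;
            case 5: /* KE */
                if (leak) {
                    dfO = -r * O;
                } else {
                    dfO   = -r * O * wE;
                    dfPsi =  r * Cf * O * wE;
                }
                break;
            case 6: /* KEi */
                if (!leak) {
                    const double dwE = DE / ((KEi + DE) * (KEi + DE));
                    dfO   = -r * KE * O * dwE;
                    dfPsi =  r * Cf * KE * O * dwE;
                }
                break;
            case 7: /* r */
                dfO   = fO / r;
                dfPsi = fPsi / r;
                break;
            case 8: /* gamma: dD/dgamma = -t * D */
                dfO   = dfO_dD   * (-(*t) * D);
                dfPsi = dfPsi_dD * (-(*t) * D);
                break;
            case 9: /* alpha */
                if (leak)
                    dfPsi = -r * (Psi - psio);
                break;
            case 10: /* D0: dD/dD0 = exp(-gamma t) */
                dfO   = dfO_dD   * expg;
                dfPsi = dfPsi_dD * expg;
                break;
            default:
                break;
            }
            const double sO = y[2 + 2 * k], sPsi = y[3 + 2 * k];
            ydot[2 + 2 * k] = J00 * sO + dfO;
            ydot[3 + 2 * k] = J10 * sO + J11 * sPsi + dfPsi;
        }
    }
}
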