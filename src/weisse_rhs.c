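/* Right-hand side of the coarse-grained whole-cell growth ODE
 * (nutrient import -> energy -> transcription -> ribosome binding ->
 * translation, with growth dilution).
 *
 * State (length 14):
 *   y[0] s_i   internal nutrient
 *   y[1] a     energy
 *   y[2] r     free ribosomes
 *   y[3..6]  m_r, m_t, m_m, m_q   free mRNA per class
 *   y[7..10] c_r, c_t, c_m, c_q   ribosome-mRNA complexes per class
 *   y[11..13] p_t, p_m, p_q       transporter / enzyme / housekeeping protein
 *
 * Parameter vector (length 21, fixed order):
 *   0 s_ext, 1 v_t, 2 K_t, 3 v_m, 4 K_m, 5 n_s, 6 w_r, 7 w_e, 8 w_q,
 *   9 theta_x (non-ribosomal transcription threshold), 10 theta_r
 *   (ribosomal transcription threshold), 11 K_q, 12 h_q, 13 k_b, 14 k_u,
 *   15 d_m, 16 g_max, 17 K_p, 18 M, 19 n_r, 20 n_x  (length 21)
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

static void weisse_rhs(const double *y, const double *p, double *dy,
                       double *lambda_out)
{
    const double s_i = y[0], a = y[1], r = y[2];
    const double *m = y + 3, *c = y + 7, *pr = y + 11;
    const double s_ext = p[0], v_t = p[1], K_t = p[2], v_m = p[3], K_m = p[4],
        n_s = p[5], w_r = p[6], w_e = p[7], w_q = p[8], theta_x = p[9],
        theta_r = p[10], K_q = p[11], h_q = p[12], k_b = p[13], k_u = p[14],
        d_m = p[15], g_max = p[16], K_p = p[17], M = p[18], n_r = p[19],
        n_x = p[20];

    const double gam = g_max * a / (K_p + a);
    const double csum = c[0] + c[1] + c[2] + c[3];
    const double lambda = gam * csum / M;
    const double nlen[4] = { n_r, n_x, n_x, n_x };
    const double imp = pr[0] * v_t * s_ext / (K_t + s_ext);
    const double cat = pr[1] * v_m * s_i / (K_m + s_i);
    const double act_r = a / (theta_r + a);
    const double act = a / (theta_x + a);
    const double inh = 1.0 / (1.0 + pow(pr[2] / K_q, h_q));
    const double om[4] = { w_r * act_r, w_e * act, w_e * act,
                           w_q * act * inh };

    double nu[4], bind[4], unbind[4], nusum = 0.0, bsum = 0.0, usum = 0.0;
    for (int k = 0; k < 4; k++) {
        nu[k] = c[k] * gam / nlen[k];
        bind[k] = k_b * r * m[k];
        unbind[k] = k_u * c[k];
        nusum += nu[k];
        bsum += bind[k];
        usum += unbind[k];
    }

    dy[0] = imp - cat - lambda * s_i;
    dy[1] = n_s * cat - gam * csum - lambda * a;
    dy[2] = nu[0] - lambda * r + nusum + usum - bsum;
    for (int k = 0; k < 4; k++) {
        dy[3 + k] = om[k] - (lambda + d_m) * m[k] + nu[k] - bind[k] + unbind[k];
        dy[7 + k] = -lambda * c[k] + bind[k] - unbind[k] - nu[k];
    }
    for (int k = 0; k < 3; k++)
        dy[11 + k] = nu[1 + k] - lambda * pr[k];

    if (lambda_out) *lambda_out = lambda;
}

/* .Call interface: dy = C_weisse_rhs(y, parms); attr "lambda" = growth rate */
SEXP C_weisse_rhs(SEXP y, SEXP parms)
{
    if (LENGTH(y) != 14) error("state vector must have length 14");
    if (LENGTH(parms) < 21) error("parameter vector must have length 21");
    SEXP dy = PROTECT(allocVector(REALSXP, 14));
    double lambda;
    weisse_rhs(REAL(y), REAL(parms), REAL(dy), &lambda);
    SEXP lam = PROTECT(ScalarReal(lambda));
    setAttrib(dy, install("lambda"), lam);
    UNPROTECT(2);
    return dy;
}

/* Jacobian of the per-capita residual g(u) = f(exp(u))/exp(u) by forward
 * differences in log-state u, plus g itself; used by the Newton solver. */
SEXP C_weisse_newton_step(SEXP u, SEXP parms, SEXP h_)
{
    if (LENGTH(u) != 14) error("log-state vector must have length 14");
    const double h = asReal(h_);
    const double *pu = REAL(u), *pp = REAL(parms);
    double y[14], dy[14], g0[14];
    for (int i = 0; i < 14; i++) y[i] = exp(pu[i]);
    weisse_rhs(y, pp, dy, NULL);
    for (int i = 0; i < 14; i++) g0[i] = dy[i] / y[i];

    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SEXP g = PROTECT(allocVector(REALSXP, 14));
    SEXP J = PROTECT(allocMatrix(REALSXP, 14, 14));
    memcpy(REAL(g), g0, sizeof g0);
    double *pj = REAL(J);
    for (int j = 0; j < 14; j++) {
        double yj[14];
        memcpy(yj, y, sizeof y);
        yj[j] = exp(pu[j] + h);
        weisse_rhs(yj, pp, dy, NULL);
        for (int i = 0; i < 14; i++)
            pj[i + 14 * j] = (dy[i] / yj[i] - g0[i]) / h;
        /* note: g_i depends on y_i in the denominator too; dy[i]/yj[i]
           only differs from dy[i]/y[i] when i == j, handled above since
           yj[i] == y[i] for i != j. */
    }
    SET_VECTOR_ELT(out, 0, g);
    SET_VECTOR_ELT(out, 1, J);
    UNPROTECT(3);
    return out;
}
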