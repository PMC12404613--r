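#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_weisse_rhs(SEXP y, SEXP parms);
SEXP C_weisse_newton_step(SEXP u, SEXP parms, SEXP h_);

static const R_CallMethodDef CallEntries[] = {
    {"C_weisse_rhs", (DL_FUNC) &C_weisse_rhs, 2},
    {"C_weisse_newton_step", (DL_FUNC) &C_weisse_newton_step, 3},
    {NULL, NULL, 0}
};

void R_init_epineutral(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
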