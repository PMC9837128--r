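#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP mornet_ssa_core(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern void mor_rre_init(void (*odeparms)(int *, double *));
extern void mor_rre_derivs(int *, double *, double *, double *, double *,
                           int *);

static const R_CallMethodDef CallEntries[] = {
    {"mornet_ssa_core", (DL_FUNC) &mornet_ssa_core, 6},
    {NULL, NULL, 0}
};

/* registered so deSolve can resolve the compiled model by name */
static const R_CMethodDef CEntries[] = {
    {"mor_rre_init",   (DL_FUNC) &mor_rre_init,   1},
    {"mor_rre_derivs", (DL_FUNC) &mor_rre_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_mornet(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
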