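#include <R.h>
#include <R_ext/Rdynload.h>

void mmp_init(void (*odeparms)(int *, double *));
void mmp_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"mmp_derivs", (DL_FUNC) &mmp_derivs, 6},
    {"mmp_init",   (DL_FUNC) &mmp_init,   1},
    {NULL, NULL, 0}
};

void R_init_mmpdyn(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    /* deSolve resolves "mmp_derivs"/"mmp_init" by name */
    R_useDynamicSymbols(dll, TRUE);
}
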