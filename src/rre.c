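/* Compiled right-hand side of the reaction-rate equation for deSolve.
 * Species order: L R RL RL_w aGDPbg aGDP aGTP bg M Ca_on Ca_off.
 * Parameters: k1..k11. Must agree with the R-level rre_rhs(). */
#include <R.h>

static double k[11];

void mor_rre_init(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, k);
}

void mor_rre_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double f1  = k[0]  * y[0] * y[1];
    double f2  = k[1]  * y[2] * y[4];
    double f3  = k[2]  * y[6];
    double f4  = k[3]  * y[2] * y[8];
    double f5  = k[4]  * y[7] * y[9];
    double f6  = k[5]  * y[5] * y[10];
    double f7  = k[6]  * y[3];
    double f8  = k[7]  * y[3];
    double f9  = k[8]  * y[8];
    double f10 = k[9]  * y[0];
    double f11 = k[10] * y[1] * y[4];

    ydot[0]  = -f1 - f10;             /* L      */
    ydot[1]  = -f1 + f7;              /* R      */
    ydot[2]  =  f1 - f4;              /* RL     */
    ydot[3]  =  f4 - f7 - f8;         /* RL_w   */
    ydot[4]  = -f2 + f6 - f11;        /* aGDPbg */
    ydot[5]  =  f3 - f6;              /* aGDP   */
    ydot[6]  =  f2 - f3 + f11;        /* aGTP   */
    ydot[7]  =  f2 - f5 + f11;        /* bg     */
    ydot[8]  =  f3 - f4 - f9;         /* M      */
    ydot[9]  = -f5 + f6;              /* Ca_on  */
    ydot[10] =  f5 - f6;              /* Ca_off */
}
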