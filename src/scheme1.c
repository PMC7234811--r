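/* Five-species binding scheme for deSolve's compiled-model interface.
 *
 * States (molar): y[0]=P*, y[1]=I, y[2]=I*, y[3]=P*I* (encounter),
 * y[4]=(PI)* (rearranged).  Parameters: k1, k_minus1 (I <-> I*),
 * kb, k_minusb (P* + I* <-> P*I*), kr, k_minusr (P*I* <-> (PI)*).
 */
#include <R.h>

static double parms[6];
#define K1   parms[0]
#define KM1  parms[1]
#define KB   parms[2]
#define KMB  parms[3]
#define KR   parms[4]
#define KMR  parms[5]

void scheme1_init(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void scheme1_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double bind = KB * y[0] * y[2] - KMB * y[3]; /* net P* + I* -> enc */
    double conf = K1 * y[1] - KM1 * y[2];        /* net I -> I*        */
    double rear = KR * y[3] - KMR * y[4];        /* net enc -> (PI)*   */

    ydot[0] = -bind;
    ydot[1] = -conf;
    ydot[2] = conf - bind;
    ydot[3] = bind - rear;
    ydot[4] = rear;
}
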