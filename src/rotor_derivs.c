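/* Right-hand side of the rotor-chain equations of motion, in C for use with
 * deSolve's compiled-function interface.
 *
 * State layout: y = (phi_0..phi_{N-1}, rho_0..rho_{N-1}).
 * Each bead moves in the plane z = h on a compliant circular orbit centred at
 * (i*ell, 0, h); beads are coupled hydrodynamically through the Green's
 * function of Stokes flow above a plane no-slip wall (Stokeslet plus Blake's
 * image system), evaluated between instantaneous bead positions.
 */

#include <R.h>
#include <math.h>

#define MAXN 64
#define NPAR (8 + MAXN)

/* p: [0]=N, [1]=a, [2]=R_orbit, [3]=ell, [4]=h, [5]=mu, [6]=lambda,
 *    [7]=truncation flag (1 = nearest neighbour only), [8..8+N-1]=F_i */
static double p[NPAR];

void rotor_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

/* Velocity-per-unit-force tensor G[i][j] at target xt for a point force at
 * source xs, both strictly above the wall z = 0.  Stokeslet minus image
 * Stokeslet plus Blake's doublet corrections; the wall-normal image term
 * carries the opposite sign to the wall-parallel ones. */
static void blake_G(const double *xs, const double *xt, double mu,
                    double G[3][3])
{
    const double hs = xs[2];
    double r[3], R[3];
    int i, j;

    for (i = 0; i < 3; i++) r[i] = xt[i] - xs[i];
    R[0] = r[0]; R[1] = r[1]; R[2] = xt[2] + xs[2];

    const double rn = sqrt(r[0]*r[0] + r[1]*r[1] + r[2]*r[2]);
    const double Rn = sqrt(R[0]*R[0] + R[1]*R[1] + R[2]*R[2]);
    const double rn3 = rn*rn*rn, Rn3 = Rn*Rn*Rn, Rn5 = Rn3*Rn*Rn;

    for (i = 0; i < 3; i++) {
        for (j = 0; j < 3; j++) {
            const double dij = (i == j) ? 1.0 : 0.0;
            /* free-space Stokeslet and image Stokeslet */
            double g = dij/rn + r[i]*r[j]/rn3
                     - dij/Rn - R[i]*R[j]/Rn3;
            /* d/dR_j [ hs R_i/R^3 - delta_i3/R - R_i R_3/R^3 ] */
            double D = hs*(dij/Rn3 - 3.0*R[i]*R[j]/Rn5)
                     + ((i == 2) ? R[j]/Rn3 : 0.0)
                     - (dij*R[2] + ((j == 2) ? R[i] : 0.0))/Rn3
                     + 3.0*R[i]*R[2]*R[j]/Rn5;
            const double M = (j == 2) ? -1.0 : 1.0;
            G[i][j] = (g + 2.0*hs*M*D) / (8.0*M_PI*mu);
        }
    }
}

void rotor_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const int N = (int) p[0];
    const double a = p[1], Rorb = p[2], ell = p[3], h = p[4];
    const double mu = p[5], lam = p[6];
    const int nn_only = (int) p[7];
    const double zeta0 = 6.0*M_PI*mu*a;
    const double zetaw = 1.0 + (9.0/16.0)*(a/h);
    const double self_mob = 1.0/(zeta0*zetaw);

    double pos[MAXN][3], F[MAXN][3], v[MAXN][3];
    double G[3][3];
    int i, j, k;

    for (i = 0; i < N; i++) {
        const double phi = y[i], rho = y[N + i];
        const double c = cos(phi), s = sin(phi);
        pos[i][0] = i*ell + rho*c;
        pos[i][1] = rho*s;
        pos[i][2] = h;
        const double Fd = p[8 + i];           /* tangential drive */
        const double Fr = -lam*(rho - Rorb);  /* radial spring */
        F[i][0] = -Fd*s + Fr*c;
        F[i][1] =  Fd*c + Fr*s;
        F[i][2] = 0.0;
        for (k = 0; k < 3; k++) v[i][k] = self_mob*F[i][k];
    }

    for (i = 0; i < N; i++) {
        for (j = 0; j < N; j++) {
            if (j == i) continue;
            if (nn_only && (j - i != 1 && i - j != 1)) continue;
            blake_G(pos[j], pos[i], mu, G);
            for (k = 0; k < 3; k++)
                v[i][k] += G[k][0]*F[j][0] + G[k][1]*F[j][1]
                         + G[k][2]*F[j][2];
        }
    }

    /* planar confinement: project onto the orbit plane */
    for (i = 0; i < N; i++) {
        const double phi = y[i], rho = y[N + i];
        const double c = cos(phi), s = sin(phi);
        const double vt = -v[i][0]*s + v[i][1]*c;
        const double vr =  v[i][0]*c + v[i][1]*s;
        ydot[i] = vt/rho;
        ydot[N + i] = vr;
    }
}
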