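// Gaussian integral engine: McMurchie-Davidson scheme over contracted
// Cartesian Gaussian shells.  All quantities in atomic units; centers are
// passed in bohr.  Angular momentum is supported up to l = 4 (g), which is
// more than any bundled basis uses.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const int LMAX = 4;

// ---------------------------------------------------------------------------
// Boys function F_n(x), n = 0..nmax
// ---------------------------------------------------------------------------
static void boys(double x, int nmax, double *F)
{
    if (x < 1e-13) {
        for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
        return;
    }
    if (x > 35.0) {
        // asymptotic F_0 plus upward recursion (stable for large x)
        F[0] = 0.5 * std::sqrt(M_PI / x);
        double ex = std::exp(-x);
        for (int n = 0; n < nmax; ++n)
            F[n + 1] = ((2.0 * n + 1.0) * F[n] - ex) / (2.0 * x);
        return;
    }
    // series for F_nmax, then downward recursion (stable for moderate x)
    double ex = std::exp(-x);
    double term = 1.0 / (2.0 * nmax + 1.0);
    double s = term;
    for (int k = 0; k < 400; ++k) {
        term *= 2.0 * x / (2.0 * nmax + 2.0 * k + 3.0);
        s += term;
        if (term < 1e-17 * s) break;
    }
    F[nmax] = ex * s;
    for (int n = nmax; n > 0; --n)
        F[n - 1] = (2.0 * x * F[n] + ex) / (2.0 * n - 1.0);
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} for a 1D Gaussian product
// E indexed as E[i][j][t]; i <= la, j <= lb, t <= i + j
// ---------------------------------------------------------------------------
struct ETab {
    double v[LMAX + 3][LMAX + 3][2 * LMAX + 5];
};

static void hermite_E(int la, int lb, double a, double b, double AB, ETab &E)
{
    double p = a + b;
    double mu = a * b / p;
    double XPA = -b * AB / p;   // P - A with AB = A - B => P-A = -(b/p)(A-B)
    double XPB =  a * AB / p;   // P - B =  (a/p)(A-B)
    std::memset(&E, 0, sizeof(ETab));
    E.v[0][0][0] = std::exp(-mu * AB * AB);
    for (int i = 0; i <= la; ++i) {
        for (int j = 0; j <= lb; ++j) {
            if (i == 0 && j == 0) continue;
            int n = i + j;
            for (int t = 0; t <= n; ++t) {
                double val = 0.0;
                if (i > 0) {
                    if (t > 0)         val += E.v[i - 1][j][t - 1] / (2.0 * p);
                    val += XPA * E.v[i - 1][j][t];
                    if (t + 1 <= n - 1) val += (t + 1.0) * E.v[i - 1][j][t + 1];
                } else {
                    if (t > 0)         val += E.v[i][j - 1][t - 1] / (2.0 * p);
                    val += XPB * E.v[i][j - 1][t];
                    if (t + 1 <= n - 1) val += (t + 1.0) * E.v[i][j - 1][t + 1];
                }
                E.v[i][j][t] = val;
            }
        }
    }
}

// ---------------------------------------------------------------------------
// Hermite Coulomb integrals R^0_{tuv}
// ---------------------------------------------------------------------------
// L is the maximum total Hermite degree t+u+v; strides on return are
// du = (L+1)^2 for t and dv = (L+1) for u, so R[t*du + u*dv + v].
static void hermite_R(int L, double p, double X, double Y, double Z,
                      std::vector<double> &R, int &du, int &dv)
{
    double T = p * (X * X + Y * Y + Z * Z);
    std::vector<double> Fn(L + 1);
    boys(T, L, Fn.data());
    int n1 = L + 1;
    du = n1 * n1;
    dv = n1;
    int block = n1 * n1 * n1;
    std::vector<double> work((size_t)(L + 1) * block, 0.0);
    double m2p = 1.0;
    for (int n = 0; n <= L; ++n) {
        work[(size_t)n * block] = m2p * Fn[n];
        m2p *= -2.0 * p;
    }
    for (int ord = 1; ord <= L; ++ord) {
        for (int t = 0; t <= ord; ++t)
        for (int u = 0; u + t <= ord; ++u) {
            int v = ord - t - u;
            int idx = t * du + u * dv + v;
            for (int n = 0; n + ord <= L; ++n) {
                double val = 0.0;
                const double *Wn1 = &work[(size_t)(n + 1) * block];
                if (t > 0) {
                    val = X * Wn1[idx - du];
                    if (t > 1) val += (t - 1.0) * Wn1[idx - 2 * du];
                } else if (u > 0) {
                    val = Y * Wn1[idx - dv];
                    if (u > 1) val += (u - 1.0) * Wn1[idx - 2 * dv];
                } else {
                    val = Z * Wn1[idx - 1];
                    if (v > 1) val += (v - 1.0) * Wn1[idx - 2];
                }
                work[(size_t)n * block + idx] = val;
            }
        }
    }
    R.assign(work.begin(), work.begin() + block);
}

// ---------------------------------------------------------------------------
// Cartesian component enumeration for a shell of angular momentum l
// ---------------------------------------------------------------------------
static void cart_components(int l, std::vector<int> &lx,
                            std::vector<int> &ly, std::vector<int> &lz)
{
    lx.clear(); ly.clear(); lz.clear();
    for (int i = l; i >= 0; --i)
        for (int j = l - i; j >= 0; --j) {
            lx.push_back(i);
            ly.push_back(j);
            lz.push_back(l - i - j);
        }
}

struct Shell {
    int l;
    int atom;        // 0-based
    double x, y, z;
    std::vector<double> exps;
    std::vector<double> coefs;  // includes primitive normalization
    int nfun;        // number of cartesian components
    int offset;      // first AO index (0-based)
    std::vector<int> lx, ly, lz;
};

static std::vector<Shell> unpack_shells(List shells)
{
    int ns = shells.size();
    std::vector<Shell> S(ns);
    int off = 0;
    for (int s = 0; s < ns; ++s) {
        List sh = shells[s];
        Shell &q = S[s];
        q.l = as<int>(sh["l"]);
        q.atom = as<int>(sh["atom"]) - 1;
        NumericVector ctr = sh["center"];
        q.x = ctr[0]; q.y = ctr[1]; q.z = ctr[2];
        NumericVector e = sh["exps"], c = sh["coefs"];
        q.exps.assign(e.begin(), e.end());
        q.coefs.assign(c.begin(), c.end());
        cart_components(q.l, q.lx, q.ly, q.lz);
        q.nfun = (int)q.lx.size();
        q.offset = off;
        off += q.nfun;
    }
    return S;
}

// ---------------------------------------------------------------------------
// One-electron integrals: overlap and kinetic
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_one_electron")]]
List cpp_one_electron(List shells, NumericMatrix atom_xyz, NumericVector charges)
{
    std::vector<Shell> S = unpack_shells(shells);
    int nao = 0;
    for (auto &s : S) nao += s.nfun;
    NumericMatrix Smat(nao, nao), Tmat(nao, nao), Vmat(nao, nao);
    int natom = atom_xyz.nrow();

    for (size_t A = 0; A < S.size(); ++A)
    for (size_t B = 0; B <= A; ++B) {
        Shell &sa = S[A], &sb = S[B];
        double ABx = sa.x - sb.x, ABy = sa.y - sb.y, ABz = sa.z - sb.z;
        int la = sa.l, lb = sb.l;
        std::vector<double> sblk(sa.nfun * sb.nfun, 0.0);
        std::vector<double> tblk(sa.nfun * sb.nfun, 0.0);
        std::vector<double> vblk(sa.nfun * sb.nfun, 0.0);
        for (size_t ia = 0; ia < sa.exps.size(); ++ia)
        for (size_t ib = 0; ib < sb.exps.size(); ++ib) {
            double a = sa.exps[ia], b = sb.exps[ib];
            double p = a + b;
            double cc = sa.coefs[ia] * sb.coefs[ib];
            double Px = (a * sa.x + b * sb.x) / p;
            double Py = (a * sa.y + b * sb.y) / p;
            double Pz = (a * sa.z + b * sb.z) / p;
            // E tables per dimension, with room for lb+2 (kinetic)
            ETab Ex, Ey, Ez;
            hermite_E(la, lb + 2, a, b, ABx, Ex);
            hermite_E(la, lb + 2, a, b, ABy, Ey);
            hermite_E(la, lb + 2, a, b, ABz, Ez);
            double pref = std::pow(M_PI / p, 1.5);
            // nuclear attraction needs full Hermite expansion
            for (int fa = 0; fa < sa.nfun; ++fa)
            for (int fb = 0; fb < sb.nfun; ++fb) {
                int i = sa.lx[fa], k = sa.ly[fa], m = sa.lz[fa];
                int j = sb.lx[fb], l = sb.ly[fb], n = sb.lz[fb];
                double sx = Ex.v[i][j][0], sy = Ey.v[k][l][0], sz = Ez.v[m][n][0];
                sblk[fa * sb.nfun + fb] += cc * pref * sx * sy * sz;
                // kinetic: T = -1/2 sum_dims d2/dx2 acting on ket
                // 1D kinetic: K_ij = -2 b^2 S_{i,j+2} + b(2j+1) S_{ij}
                //                    - j(j-1)/2 S_{i,j-2}
                double kx = -2.0 * b * b * Ex.v[i][j + 2][0]
                          + b * (2.0 * j + 1.0) * sx
                          - 0.5 * j * (j - 1.0) * (j >= 2 ? Ex.v[i][j - 2][0] : 0.0);
                double ky = -2.0 * b * b * Ey.v[k][l + 2][0]
                          + b * (2.0 * l + 1.0) * sy
                          - 0.5 * l * (l - 1.0) * (l >= 2 ? Ey.v[k][l - 2][0] : 0.0);
                double kz = -2.0 * b * b * Ez.v[m][n + 2][0]
                          + b * (2.0 * n + 1.0) * sz
                          - 0.5 * n * (n - 1.0) * (n >= 2 ? Ez.v[m][n - 2][0] : 0.0);
                tblk[fa * sb.nfun + fb] += cc * pref * (kx * sy * sz + sx * ky * sz + sx * sy * kz);
            }
            // nuclear attraction
            for (int at = 0; at < natom; ++at) {
                double Xpc = Px - atom_xyz(at, 0);
                double Ypc = Py - atom_xyz(at, 1);
                double Zpc = Pz - atom_xyz(at, 2);
                std::vector<double> R;
                int du, dv;
                hermite_R(la + lb, p, Xpc, Ypc, Zpc, R, du, dv);
                double Z = charges[at];
                for (int fa = 0; fa < sa.nfun; ++fa)
                for (int fb = 0; fb < sb.nfun; ++fb) {
                    int i = sa.lx[fa], k = sa.ly[fa], m = sa.lz[fa];
                    int j = sb.lx[fb], l = sb.ly[fb], n = sb.lz[fb];
                    double v = 0.0;
                    for (int t = 0; t <= i + j; ++t)
                    for (int u = 0; u <= k + l; ++u)
                    for (int w = 0; w <= m + n; ++w)
                        v += Ex.v[i][j][t] * Ey.v[k][l][u] * Ez.v[m][n][w] *
                             R[t * du + u * dv + w];
                    vblk[fa * sb.nfun + fb] += -Z * cc * (2.0 * M_PI / p) * v;
                }
            }
        }
        for (int fa = 0; fa < sa.nfun; ++fa)
        for (int fb = 0; fb < sb.nfun; ++fb) {
            int ii = sa.offset + fa, jj = sb.offset + fb;
            Smat(ii, jj) = Smat(jj, ii) = sblk[fa * sb.nfun + fb];
            Tmat(ii, jj) = Tmat(jj, ii) = tblk[fa * sb.nfun + fb];
            Vmat(ii, jj) = Vmat(jj, ii) = vblk[fa * sb.nfun + fb];
        }
    }
    return List::create(_["S"] = Smat, _["T"] = Tmat, _["V"] = Vmat);
}

// ---------------------------------------------------------------------------
// ERI over a shell quartet (chemist notation (ab|cd)), cartesian components
// ---------------------------------------------------------------------------
static void eri_quartet(const Shell &sa, const Shell &sb,
                        const Shell &sc, const Shell &sd,
                        std::vector<double> &out)
{
    int na = sa.nfun, nb = sb.nfun, nc = sc.nfun, nd = sd.nfun;
    out.assign((size_t)na * nb * nc * nd, 0.0);
    double ABx = sa.x - sb.x, ABy = sa.y - sb.y, ABz = sa.z - sb.z;
    double CDx = sc.x - sd.x, CDy = sc.y - sd.y, CDz = sc.z - sd.z;
    int lab = sa.l + sb.l, lcd = sc.l + sd.l;

    for (size_t ia = 0; ia < sa.exps.size(); ++ia)
    for (size_t ib = 0; ib < sb.exps.size(); ++ib) {
        double a = sa.exps[ia], b = sb.exps[ib], p = a + b;
        double cab = sa.coefs[ia] * sb.coefs[ib];
        double Px = (a * sa.x + b * sb.x) / p;
        double Py = (a * sa.y + b * sb.y) / p;
        double Pz = (a * sa.z + b * sb.z) / p;
        ETab Exab, Eyab, Ezab;
        hermite_E(sa.l, sb.l, a, b, ABx, Exab);
        hermite_E(sa.l, sb.l, a, b, ABy, Eyab);
        hermite_E(sa.l, sb.l, a, b, ABz, Ezab);
        for (size_t ic = 0; ic < sc.exps.size(); ++ic)
        for (size_t id = 0; id < sd.exps.size(); ++id) {
            double c = sc.exps[ic], d = sd.exps[id], q = c + d;
            double ccd = sc.coefs[ic] * sd.coefs[id];
            double Qx = (c * sc.x + d * sd.x) / q;
            double Qy = (c * sc.y + d * sd.y) / q;
            double Qz = (c * sc.z + d * sd.z) / q;
            ETab Excd, Eycd, Ezcd;
            hermite_E(sc.l, sd.l, c, d, CDx, Excd);
            hermite_E(sc.l, sd.l, c, d, CDy, Eycd);
            hermite_E(sc.l, sd.l, c, d, CDz, Ezcd);
            double alpha = p * q / (p + q);
            std::vector<double> R;
            int du, dv;
            hermite_R(lab + lcd, alpha, Px - Qx, Py - Qy, Pz - Qz, R, du, dv);
            double pref = 2.0 * std::pow(M_PI, 2.5) /
                          (p * q * std::sqrt(p + q)) * cab * ccd;
            for (int fa = 0; fa < na; ++fa)
            for (int fb = 0; fb < nb; ++fb) {
                int i1 = sa.lx[fa], k1 = sa.ly[fa], m1 = sa.lz[fa];
                int j1 = sb.lx[fb], l1 = sb.ly[fb], n1 = sb.lz[fb];
                // precollect bra Hermite coefficients
                for (int fc = 0; fc < nc; ++fc)
                for (int fd = 0; fd < nd; ++fd) {
                    int i2 = sc.lx[fc], k2 = sc.ly[fc], m2 = sc.lz[fc];
                    int j2 = sd.lx[fd], l2 = sd.ly[fd], n2 = sd.lz[fd];
                    double v = 0.0;
                    for (int t1 = 0; t1 <= i1 + j1; ++t1)
                    for (int u1 = 0; u1 <= k1 + l1; ++u1)
                    for (int w1 = 0; w1 <= m1 + n1; ++w1) {
                        double eb = Exab.v[i1][j1][t1] * Eyab.v[k1][l1][u1] *
                                    Ezab.v[m1][n1][w1];
                        if (eb == 0.0) continue;
                        double acc = 0.0;
                        for (int t2 = 0; t2 <= i2 + j2; ++t2)
                        for (int u2 = 0; u2 <= k2 + l2; ++u2)
                        for (int w2 = 0; w2 <= m2 + n2; ++w2) {
                            double ek = Excd.v[i2][j2][t2] * Eycd.v[k2][l2][u2] *
                                        Ezcd.v[m2][n2][w2];
                            if (ek == 0.0) continue;
                            double sign = ((t2 + u2 + w2) % 2) ? -1.0 : 1.0;
                            acc += sign * ek *
                                   R[(t1 + t2) * du + (u1 + u2) * dv + (w1 + w2)];
                        }
                        v += eb * acc;
                    }
                    out[(((size_t)fa * nb + fb) * nc + fc) * nd + fd] += pref * v;
                }
            }
        }
    }
}

// [[Rcpp::export(name = ".cpp_eri_full")]]
NumericVector cpp_eri_full(List shells, double schwarz_tol)
{
    std::vector<Shell> S = unpack_shells(shells);
    int ns = (int)S.size();
    int nao = 0;
    for (auto &s : S) nao += s.nfun;
    NumericVector G((R_xlen_t)nao * nao * nao * nao);
    double *g = G.begin();
    size_t N = nao;

    // Schwarz bounds per shell pair
    std::vector<double> Qsp((size_t)ns * ns, 0.0);
    std::vector<double> blk;
    for (int A = 0; A < ns; ++A)
    for (int B = 0; B <= A; ++B) {
        eri_quartet(S[A], S[B], S[A], S[B], blk);
        double mx = 0.0;
        int na = S[A].nfun, nb = S[B].nfun;
        for (int fa = 0; fa < na; ++fa)
        for (int fb = 0; fb < nb; ++fb) {
            double d = blk[(((size_t)fa * nb + fb) * na + fa) * nb + fb];
            if (d > mx) mx = d;
        }
        Qsp[A * ns + B] = Qsp[B * ns + A] = std::sqrt(std::max(mx, 0.0));
    }

    for (int A = 0; A < ns; ++A)
    for (int B = 0; B <= A; ++B) {
        double qab = Qsp[A * ns + B];
        for (int C = 0; C <= A; ++C) {
            int Dmax = (C == A) ? B : C;
            for (int D = 0; D <= Dmax; ++D) {
                if (qab * Qsp[C * ns + D] < schwarz_tol) continue;
                eri_quartet(S[A], S[B], S[C], S[D], blk);
                int na = S[A].nfun, nb = S[B].nfun,
                    nc = S[C].nfun, nd = S[D].nfun;
                int oa = S[A].offset, ob = S[B].offset,
                    oc = S[C].offset, od = S[D].offset;
                for (int fa = 0; fa < na; ++fa)
                for (int fb = 0; fb < nb; ++fb)
                for (int fc = 0; fc < nc; ++fc)
                for (int fd = 0; fd < nd; ++fd) {
                    double v = blk[(((size_t)fa * nb + fb) * nc + fc) * nd + fd];
                    size_t i = oa + fa, j = ob + fb, k = oc + fc, l = od + fd;
                    // fill all 8 permutations (chemist symmetry)
                    g[i + N * (j + N * (k + N * l))] = v;
                    g[j + N * (i + N * (k + N * l))] = v;
                    g[i + N * (j + N * (l + N * k))] = v;
                    g[j + N * (i + N * (l + N * k))] = v;
                    g[k + N * (l + N * (i + N * j))] = v;
                    g[l + N * (k + N * (i + N * j))] = v;
                    g[k + N * (l + N * (j + N * i))] = v;
                    g[l + N * (k + N * (j + N * i))] = v;
                }
            }
        }
    }
    G.attr("dim") = IntegerVector::create(nao, nao, nao, nao);
    return G;
}

// Diagonal (ab|ab) of the ERI matrix, computed independently of the full
// tensor routine's symmetry bookkeeping (used as a provider cross-check and
// by the Cholesky prescreen).
// [[Rcpp::export(name = ".cpp_eri_diagonal")]]
NumericMatrix cpp_eri_diagonal(List shells)
{
    std::vector<Shell> S = unpack_shells(shells);
    int ns = (int)S.size();
    int nao = 0;
    for (auto &s : S) nao += s.nfun;
    NumericMatrix Dg(nao, nao);
    std::vector<double> blk;
    for (int A = 0; A < ns; ++A)
    for (int B = 0; B < ns; ++B) {
        eri_quartet(S[A], S[B], S[A], S[B], blk);
        int na = S[A].nfun, nb = S[B].nfun;
        for (int fa = 0; fa < na; ++fa)
        for (int fb = 0; fb < nb; ++fb)
            Dg(S[A].offset + fa, S[B].offset + fb) =
                blk[(((size_t)fa * nb + fb) * na + fa) * nb + fb];
    }
    return Dg;
}
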