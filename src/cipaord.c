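/* Paced endocardial human ventricular myocyte model: ORd-family equations with
 * CiPA v1.0 conductance rescalings and a 9-state Markov IKr with dynamic drug
 * binding/trapping.  Compiled-model interface for deSolve (lsoda):
 *   initfunc "cipaord_initmod", derivs "cipaord_derivs", nout = 7 currents.
 *
 * State layout (48):
 *   0  v      mV
 *   1  nai    2 nass   3 ki   4 kss   5 cai   6 cass   7 cansr   8 cajsr  (mM)
 *   9  m     10 hf    11 hs  12 j    13 hsp  14 jp
 *  15 mL    16 hL    17 hLp
 *  18 a     19 iF    20 iS  21 ap   22 iFp  23 iSp
 *  24 d     25 ff    26 fs  27 fcaf 28 fcas 29 jca 30 nca 31 ffp 32 fcafp
 *  33 xs1   34 xs2   35 xk1
 *  36 Jrelnp 37 Jrelp 38 CaMKt
 *  39 IC1  40 IC2  41 C1  42 C2  43 O  44 IO  45 IObound 46 Obound 47 Cbound
 *
 * Parameters (15):
 *   0 conc(nM) 1 kmax 2 ku 3 npow 4 halfmax 5 vhalf
 *   6 bNaL 7 bNa 8 bCaL 9 bKs 10 bK1 11 bto   (blocked fractions, 0..1)
 *  12 stim_amp (uA/uF) 13 stim_dur (ms) 14 cl (ms)
 */
#include <R.h>
#include <math.h>

static double parms[15];

void cipaord_initmod(void (*odeparms)(int *, double *))
{
    int N = 15;
    odeparms(&N, parms);
}

/* safe exponential-drift flux terms x*exp(a)-y over exp(a)-1 */
static double expm1s(double a)
{
    double e = expm1(a);
    if (fabs(e) < 1e-12) e = (e >= 0) ? 1e-12 : -1e-12;
    return e;
}

void cipaord_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    /* physical constants and geometry */
    const double nao = 140.0, cao = 1.8, ko = 5.4;
    const double Rgas = 8314.0, T = 310.0, Frdy = 96485.0;
    const double L = 0.01, rad = 0.0011;
    const double pi = 3.14159265358979312;
    const double vcell = 1000.0 * pi * rad * rad * L;
    const double Ageo = 2.0 * pi * rad * rad + 2.0 * pi * rad * L;
    const double Acap = 2.0 * Ageo;
    const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
    const double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

    const double conc = parms[0], kmax = parms[1], ku = parms[2];
    const double npow = parms[3], halfmax = parms[4], vhalf = parms[5];
    const double mNaL = 1.0 - parms[6], mNa = 1.0 - parms[7];
    const double mCaL = 1.0 - parms[8], mKs = 1.0 - parms[9];
    const double mK1 = 1.0 - parms[10], mto = 1.0 - parms[11];
    const double stim_amp = parms[12], stim_dur = parms[13], cl = parms[14];

    double v = y[0];
    double nai = y[1], nass = y[2], ki = y[3], kss = y[4];
    double cai = y[5], cass = y[6], cansr = y[7], cajsr = y[8];
    double m = y[9], hf = y[10], hs = y[11], j = y[12], hsp = y[13], jp = y[14];
    double mL = y[15], hL = y[16], hLp = y[17];
    double a = y[18], iF = y[19], iS = y[20], ap = y[21], iFp = y[22], iSp = y[23];
    double d = y[24], ff = y[25], fs = y[26], fcaf = y[27], fcas = y[28];
    double jca = y[29], nca = y[30], ffp = y[31], fcafp = y[32];
    double xs1 = y[33], xs2 = y[34], xk1 = y[35];
    double Jrelnp = y[36], Jrelp = y[37], CaMKt = y[38];
    double IC1 = y[39], IC2 = y[40], C1 = y[41], C2 = y[42];
    double O = y[43], IO = y[44], IObound = y[45], Obound = y[46], Cbound = y[47];

    /* CaMK */
    const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
    const double CaMKo = 0.05, KmCaM = 0.0015;
    double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
    double CaMKa = CaMKb + CaMKt;
    double fCaMK = 1.0 / (1.0 + KmCaMK / CaMKa);

    /* reversal potentials */
    double ENa = (Rgas * T / Frdy) * log(nao / nai);
    double EK = (Rgas * T / Frdy) * log(ko / ki);
    const double PKNa = 0.01833;
    double EKs = (Rgas * T / Frdy) * log((ko + PKNa * nao) / (ki + PKNa * nai));
    double vffrt = v * Frdy * Frdy / (Rgas * T);
    double vfrt = v * Frdy / (Rgas * T);

    /* INa (fast) */
    double mss = 1.0 / (1.0 + exp(-(v + 39.57) / 9.871));
    double tm = 1.0 / (6.765 * exp((v + 11.64) / 34.77) +
                       8.552 * exp(-(v + 77.42) / 5.955));
    double hss = 1.0 / (1.0 + exp((v + 82.90) / 6.086));
    double thf = 1.0 / (1.432e-5 * exp(-(v + 1.196) / 6.285) +
                        6.149 * exp((v + 0.5096) / 20.27));
    double ths = 1.0 / (0.009794 * exp(-(v + 17.95) / 28.05) +
                        0.3343 * exp((v + 5.730) / 56.66));
    const double Ahf = 0.99, Ahs = 0.01;
    double h = Ahf * hf + Ahs * hs;
    double jss = hss;
    double tj = 2.038 + 1.0 / (0.02136 * exp(-(v + 100.6) / 8.281) +
                               0.3052 * exp((v + 0.9941) / 38.45));
    double hssp = 1.0 / (1.0 + exp((v + 89.1) / 6.086));
    double thsp = 3.0 * ths;
    double hp = Ahf * hf + Ahs * hsp;
    double tjp = 1.46 * tj;
    double GNa = 75.0 * mNa;
    double INa = GNa * (v - ENa) * m * m * m *
        ((1.0 - fCaMK) * h * j + fCaMK * hp * jp);

    /* INaL */
    double mLss = 1.0 / (1.0 + exp(-(v + 42.85) / 5.264));
    double tmL = tm;
    double hLss = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
    const double thL = 200.0;
    double hLssp = 1.0 / (1.0 + exp((v + 93.81) / 7.488));
    double thLp = 3.0 * thL;
    double GNaL = 0.0075 * 2.661 * mNaL;          /* endo, CiPA rescale */
    double INaL = GNaL * (v - ENa) * mL * ((1.0 - fCaMK) * hL + fCaMK * hLp);

    /* Ito (endo) */
    double ass = 1.0 / (1.0 + exp(-(v - 14.34) / 14.82));
    double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(v - 18.4099) / 29.3814))) +
                          3.5 / (1.0 + exp((v + 100.0) / 29.3814)));
    double iss = 1.0 / (1.0 + exp((v + 43.94) / 5.711));
    double tiF = 4.562 + 1.0 / (0.3933 * exp(-(v + 100.0) / 100.0) +
                                0.08004 * exp((v + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                                1.780e-8 * exp((v + 114.1) / 8.079));
    double AiF = 1.0 / (1.0 + exp((v - 213.6) / 151.2));
    double AiS = 1.0 - AiF;
    double i_to = AiF * iF + AiS * iS;
    double assp = 1.0 / (1.0 + exp(-(v - 24.34) / 14.82));
    double dti_develop = 1.354 + 1.0e-4 / (exp((v - 167.4) / 15.89) +
                                           exp(-(v - 12.23) / 0.2154));
    double dti_recover = 1.0 - 0.5 / (1.0 + exp((v + 70.0) / 20.0));
    double tiFp = dti_develop * dti_recover * tiF;
    double tiSp = dti_develop * dti_recover * tiS;
    double i_to_p = AiF * iFp + AiS * iSp;
    double Gto = 0.02 * mto;
    double Ito = Gto * (v - EK) *
        ((1.0 - fCaMK) * a * i_to + fCaMK * ap * i_to_p);

    /* ICaL / ICaNa / ICaK */
    double dss = 1.0 / (1.0 + exp(-(v + 3.940) / 4.230));
    double td = 0.6 + 1.0 / (exp(-0.05 * (v + 6.0)) + exp(0.09 * (v + 14.0)));
    double fss = 1.0 / (1.0 + exp((v + 19.58) / 3.696));
    double tff = 7.0 + 1.0 / (0.0045 * exp(-(v + 20.0) / 10.0) +
                              0.0045 * exp((v + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (0.000035 * exp(-(v + 5.0) / 4.0) +
                                 0.000035 * exp((v + 5.0) / 6.0));
    const double Aff = 0.6;
    double Afs = 1.0 - Aff;
    double f = Aff * ff + Afs * fs;
    double fcass = fss;
    double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(v - 4.0) / 7.0) +
                                0.04 * exp((v - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (0.00012 * exp(-v / 3.0) +
                                  0.00012 * exp(v / 7.0));
    double Afcaf = 0.3 + 0.6 / (1.0 + exp((v - 10.0) / 10.0));
    double Afcas = 1.0 - Afcaf;
    double fca = Afcaf * fcaf + Afcas * fcas;
    const double tjca = 75.0;
    double tffp = 2.5 * tff;
    double fp = Aff * ffp + Afs * fs;
    double tfcafp = 2.5 * tfcaf;
    double fcap = Afcaf * fcafp + Afcas * fcas;
    const double Kmn = 0.002, k2n = 1000.0;
    double km2n = jca * 1.0;
    double tmp4 = 1.0 + Kmn / cass;
    double anca = 1.0 / (k2n / km2n + tmp4 * tmp4 * tmp4 * tmp4);
    double PhiCaL = 4.0 * vffrt * (cass * exp(2.0 * vfrt) - 0.341 * cao) /
        expm1s(2.0 * vfrt);
    double PhiCaNa = 1.0 * vffrt * (0.75 * nass * exp(vfrt) - 0.75 * nao) /
        expm1s(vfrt);
    double PhiCaK = 1.0 * vffrt * (0.75 * kss * exp(vfrt) - 0.75 * ko) /
        expm1s(vfrt);
    double PCa = 0.0001 * 1.007 * mCaL;           /* endo, CiPA rescale */
    double PCap = 1.1 * PCa;
    double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
    double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
    double gate_np = d * (f * (1.0 - nca) + jca * fca * nca);
    double gate_p = d * (fp * (1.0 - nca) + jca * fcap * nca);
    double ICaL = (1.0 - fCaMK) * PCa * PhiCaL * gate_np +
        fCaMK * PCap * PhiCaL * gate_p;
    double ICaNa = (1.0 - fCaMK) * PCaNa * PhiCaNa * gate_np +
        fCaMK * PCaNap * PhiCaNa * gate_p;
    double ICaK = (1.0 - fCaMK) * PCaK * PhiCaK * gate_np +
        fCaMK * PCaKp * PhiCaK * gate_p;

    /* IKr: Markov scheme with dynamic drug binding/trapping.
     * Horizontal rows C1-C2-O (conducting pathway) and IC1-IC2-IO
     * (inactivated); vertical inactivation edges; bound states off O/IO with
     * a voltage-gated trapped state. Rates A*exp(B*v) with Q10-style
     * temperature factors q^((T-20)/10), T = 37. */
    {
        const double Tq = (37.0 - 20.0) / 10.0;
        double a1 = 0.0264 * exp(4.631e-05 * v) * exp(Tq * log(4.843));
        double b1 = 4.986e-06 * exp(-0.004226 * v) * exp(Tq * log(4.23));
        double a2 = 0.001214 * exp(0.008516 * v) * exp(Tq * log(4.962));
        double b2 = 1.854e-05 * exp(-0.04641 * v) * exp(Tq * log(3.769));
        double a11 = 0.0007868 * exp(1.535e-08 * v) * exp(Tq * log(4.942));
        double b11 = 5.455e-06 * exp(-0.1688 * v) * exp(Tq * log(4.156));
        double a31 = 0.005509 * exp(7.771e-09 * v) * exp(Tq * log(4.22));
        double b31 = 0.001416 * exp(-0.02877 * v) * exp(Tq * log(1.459));
        double a51 = 0.4492 * exp(0.008595 * v) * exp(Tq * log(5.0));
        double b51 = 0.01241 * exp(0.1725 * v) * exp(Tq * log(5.568));
        double a52 = 0.3181 * exp(3.613e-08 * v) * exp(Tq * log(4.663));
        double b52 = 0.3226 * exp(-0.0006575 * v) * exp(Tq * log(5.0));
        double a53 = 0.149 * exp(0.004668 * v) * exp(Tq * log(2.412));
        double b53 = 0.008978 * exp(-0.02215 * v) * exp(Tq * log(5.682));
        /* edges: C1->C2 a1 / C2->C1 b1 ; IC1->IC2 a11 / IC2->IC1 b11 ;
         * C2->O a31 / O->C2 b31 ; IC2->IO a2 / IO->IC2 b2 ;
         * C1->IC1 a51 / IC1->C1 b51 ; C2->IC2 a52 / IC2->C2 b52 ;
         * O->IO a53 / IO->O b53 */
        const double Kt = 3.5e-5;
        double kon = 0.0, kub = 0.0;
        if (conc > 0.0 && kmax > 0.0) {
            double dn = exp(npow * log(conc));
            kon = kmax * ku * dn / (dn + halfmax);
        }
        kub = ku * a53 / b53;   /* microscopic-reversibility-corrected unbind */
        double ktrap = Kt / (1.0 + exp(-(v - vhalf) / 6.789));

        ydot[39] = -a11 * IC1 + b11 * IC2 + a51 * C1 - b51 * IC1;       /* IC1 */
        ydot[40] = a11 * IC1 - b11 * IC2 - a2 * IC2 + b2 * IO
            + a52 * C2 - b52 * IC2;                                     /* IC2 */
        ydot[41] = -a1 * C1 + b1 * C2 - a51 * C1 + b51 * IC1;           /* C1 */
        ydot[42] = a1 * C1 - b1 * C2 - a31 * C2 + b31 * O
            - a52 * C2 + b52 * IC2;                                     /* C2 */
        ydot[43] = a31 * C2 - b31 * O - a53 * O + b53 * IO
            - kon * O + ku * Obound;                                    /* O */
        ydot[44] = a2 * IC2 - b2 * IO + a53 * O - b53 * IO
            - kon * IO + kub * IObound;                                 /* IO */
        ydot[45] = kon * IO - kub * IObound
            + Kt * Cbound - ktrap * IObound;                            /* IOb */
        ydot[46] = kon * O - ku * Obound
            + Kt * Cbound - ktrap * Obound;                             /* Ob */
        ydot[47] = ktrap * (Obound + IObound) - 2.0 * Kt * Cbound;      /* Cb */
    }
    const double GKr = 4.65854545454545618e-02;   /* includes CiPA rescale */
    double IKr = GKr * sqrt(ko / 5.4) * O * (v - EK);

    /* IKs */
    double xs1ss = 1.0 / (1.0 + exp(-(v + 11.60) / 8.932));
    double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                                 0.001292 * exp(-(v + 210.0) / 230.0));
    double xs2ss = xs1ss;
    double txs2 = 1.0 / (0.01 * exp((v - 50.0) / 20.0) +
                         0.0193 * exp(-(v + 66.54) / 31.0));
    double KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / cai, 1.4));
    double GKs = 0.0034 * 1.87 * mKs;             /* endo, CiPA rescale */
    double IKs = GKs * KsCa * xs1 * xs2 * (v - EKs);

    /* IK1 */
    double xk1ss = 1.0 / (1.0 + exp(-(v + 2.5538 * ko + 144.59) /
                                    (1.5692 * ko + 3.8115)));
    double txk1 = 122.2 / (exp(-(v + 127.2) / 20.36) +
                           exp((v + 236.8) / 69.33));
    double rk1 = 1.0 / (1.0 + exp((v + 105.8 - 2.6 * ko) / 9.493));
    double GK1 = 0.1908 * 1.698 * mK1;            /* endo, CiPA rescale */
    double IK1 = GK1 * sqrt(ko) * rk1 * xk1 * (v - EK);

    /* INaCa (myoplasmic and subspace components) */
    const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
    const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
    const double kcaon = 1.5e6, kcaoff = 5.0e3;
    const double qna = 0.5224, qca = 0.1670;
    double hca = exp(qca * v * Frdy / (Rgas * T));
    double hna = exp(qna * v * Frdy / (Rgas * T));
    const double KmCaAct = 150.0e-6;
    const double zca = 2.0, zna = 1.0;
    double Gncx = 0.0008;
    double INaCa_i, INaCa_ss;
    {
        double h1 = 1.0 + nai / kna3 * (1.0 + hna);
        double h2 = (nai * hna) / (kna3 * h1);
        double h3 = 1.0 / h1;
        double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
        double h5 = nai * nai / (h4 * kna1 * kna2);
        double h6 = 1.0 / h4;
        double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
        double h8 = nao / (kna3 * hna * h7);
        double h9 = 1.0 / h7;
        double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
        double h11 = nao * nao / (h10 * kna1 * kna2);
        double h12 = 1.0 / h10;
        double k1 = h12 * cao * kcaon;
        double k2 = kcaoff;
        double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
        double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
        double k5 = kcaoff;
        double k6 = h6 * cai * kcaon;
        double k7 = h5 * h2 * wna;
        double k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double allo = 1.0 / (1.0 + (KmCaAct / cai) * (KmCaAct / cai));
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
        INaCa_i = 0.8 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
    }
    {
        double h1 = 1.0 + nass / kna3 * (1.0 + hna);
        double h2 = (nass * hna) / (kna3 * h1);
        double h3 = 1.0 / h1;
        double h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
        double h5 = nass * nass / (h4 * kna1 * kna2);
        double h6 = 1.0 / h4;
        double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
        double h8 = nao / (kna3 * hna * h7);
        double h9 = 1.0 / h7;
        double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
        double h11 = nao * nao / (h10 * kna1 * kna2);
        double h12 = 1.0 / h10;
        double k1 = h12 * cao * kcaon;
        double k2 = kcaoff;
        double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
        double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
        double k5 = kcaoff;
        double k6 = h6 * cass * kcaon;
        double k7 = h5 * h2 * wna;
        double k8 = h8 * h11 * wna;
        double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
        double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
        double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
        double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        double allo = 1.0 / (1.0 + (KmCaAct / cass) * (KmCaAct / cass));
        double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
        double JncxCa = E2 * k2 - E1 * k1;
        INaCa_ss = 0.2 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
    }

    /* INaK */
    double INaK;
    {
        const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
        const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
        const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
        double Knai = Knai0 * exp(delta * v * Frdy / (3.0 * Rgas * T));
        double Knao = Knao0 * exp((1.0 - delta) * v * Frdy / (3.0 * Rgas * T));
        const double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8;
        const double Kmgatp = 1.698e-7, H = 1.0e-7, eP = 4.2;
        const double Khp = 1.698e-7, Knap = 224.0, Kxkur = 292.0;
        double P = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
        double t1 = 1.0 + nai / Knai, t2 = 1.0 + ki / Kki;
        double t3 = 1.0 + nao / Knao, t4 = 1.0 + ko / Kko;
        double a1 = (k1p * (nai / Knai) * (nai / Knai) * (nai / Knai)) /
            (t1 * t1 * t1 + t2 * t2 - 1.0);
        double b1 = k1m * MgADP;
        double a2 = k2p;
        double b2 = (k2m * (nao / Knao) * (nao / Knao) * (nao / Knao)) /
            (t3 * t3 * t3 + t4 * t4 - 1.0);
        double a3 = (k3p * (ko / Kko) * (ko / Kko)) /
            (t3 * t3 * t3 + t4 * t4 - 1.0);
        double b3 = (k3m * P * H) / (1.0 + MgATP / Kmgatp);
        double a4 = (k4p * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
        double b4 = (k4m * (ki / Kki) * (ki / Kki)) /
            (t1 * t1 * t1 + t2 * t2 - 1.0);
        double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
        double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
        double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
        double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
        double E1 = x1 / (x1 + x2 + x3 + x4), E2 = x2 / (x1 + x2 + x3 + x4);
        double E3 = x3 / (x1 + x2 + x3 + x4), E4 = x4 / (x1 + x2 + x3 + x4);
        const double zk = 1.0;
        double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
        double JnakK = 2.0 * (E4 * b1 - E3 * a1);
        const double Pnak = 30.0;
        INaK = Pnak * (zna * JnakNa + zk * JnakK);
    }

    /* background and pump currents */
    double xkb = 1.0 / (1.0 + exp(-(v - 14.48) / 18.34));
    const double GKb = 0.003;
    double IKb = GKb * xkb * (v - EK);
    const double PNab = 3.75e-10;
    double INab = PNab * vffrt * (nai * exp(vfrt) - nao) / expm1s(vfrt);
    const double PCab = 2.5e-8;
    double ICab = PCab * 4.0 * vffrt * (cai * exp(2.0 * vfrt) - 0.341 * cao) /
        expm1s(2.0 * vfrt);
    const double GpCa = 0.0005;
    double IpCa = GpCa * cai / (0.0005 + cai);

    /* stimulus */
    double tb = fmod(*t, cl);
    double Istim = (tb >= 0.0 && tb < stim_dur) ? stim_amp : 0.0;

    /* membrane potential */
    ydot[0] = -(INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab + Istim);

    /* gating ODEs */
    ydot[9] = (mss - m) / tm;
    ydot[10] = (hss - hf) / thf;
    ydot[11] = (hss - hs) / ths;
    ydot[12] = (jss - j) / tj;
    ydot[13] = (hssp - hsp) / thsp;
    ydot[14] = (jss - jp) / tjp;
    ydot[15] = (mLss - mL) / tmL;
    ydot[16] = (hLss - hL) / thL;
    ydot[17] = (hLssp - hLp) / thLp;
    ydot[18] = (ass - a) / ta;
    ydot[19] = (iss - iF) / tiF;
    ydot[20] = (iss - iS) / tiS;
    ydot[21] = (assp - ap) / ta;
    ydot[22] = (iss - iFp) / tiFp;
    ydot[23] = (iss - iSp) / tiSp;
    ydot[24] = (dss - d) / td;
    ydot[25] = (fss - ff) / tff;
    ydot[26] = (fss - fs) / tfs;
    ydot[27] = (fcass - fcaf) / tfcaf;
    ydot[28] = (fcass - fcas) / tfcas;
    ydot[29] = (fcass - jca) / tjca;
    ydot[30] = anca * k2n - nca * km2n;
    ydot[31] = (fss - ffp) / tffp;
    ydot[32] = (fcass - fcafp) / tfcafp;
    ydot[33] = (xs1ss - xs1) / txs1;
    ydot[34] = (xs2ss - xs2) / txs2;
    ydot[35] = (xk1ss - xk1) / txk1;

    /* SR release */
    {
        const double bt = 4.75;
        double a_rel = 0.5 * bt;
        double Jrel_inf = a_rel * (-ICaL) /
            (1.0 + pow(1.5 / cajsr, 8.0));
        double tau_rel = bt / (1.0 + 0.0123 / cajsr);
        if (tau_rel < 0.001) tau_rel = 0.001;
        ydot[36] = (Jrel_inf - Jrelnp) / tau_rel;
        double btp = 1.25 * bt;
        double a_relp = 0.5 * btp;
        double Jrel_infp = a_relp * (-ICaL) /
            (1.0 + pow(1.5 / cajsr, 8.0));
        double tau_relp = btp / (1.0 + 0.0123 / cajsr);
        if (tau_relp < 0.001) tau_relp = 0.001;
        ydot[37] = (Jrel_infp - Jrelp) / tau_relp;
    }
    double Jrel = (1.0 - fCaMK) * Jrelnp + fCaMK * Jrelp;

    /* SR uptake, leak, translocation */
    double Jupnp = 0.004375 * cai / (cai + 0.00092);
    double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
    double Jleak = 0.0039375 * cansr / 15.0;
    double Jup = (1.0 - fCaMK) * Jupnp + fCaMK * Jupp - Jleak;
    double Jtr = (cansr - cajsr) / 100.0;

    /* diffusion fluxes */
    double JdiffNa = (nass - nai) / 2.0;
    double JdiffK = (kss - ki) / 2.0;
    double Jdiff = (cass - cai) / 0.2;

    /* concentrations */
    ydot[1] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
        (Frdy * vmyo) + JdiffNa * vss / vmyo;
    ydot[2] = -(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
    ydot[3] = -(Ito + IKr + IKs + IK1 + IKb + Istim - 2.0 * INaK) * Acap /
        (Frdy * vmyo) + JdiffK * vss / vmyo;
    ydot[4] = -ICaK * Acap / (Frdy * vss) - JdiffK;
    {
        const double cmdnmax = 0.05, kmcmdn = 0.00238;   /* endo */
        const double trpnmax = 0.07, kmtrpn = 0.0005;
        const double bsrmax = 0.047, kmbsr = 0.00087;
        const double bslmax = 1.124, kmbsl = 0.0087;
        const double csqnmax = 10.0, kmcsqn = 0.8;
        double Bcai = 1.0 / (1.0 +
            cmdnmax * kmcmdn / ((kmcmdn + cai) * (kmcmdn + cai)) +
            trpnmax * kmtrpn / ((kmtrpn + cai) * (kmtrpn + cai)));
        ydot[5] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap /
                          (2.0 * Frdy * vmyo) -
                          Jup * vnsr / vmyo + Jdiff * vss / vmyo);
        double Bcass = 1.0 / (1.0 +
            bsrmax * kmbsr / ((kmbsr + cass) * (kmbsr + cass)) +
            bslmax * kmbsl / ((kmbsl + cass) * (kmbsl + cass)));
        ydot[6] = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap /
                           (2.0 * Frdy * vss) +
                           Jrel * vjsr / vss - Jdiff);
        ydot[7] = Jup - Jtr * vjsr / vnsr;
        double Bcajsr = 1.0 / (1.0 +
            csqnmax * kmcsqn / ((kmcsqn + cajsr) * (kmcsqn + cajsr)));
        ydot[8] = Bcajsr * (Jtr - Jrel);
    }

    /* CaMK trap */
    ydot[38] = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;

    /* extra outputs: the seven reported currents */
    if (ip[0] >= 7) {
        yout[0] = IKr;
        yout[1] = INaL;
        yout[2] = ICaL;
        yout[3] = INa;
        yout[4] = IKs;
        yout[5] = IK1;
        yout[6] = Ito;
    }
}
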