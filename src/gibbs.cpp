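// Gibbs sampler for the six-category descent model.
//
// Unknown individuals carry a latent category z and, per locus, a latent
// ordered pair of gene origins (resident/supplemented). Parental
// individuals are fixed-origin: their gene copies always count toward
// their own pool. Allele frequencies get conjugate Dirichlet updates from
// origin-labelled counts; mixing proportions get a Dirichlet update from
// the category counts. Category probabilities for z are computed with the
// origins marginalised, and those same probabilities are accumulated
// (Rao-Blackwellised) for the reported posterior means, so with
// frequencies and mixing fixed the report is exact after one sweep.
//
// Genotypes are integer matrices n x 2L with allele indices 1..K_l and
// 0 for missing; R's RNG is used throughout so set.seed() controls runs.

#include <Rcpp.h>
using namespace Rcpp;

static inline int sample_cat(const double* w, int k, double tot) {
  double u = unif_rand() * tot, acc = 0.0;
  for (int j = 0; j < k; ++j) { acc += w[j]; if (u <= acc) return j; }
  return k - 1;
}

// [[Rcpp::export]]
List gibbs_hybrid_cpp(IntegerMatrix genoU, IntegerMatrix genoR, IntegerMatrix genoS,
                      IntegerVector nAlleles, NumericMatrix phi,
                      int nBurn, int nSweep,
                      NumericMatrix freqR0, NumericMatrix freqS0,
                      bool fixFreq, bool fixPi,
                      double priorPi, NumericVector priorFreq) {
  const int N = genoU.nrow();
  const int L = nAlleles.size();
  const int C = phi.nrow();            // 6 categories
  const int Kmax = freqR0.ncol();

  // fixed parental allele counts per pool
  NumericMatrix baseR(L, Kmax), baseS(L, Kmax);
  for (int i = 0; i < genoR.nrow(); ++i)
    for (int l = 0; l < L; ++l)
      for (int c = 0; c < 2; ++c) {
        int a = genoR(i, 2 * l + c);
        if (a > 0) baseR(l, a - 1) += 1.0;
      }
  for (int i = 0; i < genoS.nrow(); ++i)
    for (int l = 0; l < L; ++l)
      for (int c = 0; c < 2; ++c) {
        int a = genoS(i, 2 * l + c);
        if (a > 0) baseS(l, a - 1) += 1.0;
      }

  NumericMatrix pR(clone(freqR0)), pS(clone(freqS0));
  std::vector<double> pi(C, 1.0 / C);
  std::vector<int> z(N, 0);
  NumericMatrix postAcc(N, C);
  std::vector<double> piAcc(C, 0.0);
  NumericMatrix cntR(L, Kmax), cntS(L, Kmax);
  std::vector<double> lik(C), w4(4);
  int kept = 0;

  if (!fixFreq) {
    // initialise frequencies from the parental counts + prior
    for (int l = 0; l < L; ++l) {
      int K = nAlleles[l];
      double sR = 0, sS = 0;
      for (int a = 0; a < K; ++a) {
        pR(l, a) = rgamma(1, priorFreq[l] + baseR(l, a), 1.0)[0];
        pS(l, a) = rgamma(1, priorFreq[l] + baseS(l, a), 1.0)[0];
        sR += pR(l, a); sS += pS(l, a);
      }
      for (int a = 0; a < K; ++a) { pR(l, a) /= sR; pS(l, a) /= sS; }
    }
  }

  for (int sweep = 0; sweep < nBurn + nSweep; ++sweep) {
    bool keep = sweep >= nBurn;
    std::fill(cntR.begin(), cntR.end(), 0.0);
    std::fill(cntS.begin(), cntS.end(), 0.0);
    std::vector<double> catCount(C, 0.0);

    for (int i = 0; i < N; ++i) {
      // category likelihoods with origins marginalised
      for (int c = 0; c < C; ++c) lik[c] = pi[c];
      for (int l = 0; l < L; ++l) {
        int x = genoU(i, 2 * l), y = genoU(i, 2 * l + 1);
        if (x <= 0 || y <= 0) continue;
        double prx = pR(l, x - 1), pry = pR(l, y - 1);
        double psx = pS(l, x - 1), psy = pS(l, y - 1);
        double hom = (x == y) ? 1.0 : 0.0;
        double lrr = (hom > 0.5) ? prx * prx : 2.0 * prx * pry;
        double lss = (hom > 0.5) ? psx * psx : 2.0 * psx * psy;
        double lrs = (hom > 0.5) ? prx * psx : prx * psy + pry * psx;
        for (int c = 0; c < C; ++c)
          lik[c] *= phi(c, 0) * lrr + phi(c, 1) * lrs + phi(c, 2) * lss;
      }
      double tot = 0.0;
      for (int c = 0; c < C; ++c) tot += lik[c];
      if (tot <= 0.0) { for (int c = 0; c < C; ++c) lik[c] = 1.0; tot = C; }
      if (keep) for (int c = 0; c < C; ++c) postAcc(i, c) += lik[c] / tot;
      int zi = sample_cat(lik.data(), C, tot);
      z[i] = zi;
      catCount[zi] += 1.0;

      // ordered origin pair per locus given z
      for (int l = 0; l < L; ++l) {
        int x = genoU(i, 2 * l), y = genoU(i, 2 * l + 1);
        if (x <= 0 || y <= 0) continue;
        double prx = pR(l, x - 1), pry = pR(l, y - 1);
        double psx = pS(l, x - 1), psy = pS(l, y - 1);
        w4[0] = phi(zi, 0) * prx * pry;          // (res, res)
        w4[1] = 0.5 * phi(zi, 1) * prx * psy;    // (res, sup)
        w4[2] = 0.5 * phi(zi, 1) * psx * pry;    // (sup, res)
        w4[3] = phi(zi, 2) * psx * psy;          // (sup, sup)
        double t4 = w4[0] + w4[1] + w4[2] + w4[3];
        int cfg = (t4 > 0.0) ? sample_cat(w4.data(), 4, t4)
                             : (int)std::floor(unif_rand() * 4.0);
        bool s1 = cfg >= 2;            // first copy from sup pool?
        bool s2 = (cfg == 1 || cfg == 3);
        if (s1) cntS(l, x - 1) += 1.0; else cntR(l, x - 1) += 1.0;
        if (s2) cntS(l, y - 1) += 1.0; else cntR(l, y - 1) += 1.0;
      }
    }

    if (!fixFreq) {
      for (int l = 0; l < L; ++l) {
        int K = nAlleles[l];
        double sR = 0, sS = 0;
        for (int a = 0; a < K; ++a) {
          pR(l, a) = rgamma(1, priorFreq[l] + baseR(l, a) + cntR(l, a), 1.0)[0];
          pS(l, a) = rgamma(1, priorFreq[l] + baseS(l, a) + cntS(l, a), 1.0)[0];
          sR += pR(l, a); sS += pS(l, a);
        }
        for (int a = 0; a < K; ++a) { pR(l, a) /= sR; pS(l, a) /= sS; }
      }
    }
    if (!fixPi) {
      double s = 0.0;
      std::vector<double> g(C);
      for (int c = 0; c < C; ++c) { g[c] = rgamma(1, priorPi + catCount[c], 1.0)[0]; s += g[c]; }
      for (int c = 0; c < C; ++c) pi[c] = g[c] / s;
    }
    if (keep) { for (int c = 0; c < C; ++c) piAcc[c] += pi[c]; ++kept; }
  }

  for (int i = 0; i < N; ++i)
    for (int c = 0; c < C; ++c) postAcc(i, c) /= (double)kept;
  NumericVector piMean(C);
  for (int c = 0; c < C; ++c) piMean[c] = piAcc[c] / (double)kept;

  return List::create(_["post"] = postAcc, _["pi"] = piMean,
                      _["freq_res"] = pR, _["freq_sup"] = pS);
}
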