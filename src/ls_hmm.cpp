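#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Diploid Li-Stephens haplotype-copying HMM, forward-backward.
//
// Hidden state at each site: an ordered pair (j,k) of panel haplotypes.
// The two copying processes switch independently: between adjacent sites
// each haplotype stays with probability 1-s and otherwise jumps to a
// uniformly chosen panel haplotype (including itself).  Emission integrates
// the copying error mu per haplotype allele against the 3 genotype
// likelihoods; because alleles are binary the emission matrix is constant
// on the four allele-class blocks, which the inner loops exploit.
// Everything is kept in scaled linear space with per-site normalisation;
// K^2 * T doubles of predicted-forward state are stored (K capped upstream
// by max_panel).

// out = A' F A with A = (1-s)I + (s/K) J; returns total mass of F
static double transition(const double* F, double* out, int K, double s) {
  const double a = 1.0 - s, b = s / K;
  std::vector<double> rs(K, 0.0), cs(K, 0.0);
  double tot = 0.0;
  for (int k = 0; k < K; ++k) {
    const double* col = F + (size_t)k * K;
    double csum = 0.0;
    for (int j = 0; j < K; ++j) {
      const double f = col[j];
      rs[j] += f; csum += f;
    }
    cs[k] = csum; tot += csum;
  }
  const double aa = a * a, ab = a * b, bb = b * b * tot;
  for (int k = 0; k < K; ++k) {
    const double* col = F + (size_t)k * K;
    double* ocol = out + (size_t)k * K;
    const double ck = ab * cs[k] + bb;
    for (int j = 0; j < K; ++j)
      ocol[j] = aa * col[j] + ab * rs[j] + ck;
  }
  return tot;
}

// [[Rcpp::export(name = ".ls_fwbw")]]
NumericMatrix ls_fwbw(const IntegerMatrix& hap,   // K x T, alleles 0/1
                      const NumericMatrix& lik,   // 3 x T, genotype likelihoods
                      const NumericVector& srate, // T-1 switch probabilities
                      double mu) {
  const int K = hap.nrow(), T = hap.ncol();
  if (lik.ncol() != T || lik.nrow() != 3)
    stop("likelihood matrix must be 3 x n_sites");
  if (T > 0 && srate.size() != T - 1)
    stop("need one switch rate per adjacent site pair");
  const size_t KK = (size_t)K * K;

  std::vector<double> pred((size_t)T * KK);  // prior before emission, scaled
  std::vector<double> F(KK), B(KK), tmp(KK);
  std::vector<int> cls(K);
  // per-site emission by allele class: ecl[a][b], and the three genotype
  // mixture components mcl[g][a][b]
  double ecl[2][2], mcl[3][2][2];
  const double pm[2] = {mu, 1.0 - mu};       // P(copy=1 | class)

  auto site_tables = [&](int t) {
    const double l0 = lik(0, t), l1 = lik(1, t), l2 = lik(2, t);
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) {
        const double pj = pm[a], pk = pm[b];
        mcl[0][a][b] = (1 - pj) * (1 - pk) * l0;
        mcl[1][a][b] = (pj * (1 - pk) + (1 - pj) * pk) * l1;
        mcl[2][a][b] = pj * pk * l2;
        ecl[a][b] = mcl[0][a][b] + mcl[1][a][b] + mcl[2][a][b];
      }
    for (int j = 0; j < K; ++j) cls[j] = hap(j, t);
  };
  auto scale = [&](std::vector<double>& M) {
    double tot = 0.0;
    for (size_t i = 0; i < KK; ++i) tot += M[i];
    if (tot <= 0.0) stop("forward-backward underflow: all-zero state vector");
    const double inv = 1.0 / tot;
    for (size_t i = 0; i < KK; ++i) M[i] *= inv;
  };

  // forward
  for (int t = 0; t < T; ++t) {
    double* pr = &pred[(size_t)t * KK];
    if (t == 0) {
      const double u = 1.0 / (double)KK;
      std::fill(pr, pr + KK, u);
    } else {
      transition(F.data(), pr, K, srate[t - 1]);
    }
    site_tables(t);
    for (int k = 0; k < K; ++k) {
      const double* pcol = pr + (size_t)k * K;
      double* fcol = F.data() + (size_t)k * K;
      const double e0 = ecl[0][cls[k]], e1 = ecl[1][cls[k]];
      for (int j = 0; j < K; ++j)
        fcol[j] = pcol[j] * (cls[j] ? e1 : e0);
    }
    scale(F);
  }

  // backward + collapse to genotype posteriors
  NumericMatrix gp(3, T);
  std::fill(B.begin(), B.end(), 1.0 / (double)KK);
  for (int t = T - 1; t >= 0; --t) {
    const double* pr = &pred[(size_t)t * KK];
    site_tables(t);
    double S[2][2] = {{0.0, 0.0}, {0.0, 0.0}};  // pred*B mass by class pair
    for (int k = 0; k < K; ++k) {
      const double* pcol = pr + (size_t)k * K;
      const double* bcol = B.data() + (size_t)k * K;
      double s0 = 0.0, s1 = 0.0;
      for (int j = 0; j < K; ++j) {
        const double w = pcol[j] * bcol[j];
        if (cls[j]) s1 += w; else s0 += w;
      }
      S[0][cls[k]] += s0; S[1][cls[k]] += s1;
    }
    double g[3] = {0.0, 0.0, 0.0};
    for (int gi = 0; gi < 3; ++gi)
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b)
          g[gi] += S[a][b] * mcl[gi][a][b];
    const double tot = g[0] + g[1] + g[2];
    if (tot <= 0.0) stop("zero posterior mass at site %d", t + 1);
    gp(0, t) = g[0] / tot; gp(1, t) = g[1] / tot; gp(2, t) = g[2] / tot;
    if (t > 0) {
      // fold emission at t into B, then pull back through the transition
      for (int k = 0; k < K; ++k) {
        double* bcol = B.data() + (size_t)k * K;
        double* tcol = tmp.data() + (size_t)k * K;
        const double e0 = ecl[0][cls[k]], e1 = ecl[1][cls[k]];
        for (int j = 0; j < K; ++j)
          tcol[j] = bcol[j] * (cls[j] ? e1 : e0);
      }
      transition(tmp.data(), B.data(), K, srate[t - 1]); // A is symmetric
      scale(B);
    }
  }
  return gp;
}
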