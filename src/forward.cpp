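#include "bp.h"
using namespace Rcpp;

// Recruitment probability for a pre-breeder arriving at age `a` over interval
// j: zero before age 3, age specific at 3..6, forced at 7+.
static inline double recruit_prob(int a, int j, const CRParams& p) {
  switch (a) {
  case 3: return p.rho3[j * p.stride];
  case 4: return p.rho4[j * p.stride];
  case 5: return p.rho5[j * p.stride];
  case 6: return p.rho6[j * p.stride];
  default: return (a >= 7) ? 1.0 : 0.0;
  }
}

double forward_history(const int* obs, int T, int ring, const CRParams& p) {
  // state order: 0 P, 1 F, 2 E, 3 S, 4 dead
  double alpha[5] = {0, 0, 0, 0, 0};
  int y0;  // 1-based year at which the forward pass starts (conditioned on)

  if (ring >= 1) {
    if (ring >= T) return 0.0;  // ringed in the last year: no data
    y0 = ring;
    alpha[0] = 1.0;  // alive chick, age 0
  } else {
    // pre-window bird: condition on first in-window resighting
    y0 = 0;
    for (int y = 1; y <= T; ++y) {
      if (obs[y - 1] > 0) { y0 = y; break; }
    }
    if (y0 == 0 || y0 == T) return 0.0;  // never seen, or seen only at T
    int code = obs[y0 - 1];
    int age = y0 - ring;
    if (code == 1) {
      if (age < 1 || age > 6) return R_NegInf;  // pre-breeder outside ages 1-6
      alpha[0] = 1.0;
    } else if (code == 2) {
      if (age < 3) return R_NegInf;
      alpha[2] = 1.0;  // F and E have identical dynamics onwards
    } else if (code == 3) {
      if (age < 4) return R_NegInf;  // skipped after breeding at >= 3
      alpha[3] = 1.0;
    } else {
      return R_NegInf;
    }
  }

  double ll = 0.0;
  for (int y = y0 + 1; y <= T; ++y) {
    int j = y - 2;          // interval (y-1) -> y
    int a = y - ring;       // age at year y
    double s = (a <= 2) ? p.phi0[j * p.stride] : p.phi2[j * p.stride];
    double phi2 = p.phi2[j * p.stride];
    double psib = p.psib[j * p.stride];
    double psis = p.psis[j * p.stride];
    double rec = recruit_prob(a, j, p);

    double nP = alpha[0] * s * (1.0 - rec);
    double nF = alpha[0] * s * rec;
    double nE = (alpha[1] + alpha[2]) * phi2 * psib + alpha[3] * phi2 * psis;
    double nS = (alpha[1] + alpha[2]) * phi2 * (1.0 - psib) +
                alpha[3] * phi2 * (1.0 - psis);
    double nD = alpha[4] + alpha[0] * (1.0 - s) +
                (alpha[1] + alpha[2] + alpha[3]) * (1.0 - phi2);
    alpha[0] = nP; alpha[1] = nF; alpha[2] = nE; alpha[3] = nS; alpha[4] = nD;

    int code = obs[y - 1];
    if (code >= 0) {
      double pPre = (a == 1) ? p.pY[(y - 2) * p.stride]
                             : p.pP[(y - 2) * p.stride];
      switch (code) {
      case 0:
        alpha[0] *= (1.0 - pPre);
        alpha[1] *= (1.0 - p.pR);
        alpha[2] *= (1.0 - p.pR);
        alpha[3] *= (1.0 - p.pR);
        break;  // dead: unit emission
      case 1:
        alpha[0] *= pPre; alpha[1] = alpha[2] = alpha[3] = alpha[4] = 0.0;
        break;
      case 2:
        alpha[1] *= p.pR; alpha[2] *= p.pR;
        alpha[0] = alpha[3] = alpha[4] = 0.0;
        break;
      case 3:
        alpha[3] *= p.pR;
        alpha[0] = alpha[1] = alpha[2] = alpha[4] = 0.0;
        break;
      default:
        Rcpp::stop("illegal observation code");
      }
    }
    double tot = alpha[0] + alpha[1] + alpha[2] + alpha[3] + alpha[4];
    if (!(tot > 0.0)) return R_NegInf;
    ll += std::log(tot);
    for (int k = 0; k < 5; ++k) alpha[k] /= tot;
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector bp_forward(IntegerMatrix obs, IntegerVector ring,
                         NumericVector phi0, NumericVector phi2,
                         NumericVector rho3, NumericVector rho4,
                         NumericVector rho5, NumericVector rho6,
                         NumericVector psib, NumericVector psis,
                         NumericVector pY, NumericVector pP,
                         double pR, bool time_varying) {
  int H = obs.nrow(), T = obs.ncol();
  CRParams p;
  p.phi0 = phi0.begin(); p.phi2 = phi2.begin();
  p.rho3 = rho3.begin(); p.rho4 = rho4.begin();
  p.rho5 = rho5.begin(); p.rho6 = rho6.begin();
  p.psib = psib.begin(); p.psis = psis.begin();
  p.pY = pY.begin(); p.pP = pP.begin();
  p.pR = pR;
  p.stride = time_varying ? 1 : 0;

  NumericVector out(H);
  std::vector<int> row(T);
  for (int h = 0; h < H; ++h) {
    for (int t = 0; t < T; ++t) row[t] = obs(h, t);
    out[h] = forward_history(row.data(), T, ring[h], p);
  }
  return out;
}
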