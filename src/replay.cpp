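#include <Rcpp.h>
using namespace Rcpp;

// Session-replay likelihoods for the two-step task agents. The R level
// holds the reference implementations built from the exported per-step
// operations; these replays are the hot path for multi-restart fitting
// and must agree with the R engine exactly (tested).

static const double PROB_FLOOR = 1e-12;
static const double CONC_FLOOR = 1e-6;

// Most likely transition structure from counts; ties -> flat (id 3).
// Fills P[a][s]; n11/n22 are "diagonal" (action i -> state i) counts.
static void infer_structure_cpp(const int counts[2][2], double P[2][2]) {
  int nd = counts[0][0] + counts[1][1];
  int no = counts[0][1] + counts[1][0];
  double l07 = nd * std::log(0.7) + no * std::log(0.3);
  double l03 = nd * std::log(0.3) + no * std::log(0.7);
  double lfl = (nd + no) * std::log(0.5);
  double q;
  if (lfl >= std::max(l07, l03) - 1e-12) {
    q = 0.5;
  } else if (l07 > l03) {
    q = 0.7;
  } else {
    q = 0.3;
  }
  P[0][0] = q;       P[0][1] = 1 - q;
  P[1][0] = 1 - q;   P[1][1] = q;
}

static inline void softmax2(double u0, double u1, double* p) {
  double m = std::max(u0, u1);
  double e0 = std::exp(u0 - m), e1 = std::exp(u1 - m);
  p[0] = e0 / (e0 + e1);
  p[1] = e1 / (e0 + e1);
}

static inline double beta_kl_cpp(double a1, double b1, double a2, double b2) {
  return R::lbeta(a2, b2) - R::lbeta(a1, b1) +
         (a1 - a2) * R::digamma(a1) + (b1 - b2) * R::digamma(b1) +
         (a2 - a1 + b2 - b1) * R::digamma(a1 + b1);
}

// [[Rcpp::export]]
double nll_hybrid_cpp(NumericVector par, IntegerVector a1, IntegerVector s2,
                      IntegerVector a2, IntegerVector o, int pure = 0) {
  // par: alpha1, alpha2, elig_lambda, w, beta1, beta2, rho
  // pure: 0 hybrid, 1 model-free only, 2 model-based only
  double alpha1 = par[0], alpha2 = par[1], elig = par[2], w = par[3];
  double beta1 = par[4], beta2 = par[5], rho = par[6];
  int n = a1.size();
  double q1[2] = {0, 0};
  double q2[2][2] = {{0, 0}, {0, 0}};
  int counts[2][2] = {{0, 0}, {0, 0}};
  int prev = -1;
  double nll = 0.0;
  for (int t = 0; t < n; t++) {
    int ia1 = a1[t] - 1, is2 = s2[t] - 1, ia2 = a2[t] - 1, io = o[t];
    double P[2][2];
    infer_structure_cpp(counts, P);
    double best0 = std::max(q2[0][0], q2[0][1]);
    double best1 = std::max(q2[1][0], q2[1][1]);
    double qnet[2];
    for (int j = 0; j < 2; j++) {
      double qmb = P[j][0] * best0 + P[j][1] * best1;
      if (pure == 1) {
        qnet[j] = q1[j];
      } else if (pure == 2) {
        qnet[j] = qmb;
      } else {
        qnet[j] = w * qmb + (1 - w) * q1[j];
      }
    }
    double u0 = beta1 * qnet[0] + (prev == 0 ? rho : 0.0);
    double u1 = beta1 * qnet[1] + (prev == 1 ? rho : 0.0);
    double p[2];
    softmax2(u0, u1, p);
    nll -= std::log(std::max(p[ia1], PROB_FLOOR));
    softmax2(beta2 * q2[is2][0], beta2 * q2[is2][1], p);
    nll -= std::log(std::max(p[ia2], PROB_FLOOR));
    // SARSA(lambda) updates
    double d1 = q2[is2][ia2] - q1[ia1];
    double d2 = io - q2[is2][ia2];
    q1[ia1] += alpha1 * d1 + alpha1 * elig * d2;
    q2[is2][ia2] += alpha2 * d2;
    counts[ia1][is2] += 1;
    prev = ia1;
  }
  return nll;
}

// [[Rcpp::export]]
double nll_ai_cpp(NumericVector par, IntegerVector a1, IntegerVector s2,
                  IntegerVector a2, IntegerVector o,
                  bool prior_pull = false, double hyp_increment = 1.0) {
  // par: pref_lambda, kappa, gamma1, gamma2, prior_mean, l,
  //      nu_ps, nu_sd, nu_ud  (variant nus already zeroed by caller)
  double lam = par[0], kap = par[1], g1 = par[2], g2 = par[3];
  double pm = par[4], l = par[5];
  double nu_ps = par[6], nu_sd = par[7], nu_ud = par[8];
  double a0 = 2.0 * pm, b0 = 2.0 * (1.0 - pm);
  double al[2][2] = {{a0, a0}, {a0, a0}};
  double be[2][2] = {{b0, b0}, {b0, b0}};
  int counts[2][2] = {{0, 0}, {0, 0}};
  int prev = -1;
  int n = a1.size();
  // log preference probabilities
  double lnZ = std::log(std::exp(lam) + std::exp(-lam));
  double lp1 = lam - lnZ, lp0 = -lam - lnZ;
  double m_ps = nu_ps / (1.0 - nu_ps);
  // habit kernel values
  double hZ = std::exp(kap) + std::exp(-kap);
  double h_rep = std::exp(kap) / hZ, h_alt = std::exp(-kap) / hZ;
  double nll = 0.0;
  for (int t = 0; t < n; t++) {
    int ia1 = a1[t] - 1, is2 = s2[t] - 1, ia2 = a2[t] - 1, io = o[t];
    // expected free energy per final-stage pair
    double G[2][2];
    for (int s = 0; s < 2; s++) {
      for (int a = 0; a < 2; a++) {
        double A = al[s][a], B = be[s][a];
        double S = A + B;
        double q1 = A / S;
        double ext = -(q1 * lp1 + (1 - q1) * lp0);
        double intr;
        if (hyp_increment == 1.0) {
          // one-step conjugate update: KL(Beta(a+1,b)||Beta(a,b)) reduces to
          // ln((a+b)/a) + psi(a) + 1/a - psi(a+b) - 1/(a+b)
          double psiS = R::digamma(S), lnS = std::log(S);
          double kl1 = lnS - std::log(A) + R::digamma(A) + 1.0 / A -
                       psiS - 1.0 / S;
          double kl0 = lnS - std::log(B) + R::digamma(B) + 1.0 / B -
                       psiS - 1.0 / S;
          intr = q1 * kl1 + (1 - q1) * kl0;
        } else {
          intr = q1 * beta_kl_cpp(A + hyp_increment, B, A, B) +
                 (1 - q1) * beta_kl_cpp(A, B + hyp_increment, A, B);
        }
        G[s][a] = ext - intr;
      }
    }
    double P[2][2];
    infer_structure_cpp(counts, P);
    double sumG0 = G[0][0] + G[0][1], sumG1 = G[1][0] + G[1][1];
    double u0 = -g1 * (P[0][0] * sumG0 + P[0][1] * sumG1);
    double u1 = -g1 * (P[1][0] * sumG0 + P[1][1] * sumG1);
    if (prev >= 0) {
      u0 += (prev == 0 ? h_rep : h_alt);
      u1 += (prev == 1 ? h_rep : h_alt);
    }
    double p[2];
    softmax2(u0, u1, p);
    nll -= std::log(std::max(p[ia1], PROB_FLOOR));
    softmax2(-g2 * G[is2][0], -g2 * G[is2][1], p);
    nll -= std::log(std::max(p[ia2], PROB_FLOOR));
    // belief update: sampled pair
    double A = al[is2][ia2], B = be[is2][ia2];
    double q1 = A / (A + B);
    double p_obs = io == 1 ? q1 : 1 - q1;
    double ps = -std::log(std::max(p_obs, PROB_FLOOR));
    double chi = m_ps * ps / (1.0 + m_ps * ps);
    double An = (1 - chi) * A + io * l;
    double Bn = (1 - chi) * B + (1 - io) * l;
    if (prior_pull) {
      An += chi * a0;
      Bn += chi * b0;
    }
    An = (1 - nu_sd) * An + nu_sd * a0;
    Bn = (1 - nu_sd) * Bn + nu_sd * b0;
    // unsampled pairs decay toward the prior
    for (int s = 0; s < 2; s++) {
      for (int a = 0; a < 2; a++) {
        al[s][a] = (1 - nu_ud) * al[s][a] + nu_ud * a0;
        be[s][a] = (1 - nu_ud) * be[s][a] + nu_ud * b0;
      }
    }
    al[is2][ia2] = An;
    be[is2][ia2] = Bn;
    for (int s = 0; s < 2; s++) {
      for (int a = 0; a < 2; a++) {
        al[s][a] = std::max(al[s][a], CONC_FLOOR);
        be[s][a] = std::max(be[s][a], CONC_FLOOR);
      }
    }
    counts[ia1][is2] += 1;
    prev = ia1;
  }
  return nll;
}
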