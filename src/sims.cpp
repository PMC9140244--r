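#include <Rcpp.h>
using namespace Rcpp;

// Three-genotype Wright-Fisher forward simulation.
//
// Genotypes: A ancestral, B other-beneficial, C focal CNV. Each generation
// applies mutation (out of A only), viability selection (w = 1, 1+s_B, 1+s_C),
// then multinomial drift at constant size N. Returns the frequency of C at
// every generation 0..n_gen (generation 0 is the all-ancestral state).
//
// Drift uses the conditional-binomial decomposition of the multinomial so N
// can exceed .Machine$integer.max; draws come from R's RNG stream.
// [[Rcpp::export]]
NumericVector wf_core(double delta_c, double s_c, double delta_b, double s_b,
                      double N, int n_gen) {
  NumericVector xc_path(n_gen + 1);
  double xA = 1.0, xB = 0.0, xC = 0.0;
  xc_path[0] = 0.0;
  const double wB = 1.0 + s_b, wC = 1.0 + s_c;
  for (int g = 1; g <= n_gen; ++g) {
    // mutation
    double mA = (1.0 - delta_b - delta_c) * xA;
    double mB = xA * delta_b + xB;
    double mC = xA * delta_c + xC;
    // selection
    double wbar = mA + wB * mB + wC * mC;
    if (wbar <= 0.0) stop("mean fitness is non-positive");
    double pA = mA / wbar, pB = wB * mB / wbar, pC = wC * mC / wbar;
    // multinomial drift via conditional binomials
    double nA = R::rbinom(N, pA);
    double rest = N - nA;
    double pBc = (pA >= 1.0) ? 0.0 : pB / (1.0 - pA);
    if (pBc > 1.0) pBc = 1.0;
    double nB = (rest > 0.0) ? R::rbinom(rest, pBc) : 0.0;
    double nC = N - nA - nB;
    xA = nA / N; xB = nB / N; xC = nC / N;
    xc_path[g] = xC;
  }
  return xc_path;
}

// One tau-leap attempt; returns false (leaving state untouched) if the leap
// would drive a count or the substrate negative.
static bool leap_once(double &nA, double &nB, double &nC, double &S,
                      double tau, double D, double S0, double k, double Y,
                      double rA, double rB, double rC, double volume,
                      double delta_c, double delta_b) {
  double monod = S / (S + k);
  double gA = nA * rA * monod, gB = nB * rB * monod, gC = nC * rC * monod;
  double GA = (gA > 0) ? R::rpois(gA * tau) : 0.0;
  double GB = (gB > 0) ? R::rpois(gB * tau) : 0.0;
  double GC = (gC > 0) ? R::rpois(gC * tau) : 0.0;
  double DA = (nA > 0) ? R::rpois(nA * D * tau) : 0.0;
  double DB = (nB > 0) ? R::rpois(nB * D * tau) : 0.0;
  double DC = (nC > 0) ? R::rpois(nC * D * tau) : 0.0;
  // a fraction delta of ancestral birth events yields mutant offspring
  double MC = (GA > 0 && delta_c > 0) ? R::rbinom(GA, delta_c) : 0.0;
  double rem = GA - MC;
  double pb = (delta_c < 1.0) ? delta_b / (1.0 - delta_c) : 0.0;
  double MB = (rem > 0 && pb > 0) ? R::rbinom(rem, pb) : 0.0;
  double nA2 = nA + GA - MC - MB - DA;
  double nB2 = nB + GB + MB - DB;
  double nC2 = nC + GC + MC - DC;
  double S2 = S + (S0 - S) * D * tau - (GA + GB + GC) / (Y * volume);
  if (nA2 < 0 || nB2 < 0 || nC2 < 0 || S2 < 0) return false;
  nA = nA2; nB = nB2; nC = nC2; S = S2;
  return true;
}

// Advance the chemostat state by dt hours using tau-leaping with step tau.
// If a leap fails the negative-count guard it is retried at tau/2, down to a
// floor of tau/32; at the floor, negative results are clamped at zero.
static void advance(double &nA, double &nB, double &nC, double &S,
                    double dt, double tau, double D, double S0, double k,
                    double Y, double rA, double rB, double rC, double volume,
                    double delta_c, double delta_b) {
  double t = 0.0;
  const double tau_floor = tau / 32.0;
  while (t < dt - 1e-12) {
    double step = std::min(tau, dt - t);
    double sub = step;
    bool ok = false;
    while (!ok) {
      ok = leap_once(nA, nB, nC, S, sub, D, S0, k, Y, rA, rB, rC, volume,
                     delta_c, delta_b);
      if (!ok) {
        if (sub / 2.0 < tau_floor) {
          // at the floor: take the leap and clamp at zero
          double monod = S / (S + k);
          double gA = nA * rA * monod, gB = nB * rB * monod,
                 gC = nC * rC * monod;
          double GA = (gA > 0) ? R::rpois(gA * sub) : 0.0;
          double GB = (gB > 0) ? R::rpois(gB * sub) : 0.0;
          double GC = (gC > 0) ? R::rpois(gC * sub) : 0.0;
          double DA = (nA > 0) ? R::rpois(nA * D * sub) : 0.0;
          double DB = (nB > 0) ? R::rpois(nB * D * sub) : 0.0;
          double DC = (nC > 0) ? R::rpois(nC * D * sub) : 0.0;
          double MC = (GA > 0 && delta_c > 0) ? R::rbinom(GA, delta_c) : 0.0;
          double rem = GA - MC;
          double pb = (delta_c < 1.0) ? delta_b / (1.0 - delta_c) : 0.0;
          double MB = (rem > 0 && pb > 0) ? R::rbinom(rem, pb) : 0.0;
          nA = std::max(0.0, nA + GA - MC - MB - DA);
          nB = std::max(0.0, nB + GB + MB - DB);
          nC = std::max(0.0, nC + GC + MC - DC);
          S = std::max(0.0, S + (S0 - S) * D * sub -
                                (GA + GB + GC) / (Y * volume));
          ok = true;
        } else {
          sub /= 2.0;
        }
      }
    }
    t += sub;
    if (sub < step) {
      // completed only part of this step; continue from the new state
      continue;
    }
  }
}

// Stochastic chemostat simulation recording state at requested hours.
// record_h must be non-decreasing; state is recorded exactly at each mark
// (the last leap before a mark is shortened to land on it).
// [[Rcpp::export]]
List chemo_core(double delta_c, double s_c, double delta_b, double s_b,
                double D, double S0, double k, double Y, double mu_max,
                double volume, double inoculum, double init_frac_b,
                double tau, NumericVector record_h) {
  int m = record_h.size();
  NumericVector oA(m), oB(m), oC(m), oS(m);
  const double ln2 = std::log(2.0);
  double rA = mu_max;
  double rB = mu_max * (1.0 + s_b * ln2);
  double rC = mu_max * (1.0 + s_c * ln2);
  double nB = std::floor(inoculum * init_frac_b + 0.5);
  double nA = inoculum - nB, nC = 0.0, S = S0;
  double t = 0.0;
  for (int i = 0; i < m; ++i) {
    double target = record_h[i];
    if (target < t - 1e-9) stop("record times must be non-decreasing");
    if (target > t) {
      advance(nA, nB, nC, S, target - t, tau, D, S0, k, Y, rA, rB, rC,
              volume, delta_c, delta_b);
      t = target;
    }
    oA[i] = nA; oB[i] = nB; oC[i] = nC; oS[i] = S;
  }
  return List::create(_["hours"] = record_h, _["n_a"] = oA, _["n_b"] = oB,
                      _["n_c"] = oC, _["s_mm"] = oS);
}

// Neutral two-allele Wright-Fisher chain (used as the drift oracle for
// effective-population-size estimation): binomial resampling of p each
// generation, returning the frequency path of allele 1 over n_gen
// generations starting from p0.
// [[Rcpp::export]]
NumericVector wf_neutral_core(double N, double p0, int n_gen) {
  NumericVector path(n_gen + 1);
  double p = p0;
  path[0] = p;
  for (int g = 1; g <= n_gen; ++g) {
    p = R::rbinom(N, p) / N;
    path[g] = p;
  }
  return path;
}
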