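#include <Rcpp.h>
using namespace Rcpp;

// Gamete simulation under a Haldane (no-interference) map.
//
// Loci are a single flat vector ordered by chromosome then genetic
// position.  rfrac[j] is the recombination fraction between locus j and
// locus j+1 (length m-1).  A chromosome boundary is encoded as
// rfrac = 0.5: switching state with probability 1/2 is exactly an
// independent uniform restart, so independent assortment needs no
// special case.

static inline int start_allele() { return unif_rand() < 0.5 ? 1 : 0; }

// [[Rcpp::export]]
IntegerMatrix sim_gametes_cpp(int n, int m, NumericVector rfrac) {
  if (m < 1) stop("need at least one locus");
  if (rfrac.size() != m - 1) stop("rfrac must have length m - 1");
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    int a = start_allele();
    out(i, 0) = a;
    for (int j = 1; j < m; ++j) {
      if (unif_rand() < rfrac[j - 1]) a = 1 - a;
      out(i, j) = a;
    }
  }
  return out;
}

// Rejection-sample surviving seeds of a cross until n_target accumulate.
//
// design: 0 = mea_pool  (homozygous mutant mother, fixed all-A maternal
//                        contribution, every seed maternally mutant)
//         1 = wt_pool   (wild-type mother, fixed all-A maternal
//                        contribution, no seed maternally mutant)
//         2 = f2_selfing (selfed F1: maternal gamete simulated from the
//                        same heterozygous parent; the maternal-effect
//                        locus segregates independently, so a seed is
//                        maternally mutant with probability 1/2)
//
// Survival of a maternally mutant seed is min(cap, v0 * prod r_i) over
// rescue loci where the paternal gamete carries allele B; an infinite
// multiplier short-circuits to `cap` (fully penetrant rescue even when
// v0 = 0).  Maternally wild-type seeds survive with prob wt_viability.
//
// Segregation distortion acts on transmission, before viability: a
// paternal gamete is accepted with weight proportional to b (allele B)
// or 1-b (allele A) at each distortion locus, normalised per locus so
// the maximum weight is 1.
//
// [[Rcpp::export]]
List sim_survivors_cpp(int n_target, int m, NumericVector rfrac,
                       IntegerVector rescue_idx, NumericVector rescue_mult,
                       double v0, double cap, double wt_viability,
                       IntegerVector distort_idx, NumericVector distort_bias,
                       int design, double max_attempts) {
  if (n_target < 1) stop("n_target must be >= 1");
  IntegerMatrix paternal(n_target, m);
  bool selfing = (design == 2);
  IntegerMatrix maternal(selfing ? n_target : 0, selfing ? m : 0);
  LogicalVector mutant(n_target);
  std::vector<int> g(m), gm;
  if (selfing) gm.resize(m);

  int accepted = 0;
  double attempts = 0;
  while (accepted < n_target && attempts < max_attempts) {
    attempts += 1;
    // paternal gamete
    int a = start_allele();
    g[0] = a;
    for (int j = 1; j < m; ++j) {
      if (unif_rand() < rfrac[j - 1]) a = 1 - a;
      g[j] = a;
    }
    // transmission distortion (gametic, independent of seed viability)
    bool rejected = false;
    for (int k = 0; k < distort_idx.size(); ++k) {
      double b = distort_bias[k];
      double hi = b > 1 - b ? b : 1 - b;
      double w = (g[distort_idx[k]] == 1 ? b : 1 - b) / hi;
      if (unif_rand() >= w) { rejected = true; break; }
    }
    if (rejected) continue;

    bool is_mut;
    if (design == 0) is_mut = true;
    else if (design == 1) is_mut = false;
    else is_mut = unif_rand() < 0.5;

    double s;
    if (is_mut) {
      double prod = v0;
      bool full = false;
      for (int k = 0; k < rescue_idx.size(); ++k) {
        if (g[rescue_idx[k]] == 1) {
          if (!R_finite(rescue_mult[k])) full = true;
          else prod *= rescue_mult[k];
        }
      }
      s = full ? cap : (prod < cap ? prod : cap);
    } else {
      s = wt_viability;
    }
    if (unif_rand() >= s) continue;

    if (selfing) {
      int am = start_allele();
      gm[0] = am;
      for (int j = 1; j < m; ++j) {
        if (unif_rand() < rfrac[j - 1]) am = 1 - am;
        gm[j] = am;
      }
      for (int j = 0; j < m; ++j) maternal(accepted, j) = gm[j];
    }
    for (int j = 0; j < m; ++j) paternal(accepted, j) = g[j];
    mutant[accepted] = is_mut;
    ++accepted;
  }
  return List::create(_["paternal"] = paternal,
                      _["maternal"] = maternal,
                      _["maternally_mutant"] = mutant,
                      _["n_accepted"] = accepted,
                      _["attempts"] = attempts);
}
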