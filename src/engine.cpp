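// Whole-population simulation engine.
//
// The model semantics (homing transition tables, survival calibration,
// initial population) are computed in R and passed in; this file only runs
// the stochastic five-stage breeding cycle at speed:
//   (i) mate allocation, (ii) reproduction + inheritance, (iii) zygotic
//   Y-shredding / germline homing (embedded in conception), (iv) density-
//   dependent mortality, (v) aging.
// All randomness flows through R's RNG, so runs are reproducible with
// set.seed().
//
// Allele codes (autosomes): 0 = drive (G); 1 + 2*s + del = W/R allele with
// s susceptible sites and deletion flag del (s >= 1 is W, s == 0 is R).
// Homing-outcome codes: -1 = homing (becomes G), -2 = non-functional
// (embryonic-lethal if inherited, coding placement only), else an allele
// code whose deletion flag is OR-ed with the parent allele's.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct OutcomeTab {
  std::vector<int> code;
  std::vector<double> cum;
};

struct Pop {
  std::vector<int> allos;   // 0 = XX, 1 = XY, 2 = XO
  std::vector<int> am, ap;  // allele codes
  std::vector<int> age;
  std::vector<int> ydrive;  // Y carries X-shredder cassette
  std::vector<int> gyo;     // -1 unset / 0 / 1: lifetime germline-YO state
  size_t size() const { return allos.size(); }
  void reserve(size_t n) {
    allos.reserve(n); am.reserve(n); ap.reserve(n);
    age.reserve(n); ydrive.reserve(n); gyo.reserve(n);
  }
  void push(int a, int m, int p, int g, int yd, int gy) {
    allos.push_back(a); am.push_back(m); ap.push_back(p);
    age.push_back(g); ydrive.push_back(yd); gyo.push_back(gy);
  }
};

inline int sample_outcome(const OutcomeTab& t) {
  double u = unif_rand();
  size_t k = 0;
  while (k + 1 < t.cum.size() && u >= t.cum[k]) ++k;
  return t.code[k];
}

// transmit one autosomal allele from a parent with alleles (a1, a2),
// applying a fresh per-gamete homing event when the parent is a G/W(s>=1)
// heterozygote. Returns the allele code, or -2 for an embryonic lethal
// (non-functional outcomes only enter the tables under coding placement).
inline int transmit_allele(int a1, int a2,
                           const std::vector<OutcomeTab>& tabs) {
  bool g1 = a1 == 0, g2 = a2 == 0;
  if (g1 != g2) {
    int w = g1 ? a2 : a1;
    int s = (w - 1) >> 1;
    int del = (w - 1) & 1;
    if (s >= 1) {
      int out = sample_outcome(tabs[s - 1]);
      if (unif_rand() < 0.5) {             // transmit the modified allele
        if (out == -1) return 0;           // homed: drive
        if (out == -2) return -2;          // non-functional: lethal
        int j = (out - 1) >> 1;
        int dn = (out - 1) & 1;
        return 1 + 2 * j + (dn | del);
      }
      return 0;                            // transmit the drive allele
    }
  }
  return unif_rand() < 0.5 ? a1 : a2;
}

inline int allele_cat(int code) {          // 0 = G, 1 = W, 2 = R
  if (code == 0) return 0;
  return code >= 3 ? 1 : 2;
}

inline int geno_index(int c1, int c2) {    // WW WG GG WR GR RR
  int a = allele_cat(c1), b = allele_cat(c2);
  if (a > b) std::swap(a, b);              // a <= b with order G<W<R
  if (a == 1 && b == 1) return 0;          // WW
  if (a == 0 && b == 1) return 1;          // WG
  if (a == 0 && b == 0) return 2;          // GG
  if (a == 1 && b == 2) return 3;          // WR
  if (a == 0 && b == 2) return 4;          // GR
  return 5;                                // RR
}

void record(const Pop& pop, IntegerMatrix& traj, int row) {
  int n = (int)pop.size();
  int allos[3] = {0, 0, 0};
  int geno[6] = {0, 0, 0, 0, 0, 0};
  int carriers = 0;
  for (size_t i = 0; i < pop.size(); ++i) {
    ++allos[pop.allos[i]];
    ++geno[geno_index(pop.am[i], pop.ap[i])];
    if (pop.am[i] == 0 || pop.ap[i] == 0 || pop.ydrive[i]) ++carriers;
  }
  traj(row, 0) = n;
  for (int k = 0; k < 3; ++k) traj(row, 1 + k) = allos[k];
  for (int k = 0; k < 6; ++k) traj(row, 4 + k) = geno[k];
  traj(row, 10) = carriers;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_simulation(List init, List tables, List pars) {
  const int n_cycles = as<int>(pars["n_cycles"]);
  const double py = as<double>(pars["p_y"]);
  const double pxxo = as<double>(pars["p_x_xo"]);
  const double xofert = as<double>(pars["xo_fertility"]);
  const double litter_mean = as<double>(pars["litter_mean"]);
  const int fmax = as<int>(pars["f_max"]);
  const double surv_a = as<double>(pars["surv_a"]);
  const double surv_b = as<double>(pars["surv_b"]);
  const int strategy = as<int>(pars["strategy"]);  // 0 ychope, 1 xshredder
  const double px = as<double>(pars["p_x"]);
  const double pyyo = as<double>(pars["p_y_yo"]);
  const bool per_gamete = as<bool>(pars["per_gamete"]);

  std::vector<OutcomeTab> tabs(tables.size());
  for (int s = 0; s < tables.size(); ++s) {
    List t = tables[s];
    tabs[s].code = as<std::vector<int> >(t["codes"]);
    tabs[s].cum = as<std::vector<double> >(t["cum"]);
  }

  Pop pop;
  {
    IntegerVector allos = init["allosome"], am = init["allele_m"],
                  ap = init["allele_p"], age = init["age"],
                  yd = init["y_drive"];
    pop.reserve(allos.size() * 2);
    for (int i = 0; i < allos.size(); ++i)
      pop.push(allos[i], am[i], ap[i], age[i], yd[i], -1);
  }

  IntegerMatrix traj(n_cycles + 1, 11);
  record(pop, traj, 0);
  int erad_cycle = -1;

  std::vector<int> females, males, pool, used, pair_f, pair_m;
  Pop born;

  for (int t = 1; t <= n_cycles; ++t) {
    const int n_census = (int)pop.size();
    if (n_census == 0) { erad_cycle = (erad_cycle < 0) ? t - 1 : erad_cycle; break; }

    // (i) mate allocation ---------------------------------------------------
    females.clear(); males.clear();
    for (size_t i = 0; i < pop.size(); ++i)
      (pop.allos[i] == 1 ? males : females).push_back((int)i);
    // random female order (Fisher-Yates)
    for (size_t i = females.size(); i > 1; --i) {
      size_t j = (size_t)(unif_rand() * i);
      if (j >= i) j = i - 1;
      std::swap(females[i - 1], females[j]);
    }
    pool = males;
    used.assign(pool.size(), 0);
    size_t psize = pool.size();
    pair_f.clear(); pair_m.clear();
    for (size_t fi = 0; fi < females.size() && psize > 0; ++fi) {
      size_t k = (size_t)(unif_rand() * psize);
      if (k >= psize) k = psize - 1;
      pair_f.push_back(females[fi]);
      pair_m.push_back(pool[k]);
      if (++used[k] >= fmax) {
        pool[k] = pool[psize - 1];
        used[k] = used[psize - 1];
        --psize;
      }
    }

    // (ii)+(iii) reproduction, inheritance, shredding -----------------------
    born.allos.clear(); born.am.clear(); born.ap.clear();
    born.age.clear(); born.ydrive.clear(); born.gyo.clear();
    for (size_t p = 0; p < pair_f.size(); ++p) {
      const int f = pair_f[p], m = pair_m[p];
      const bool xo_mother = pop.allos[f] == 2;
      const double mean = litter_mean * (xo_mother ? xofert : 1.0);
      const int litter = (int)R::rpois(mean);
      if (litter == 0) continue;

      bool father_yo = false;
      if (strategy == 1 && pop.ydrive[m] && !per_gamete) {
        if (pop.gyo[m] < 0)                 // decide once, at first breeding
          pop.gyo[m] = unif_rand() < px ? 1 : 0;
        father_yo = pop.gyo[m] == 1;
      }

      for (int c = 0; c < litter; ++c) {
        int cm = transmit_allele(pop.am[f], pop.ap[f], tabs);
        if (cm == -2) continue;             // inherited non-functional: lethal
        int cp = transmit_allele(pop.am[m], pop.ap[m], tabs);
        if (cp == -2) continue;

        // maternal allosome
        bool mat_x = !xo_mother || unif_rand() < pxxo;
        // paternal allosome: 0 = X, 1 = Y, 2 = O
        int pat;
        int child_yd = 0;
        if (strategy == 1 && pop.ydrive[m]) {
          bool yo = per_gamete ? (unif_rand() < px) : father_yo;
          if (yo)
            pat = unif_rand() < pyyo ? 1 : 2;
          else
            pat = unif_rand() < 0.5 ? 0 : 1;
          if (pat == 1) child_yd = 1;       // Y-linkage of the cassette
        } else {
          pat = unif_rand() < 0.5 ? 0 : 1;
        }

        if (!mat_x && pat != 0) continue;   // YO or OO conception: lethal
        int allos;
        if (pat == 1) allos = 1;            // XY
        else if (!mat_x || pat == 2) allos = 2;  // XO
        else allos = 0;                     // XX

        // zygotic Y-shredding (ychope only)
        if (strategy == 0 && allos == 1 && (cm == 0 || cp == 0) &&
            unif_rand() < py)
          allos = 2;

        born.push(allos, cm, cp, 0, child_yd, -1);
      }
    }

    // (iv) mortality at pre-breeding-census density, (v) aging -------------
    const double s = 1.0 / (1.0 + std::exp(surv_a + surv_b * n_census));
    Pop next;
    next.reserve(pop.size() + born.size());
    for (size_t i = 0; i < pop.size(); ++i)
      if (unif_rand() < s)
        next.push(pop.allos[i], pop.am[i], pop.ap[i], pop.age[i] + 1,
                  pop.ydrive[i], pop.gyo[i]);
    for (size_t i = 0; i < born.size(); ++i)
      if (unif_rand() < s)
        next.push(born.allos[i], born.am[i], born.ap[i], 1,
                  born.ydrive[i], -1);
    pop = std::move(next);

    record(pop, traj, t);
    if (pop.size() == 0 && erad_cycle < 0) erad_cycle = t;
  }

  return List::create(_["traj"] = traj,
                      _["eradication_cycle"] = erad_cycle);
}
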