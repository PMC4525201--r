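#include <Rcpp.h>
using namespace Rcpp;

// Individual-based Wright-Fisher dynamics of a single sex-linked biallelic locus.
//
// State is tracked as genotype counts, which is an exact summary of the process:
// with random mating and fitness-proportional sampling of parents (with
// replacement), offspring genotypes are conditionally independent given the
// parental genotype counts, so the next generation is a set of binomial draws
// from the fitness-weighted transmission probabilities.
//
// Everything is written for the heterogametic-sex chromosome (X in XY, Z in ZW):
// "het" refers to the sex carrying one copy, "hom" to the sex carrying two.
// The XY/ZW swap is done in the R wrappers by passing the right sex into each slot.

static inline double gauss_fitness(double z, double S) {
  return std::exp(-0.5 * S * z * z);
}

struct WFLocus {
  int N;             // individuals per sex
  double w_het_R, w_het_M;           // hemizygous-sex fitnesses
  double w_hom_RR, w_hom_RM, w_hom_MM; // diploid-sex fitnesses
  // genotype counts
  int n_het_M;       // mutant hemizygotes (0..N)
  int n_hom_RM, n_hom_MM;

  void set_fitness(double z_het, double d_het, double S_het,
                   double z_hom, double d_hom, double S_hom, bool dominant) {
    w_het_R  = gauss_fitness(z_het, S_het);
    w_het_M  = gauss_fitness(z_het + d_het, S_het);
    w_hom_RR = gauss_fitness(z_hom, S_hom);
    double z_rm = dominant ? (z_hom + 2.0 * d_hom) : (z_hom + d_hom);
    w_hom_RM = gauss_fitness(z_rm, S_hom);
    w_hom_MM = gauss_fitness(z_hom + 2.0 * d_hom, S_hom);
  }

  // Place one mutant copy uniformly among the 3N gene copies.
  void seed_single_copy() {
    n_het_M = 0; n_hom_RM = 0; n_hom_MM = 0;
    if (unif_rand() < 1.0 / 3.0) n_het_M = 1; else n_hom_RM = 1;
  }

  int mutant_copies() const { return n_het_M + n_hom_RM + 2 * n_hom_MM; }

  // One Wright-Fisher generation; returns mutant copy count afterwards.
  int step() {
    // Transmission of M from the hemizygous sex (its single sex-linked copy
    // goes to every offspring of the diploid sex; in XY the father -> daughters,
    // in ZW the mother -> sons).
    double w_het_tot = (N - n_het_M) * w_het_R + n_het_M * w_het_M;
    double p_het = (n_het_M * w_het_M) / w_het_tot;
    // Transmission of M from the diploid sex (one of its two copies, to all
    // offspring of either sex).
    int n_hom_RR = N - n_hom_RM - n_hom_MM;
    double w_hom_tot = n_hom_RR * w_hom_RR + n_hom_RM * w_hom_RM + n_hom_MM * w_hom_MM;
    double p_hom = (0.5 * n_hom_RM * w_hom_RM + n_hom_MM * w_hom_MM) / w_hom_tot;

    // Offspring of the hemizygous sex: sex-linked copy comes from the diploid parent.
    int new_het_M = (int) R::rbinom(N, p_hom);
    // Offspring of the diploid sex: one copy from each parental sex, independent.
    double p_mm = p_hom * p_het;
    double p_rm = p_hom * (1.0 - p_het) + (1.0 - p_hom) * p_het;
    int new_MM = (int) R::rbinom(N, p_mm);
    double denom = 1.0 - p_mm;
    int new_RM = (denom > 0.0) ? (int) R::rbinom(N - new_MM, p_rm / denom) : 0;

    n_het_M = new_het_M; n_hom_RM = new_RM; n_hom_MM = new_MM;
    return mutant_copies();
  }
};

// [[Rcpp::export(name = ".wf_invasion_batch")]]
List wf_invasion_batch(int n_reps, int N,
                       double z_het, double d_het, double S_het,
                       double z_hom, double d_hom, double S_hom,
                       bool dominant, double max_gen) {
  WFLocus pop; pop.N = N;
  pop.set_fitness(z_het, d_het, S_het, z_hom, d_hom, S_hom, dominant);
  int fixed = 0, lost = 0, undecided = 0;
  double total_gen = 0.0;
  const int all = 3 * N;
  for (int r = 0; r < n_reps; ++r) {
    pop.seed_single_copy();
    double gen = 0.0;
    int cnt = pop.mutant_copies();
    while (cnt > 0 && cnt < all && gen < max_gen) { cnt = pop.step(); gen += 1.0; }
    total_gen += gen;
    if (cnt == all) ++fixed; else if (cnt == 0) ++lost; else ++undecided;
    if (r % 4096 == 0) checkUserInterrupt();
  }
  return List::create(_["fixed"] = fixed, _["lost"] = lost,
                      _["undecided"] = undecided,
                      _["mean_generations"] = total_gen / n_reps);
}

// Expose a single generation step so tests can verify sex-linked inheritance
// directly (e.g. with all hemizygous parents mutant, every diploid offspring
// is a heterozygote and no hemizygous offspring carries the mutant).
// [[Rcpp::export(name = ".wf_generation_step")]]
IntegerVector wf_generation_step(int N, int n_het_M, int n_hom_RM, int n_hom_MM,
                                 double z_het, double d_het, double S_het,
                                 double z_hom, double d_hom, double S_hom,
                                 bool dominant) {
  WFLocus pop; pop.N = N;
  pop.set_fitness(z_het, d_het, S_het, z_hom, d_hom, S_hom, dominant);
  pop.n_het_M = n_het_M; pop.n_hom_RM = n_hom_RM; pop.n_hom_MM = n_hom_MM;
  pop.step();
  return IntegerVector::create(_["n_het_M"] = pop.n_het_M,
                               _["n_hom_RM"] = pop.n_hom_RM,
                               _["n_hom_MM"] = pop.n_hom_MM);
}

// Origin-fixation simulation: iterate mutation -> invasion; on fixation the
// hemizygous sex moves by delta_het and the diploid sex by 2*delta_hom.
// Returns one row per substitution (plus the initial state). `attempts` counts
// mutations arisen, so attempts/(3*N*mu) is elapsed time in generations when
// segregation time is ignored.
// [[Rcpp::export(name = ".wf_origin_fixation")]]
List wf_origin_fixation(int N, int n_substitutions,
                        double z_het0, double z_hom0,
                        double S_het, double S_hom,
                        double rho, double sigma2,
                        bool dominant, double max_gen, double max_attempts) {
  std::vector<double> zh(1, z_het0), zo(1, z_hom0), att(1, 0.0);
  double z_het = z_het0, z_hom = z_hom0;
  double attempts = 0.0;
  double sd = std::sqrt(sigma2), rc = std::sqrt(1.0 - rho * rho);
  WFLocus pop; pop.N = N;
  const int all = 3 * N;
  bool capped = false;
  for (int s = 0; s < n_substitutions; ++s) {
    for (;;) {
      if (attempts >= max_attempts) { capped = true; break; }
      attempts += 1.0;
      double x1 = norm_rand(), x2 = norm_rand();
      double d_het = sd * x1;
      double d_hom = sd * (rho * x1 + rc * x2);
      pop.set_fitness(z_het, d_het, S_het, z_hom, d_hom, S_hom, dominant);
      pop.seed_single_copy();
      double gen = 0.0;
      int cnt = pop.mutant_copies();
      while (cnt > 0 && cnt < all && gen < max_gen) { cnt = pop.step(); gen += 1.0; }
      if (cnt == all) {
        z_het += d_het;
        z_hom += 2.0 * d_hom;
        zh.push_back(z_het); zo.push_back(z_hom); att.push_back(attempts);
        break;
      }
      if (std::fmod(attempts, 8192.0) == 0.0) checkUserInterrupt();
    }
    if (capped) break;
  }
  return List::create(_["z_het"] = wrap(zh), _["z_hom"] = wrap(zo),
                      _["attempts"] = wrap(att), _["capped"] = capped);
}
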