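#include <Rcpp.h>
using namespace Rcpp;

// Dioecious Wright-Fisher generation cycle with multiplicative selection,
// fitness-proportional polygamous mating within each sex, free
// recombination (independent per-locus Mendelian transmission of unphased
// dosages) and one-way wild-type -> deleterious mutation.
//
// Genotypes are stored as an integer dosage matrix (individuals x loci,
// values 0/1/2). Uses R's RNG so set.seed() governs reproducibility.

static double genotype_fitness_row(const IntegerMatrix& geno, int i,
                                   const NumericVector& s,
                                   const NumericVector& h) {
  const int L = geno.ncol();
  double w = 1.0;
  for (int l = 0; l < L; ++l) {
    const int d = geno(i, l);
    if (d == 1) {
      w *= 1.0 - s[l] * h[l];
    } else if (d == 2) {
      w *= 1.0 - s[l];
    }
    if (w == 0.0) return 0.0;
  }
  return w;
}

// [[Rcpp::export(name = ".genotype_fitness_cpp")]]
NumericVector genotype_fitness_cpp(IntegerMatrix geno, NumericVector s,
                                   NumericVector h) {
  const int N = geno.nrow();
  NumericVector w(N);
  for (int i = 0; i < N; ++i) w[i] = genotype_fitness_row(geno, i, s, h);
  return w;
}

// [[Rcpp::export(name = ".population_load_cpp")]]
double population_load_cpp(IntegerMatrix geno, NumericVector s,
                           NumericVector h) {
  const int N = geno.nrow();
  const int L = geno.ncol();
  double load = 0.0;
  for (int l = 0; l < L; ++l) {
    long sum = 0;
    for (int i = 0; i < N; ++i) sum += geno(i, l);
    const double q = static_cast<double>(sum) / (2.0 * N);
    load += s[l] * (1.0 - 2.0 * h[l]) * (1.0 - q) * q;
  }
  return load;
}

// Draw an index proportional to cumulative weights cum (last entry total).
static int sample_cum(const std::vector<double>& cum) {
  const double r = unif_rand() * cum.back();
  return static_cast<int>(std::lower_bound(cum.begin(), cum.end(), r) -
                          cum.begin());
}

// One transmitted allele from parent with dosage d (0/1/2).
static inline int transmit(int d) {
  if (d == 0) return 0;
  if (d == 2) return 1;
  return unif_rand() < 0.5 ? 1 : 0;
}

// Simulate n_gen generations in place. Records mean fitness and the
// standing load s(1-2h)pq for generations 0..n_gen (stats of the incoming
// population first). `female` flags the sex of each row; offspring keep a
// fixed half-and-half sex ratio with females in the first N/2 rows.
// With selection = false parents are drawn uniformly within sex.
// Throws if every individual of one sex has zero fitness (extinction).
// [[Rcpp::export(name = ".wf_sim_cpp")]]
List wf_sim_cpp(IntegerMatrix geno, LogicalVector female, NumericVector s,
                NumericVector h, NumericVector u, int n_gen,
                bool selection, bool track_het) {
  const int N = geno.nrow();
  const int L = geno.ncol();
  if (N % 2 != 0) stop("population size must be even (sex ratio of one)");

  IntegerMatrix cur = clone(geno);
  LogicalVector fem = clone(female);
  NumericVector w_mean(n_gen + 1), load(n_gen + 1), het(n_gen + 1);

  RNGScope scope;

  for (int gen = 0; gen <= n_gen; ++gen) {
    NumericVector w = genotype_fitness_cpp(cur, s, h);
    w_mean[gen] = mean(w);
    load[gen] = population_load_cpp(cur, s, h);
    if (track_het) {
      double hsum = 0.0;
      for (int l = 0; l < L; ++l) {
        long sum = 0;
        for (int i = 0; i < N; ++i) sum += cur(i, l);
        const double q = static_cast<double>(sum) / (2.0 * N);
        hsum += 2.0 * q * (1.0 - q);
      }
      het[gen] = hsum / L;
    }
    if (gen == n_gen) break;

    // cumulative sampling weights within each sex
    std::vector<int> fidx, midx;
    fidx.reserve(N / 2); midx.reserve(N / 2);
    for (int i = 0; i < N; ++i) (fem[i] ? fidx : midx).push_back(i);
    if (fidx.empty() || midx.empty()) stop("one sex is missing");
    std::vector<double> fcum(fidx.size()), mcum(midx.size());
    double acc = 0.0;
    for (size_t i = 0; i < fidx.size(); ++i) {
      acc += selection ? w[fidx[i]] : 1.0;
      fcum[i] = acc;
    }
    if (acc <= 0.0) stop("extinction: all females have zero fitness");
    acc = 0.0;
    for (size_t i = 0; i < midx.size(); ++i) {
      acc += selection ? w[midx[i]] : 1.0;
      mcum[i] = acc;
    }
    if (acc <= 0.0) stop("extinction: all males have zero fitness");

    IntegerMatrix next(N, L);
    for (int o = 0; o < N; ++o) {
      const int mom = fidx[sample_cum(fcum)];
      const int dad = midx[sample_cum(mcum)];
      for (int l = 0; l < L; ++l) {
        next(o, l) = transmit(cur(mom, l)) + transmit(cur(dad, l));
      }
    }

    // One-way mutation: each transmitted wild-type allele mutates with
    // probability u[l]; equivalently Binomial(#wild-type copies, u[l])
    // mutations placed uniformly without replacement among those copies.
    for (int l = 0; l < L; ++l) {
      if (u[l] <= 0.0) continue;
      long wt = 0;
      for (int i = 0; i < N; ++i) wt += 2 - next(i, l);
      if (wt == 0) continue;
      int m = static_cast<int>(R::rbinom(static_cast<double>(wt), u[l]));
      for (int j = 0; j < m; ++j) {
        long r = static_cast<long>(unif_rand() * static_cast<double>(wt));
        if (r >= wt) r = wt - 1;
        long acc2 = 0;
        for (int i = 0; i < N; ++i) {
          acc2 += 2 - next(i, l);
          if (acc2 > r) { next(i, l) += 1; break; }
        }
        --wt;
      }
    }
    for (int i = 0; i < N; ++i) fem[i] = i < N / 2;
    cur = next;
  }

  return List::create(_["geno"] = cur, _["female"] = fem,
                      _["w_mean"] = w_mean, _["load"] = load,
                      _["het"] = het);
}
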