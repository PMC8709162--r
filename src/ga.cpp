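#include <Rcpp.h>
using namespace Rcpp;

// Ordinal bin of a continuous opinion in [0,1] on an n-point scale:
// ceil(y * n), snapping products within 1e-12 of an integer first so exact
// bin boundaries are not pushed up a bin, with y = 0 mapping to bin 1.
static inline int bin_of(double y, int n) {
  double z = y * n;
  double r = std::round(z);
  if (std::fabs(z - r) < 1e-12) z = r;
  int b = (int)std::ceil(z);
  if (b < 1) b = 1;
  if (b > n) b = n;
  return b;
}

// Bin-gated objective: simulate plain DeGroot from x0 through the last
// observed step, and at each observed step t > 0 add
// B(xhat, xobs) * |xhat - xobs| per agent, where B is the bin deviation
// and xobs the mid-bin transform of the observed ordinal score.
// [[Rcpp::export]]
double cpp_objective(const NumericMatrix& W, const NumericVector& x0,
                     const IntegerMatrix& obs, const IntegerVector& steps,
                     int n) {
  const int M = x0.size();
  if (W.nrow() != M || W.ncol() != M || obs.nrow() != M ||
      obs.ncol() != steps.size())
    stop("dimension mismatch in objective");
  std::vector<double> x(x0.begin(), x0.end()), xn(M);
  double f = 0.0;
  int k = 0;
  const int t_max = steps.size() ? steps[steps.size() - 1] : 0;
  for (int t = 1; t <= t_max; ++t) {
    for (int i = 0; i < M; ++i) {
      double s = 0.0;
      for (int j = 0; j < M; ++j) s += W(i, j) * x[j];
      if (s < 0.0) s = 0.0;
      if (s > 1.0) s = 1.0;
      xn[i] = s;
    }
    x = xn;
    if (k < steps.size() && steps[k] == t) {
      for (int i = 0; i < M; ++i) {
        double xobs = (obs(i, k) - 0.5) / n;
        int B = std::abs(bin_of(x[i], n) - obs(i, k));
        if (B > 0) f += B * std::fabs(x[i] - xobs);
      }
      ++k;
    }
  }
  return f;
}

// Uniform random feasible chromosome: i.i.d. U(0,1) on permitted entries,
// rows normalised to sum 1.
// [[Rcpp::export]]
NumericMatrix cpp_random_chromosome(const NumericMatrix& A) {
  const int M = A.nrow();
  NumericMatrix W(M, M);
  for (int i = 0; i < M; ++i) {
    double s = 0.0;
    for (int j = 0; j < M; ++j)
      if (A(i, j) == 1.0) { W(i, j) = unif_rand(); s += W(i, j); }
    if (s <= 0.0) { W(i, i) = 1.0; s = 1.0; }
    for (int j = 0; j < M; ++j) W(i, j) /= s;
  }
  return W;
}

// Blending: per gene (row), a convex combination of the two parents with
// a fresh U(0,1) coefficient. Convexity preserves row sums, bounds and
// structural zeros.
// [[Rcpp::export]]
NumericMatrix cpp_blend(const NumericMatrix& W1, const NumericMatrix& W2) {
  const int M = W1.nrow();
  NumericMatrix C(M, M);
  for (int i = 0; i < M; ++i) {
    double u = unif_rand();
    for (int j = 0; j < M; ++j)
      C(i, j) = u * W1(i, j) + (1.0 - u) * W2(i, j);
  }
  return C;
}

// Crossover: exchange whole genes — each row taken from either parent
// with probability 1/2.
// [[Rcpp::export]]
NumericMatrix cpp_crossover(const NumericMatrix& W1,
                            const NumericMatrix& W2) {
  const int M = W1.nrow();
  NumericMatrix C(M, M);
  for (int i = 0; i < M; ++i) {
    const NumericMatrix& P = (unif_rand() < 0.5) ? W1 : W2;
    for (int j = 0; j < M; ++j) C(i, j) = P(i, j);
  }
  return C;
}

static void mutate_row(NumericMatrix& W, const NumericMatrix& A, int i,
                       double sd) {
  const int M = W.ncol();
  double s = 0.0;
  for (int j = 0; j < M; ++j) {
    if (A(i, j) == 1.0) {
      double v = W(i, j) + norm_rand() * sd;
      W(i, j) = (v > 0.0) ? v : 0.0;
    } else {
      W(i, j) = 0.0;
    }
    s += W(i, j);
  }
  if (s <= 0.0) {  // all permitted mass clipped away: redraw uniformly
    for (int j = 0; j < M; ++j)
      if (A(i, j) == 1.0) { W(i, j) = unif_rand(); s += W(i, j); }
    if (s <= 0.0) { W(i, i) = 1.0; s = 1.0; }
  }
  for (int j = 0; j < M; ++j) W(i, j) /= s;
}

// Mutation: perturb every permitted entry of each row with Normal(0, sd)
// noise, clip at zero, renormalise the row.
// [[Rcpp::export]]
NumericMatrix cpp_mutate(const NumericMatrix& W, const NumericMatrix& A,
                         double sd) {
  NumericMatrix C = clone(W);
  for (int i = 0; i < C.nrow(); ++i) mutate_row(C, A, i, sd);
  return C;
}

// Full GA loop. Population of feasible chromosomes; tournament selection,
// whole-row crossover, per-row blending, per-row mutation, elitist
// survival. Uses R's RNG throughout, so set.seed() makes runs exactly
// reproducible. Returns the best individual found.
// [[Rcpp::export]]
List cpp_ga_fit(const NumericMatrix& A, const NumericVector& x0,
                const IntegerMatrix& obs, const IntegerVector& steps,
                int n, int pop_size, int n_generations, int tournament_size,
                double blend_rate, double crossover_rate,
                double mutation_rate, double mutation_sd, int elite_count,
                double tol) {
  const int M = A.nrow();
  std::vector<NumericMatrix> pop(pop_size);
  std::vector<double> fit(pop_size);
  for (int k = 0; k < pop_size; ++k) {
    pop[k] = cpp_random_chromosome(A);
    fit[k] = cpp_objective(pop[k], x0, obs, steps, n);
  }
  NumericVector trace(n_generations);
  int gens = 0;
  bool converged = false;

  std::vector<int> idx(pop_size);
  for (int g = 0; g < n_generations; ++g) {
    // rank current population (ascending objective)
    for (int k = 0; k < pop_size; ++k) idx[k] = k;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return fit[a] < fit[b]; });
    gens = g + 1;
    trace[g] = fit[idx[0]];
    if (fit[idx[0]] <= tol) { converged = true; break; }

    std::vector<NumericMatrix> next(pop_size);
    std::vector<double> nfit(pop_size);
    int e = std::min(elite_count, pop_size);
    for (int k = 0; k < e; ++k) {      // elitist survival
      next[k] = pop[idx[k]];
      nfit[k] = fit[idx[k]];
    }
    for (int k = e; k < pop_size; ++k) {
      // tournament selection of two parents
      int p1 = -1, p2 = -1;
      for (int r = 0; r < tournament_size; ++r) {
        int c = (int)(unif_rand() * pop_size);
        if (c >= pop_size) c = pop_size - 1;
        if (p1 < 0 || fit[c] < fit[p1]) p1 = c;
      }
      for (int r = 0; r < tournament_size; ++r) {
        int c = (int)(unif_rand() * pop_size);
        if (c >= pop_size) c = pop_size - 1;
        if (p2 < 0 || fit[c] < fit[p2]) p2 = c;
      }
      NumericMatrix child = clone(pop[p1]);
      if (unif_rand() < crossover_rate) {
        for (int i = 0; i < M; ++i)
          if (unif_rand() < 0.5)
            for (int j = 0; j < M; ++j) child(i, j) = pop[p2](i, j);
      }
      if (unif_rand() < blend_rate) {
        for (int i = 0; i < M; ++i) {
          double u = unif_rand();
          for (int j = 0; j < M; ++j)
            child(i, j) = u * child(i, j) + (1.0 - u) * pop[p2](i, j);
        }
      }
      for (int i = 0; i < M; ++i)
        if (unif_rand() < mutation_rate) mutate_row(child, A, i, mutation_sd);
      next[k] = child;
      nfit[k] = cpp_objective(child, x0, obs, steps, n);
    }
    pop.swap(next);
    fit.swap(nfit);
  }

  int best = 0;
  for (int k = 1; k < pop_size; ++k)
    if (fit[k] < fit[best]) best = k;
  return List::create(_["weights"] = pop[best],
                      _["objective"] = fit[best],
                      _["generations"] = gens,
                      _["converged"] = converged,
                      _["trace"] = trace[Range(0, std::max(gens - 1, 0))]);
}
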