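// Continuous genetic algorithm over the non-negative L1 ball for
// maximizing x' W x + lambda * f' x. The population loop lives here;
// seeding, initialization and the final simplex projection stay in R.
// All randomness goes through R's RNG so set.seed() governs the run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double runif01() { return unif_rand(); }

// fitness of every column of X: diag(X' W X) + lam * f' X
static arma::vec fitness_all(const arma::mat& W, const arma::vec& f,
                             double lam, const arma::mat& X) {
  arma::mat WX = W * X;
  arma::vec quad = arma::sum(X % WX, 0).t();
  arma::vec lin = X.t() * f;
  return quad + lam * lin;
}

// repair into the non-negative L1 ball: clip negatives, rescale if sum > 1
static void repair(arma::vec& x) {
  x.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  double s = arma::accu(x);
  if (s > 1.0) {
    x /= s;
  } else if (s == 0.0) {
    x.fill(1.0 / x.n_elem);  // degenerate individual: reset to barycenter
  }
}

// exact sort-and-scan Euclidean projection onto the standard simplex
static void project_simplex(arma::vec& x) {
  arma::vec u = arma::sort(x, "descend");
  double css = 0.0, nu = 0.0;
  arma::uword rho = 0;
  for (arma::uword j = 0; j < u.n_elem; ++j) {
    css += u(j);
    double cand = (css - 1.0) / (j + 1);
    if (u(j) - cand > 0.0) {
      rho = j + 1;
      nu = cand;
    }
  }
  (void)rho;
  x.transform([nu](double v) { double w = v - nu; return w > 0.0 ? w : 0.0; });
}

// tournament of two: index of the fitter of two random individuals
static arma::uword tournament(const arma::vec& fit) {
  arma::uword P = fit.n_elem;
  arma::uword a = (arma::uword)(runif01() * P); if (a >= P) a = P - 1;
  arma::uword b = (arma::uword)(runif01() * P); if (b >= P) b = P - 1;
  return fit(a) >= fit(b) ? a : b;
}

// [[Rcpp::export]]
List ga_core(const arma::mat& W, const arma::vec& f, double lam,
             arma::mat pop, int iterations, double mutation_rate,
             double crossover_rate, int elitism, int convergence_window,
             double convergence_tol, bool early_stop, bool project_each,
             int trace_every) {
  const arma::uword k = W.n_rows;
  const arma::uword P = pop.n_cols;
  if (k == 0) stop("empty problem: k = 0");
  if (pop.n_rows != k) stop("population dimension mismatch");
  if (elitism < 1) elitism = 1;
  if ((arma::uword)elitism > P) elitism = P;

  arma::vec fit = fitness_all(W, f, lam, pop);
  if (!fit.is_finite()) stop("non-finite objective at generation 0");

  arma::uword best_idx = fit.index_max();
  arma::vec best = pop.col(best_idx);
  double best_obj = fit(best_idx);

  std::vector<double> trace_gen, trace_best, trace_var;
  std::vector<double> best_hist;  // best objective per generation
  best_hist.reserve(iterations);

  bool converged = false;
  int gen = 0;
  for (gen = 1; gen <= iterations; ++gen) {
    // next generation: elites first, then offspring
    arma::mat next(k, P);
    arma::uvec ord = arma::sort_index(fit, "descend");
    for (int e = 0; e < elitism; ++e) next.col(e) = pop.col(ord(e));

    const double inv_k = 1.0 / (double)k;
    for (arma::uword c = elitism; c < P; ++c) {
      arma::uword p1 = tournament(fit);
      arma::vec child;
      if (runif01() < crossover_rate) {
        arma::uword p2 = tournament(fit);
        double alpha = runif01();  // arithmetic crossover
        child = alpha * pop.col(p1) + (1.0 - alpha) * pop.col(p2);
      } else {
        child = pop.col(p1);
      }
      for (arma::uword i = 0; i < k; ++i) {
        if (runif01() < mutation_rate) {
          double sigma = 0.1 * (child(i) + inv_k);
          child(i) += sigma * norm_rand();
        }
      }
      repair(child);
      if (project_each) project_simplex(child);
      next.col(c) = child;
    }
    pop = next;
    fit = fitness_all(W, f, lam, pop);
    if (!fit.is_finite()) {
      stop("non-finite objective at generation %d", gen);
    }

    best_idx = fit.index_max();
    if (fit(best_idx) > best_obj) {   // elitism keeps this monotone
      best_obj = fit(best_idx);
      best = pop.col(best_idx);
    }
    best_hist.push_back(best_obj);

    if (gen % trace_every == 0 || gen == iterations) {
      trace_gen.push_back(gen);
      trace_best.push_back(best_obj);
      trace_var.push_back(arma::var(fit));
    }

    // stagnation of the elitist best over the convergence window
    if (gen >= convergence_window) {
      double then = best_hist[gen - convergence_window];
      double scale = std::max(1.0, std::fabs(best_obj));
      if (best_obj - then <= convergence_tol * scale) {
        converged = true;
        if (early_stop) break;
      }
    }
    if (gen % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  if (gen > iterations) gen = iterations;

  return List::create(
    _["best"] = best,
    _["best_objective"] = best_obj,
    _["trace_generation"] = trace_gen,
    _["trace_best"] = trace_best,
    _["trace_variance"] = trace_var,
    _["generations_run"] = gen,
    _["converged"] = converged
  );
}
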