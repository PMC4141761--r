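#' Sub-network objective function
#'
#' The quantity maximized over the standard simplex:
#' `F(x) = x' W x + lambda * f' x`. For an unweighted adjacency `W` and
#' `f = 0` this is the Motzkin-Straus form whose simplex maximum is
#' `1 - 1/omega`, `omega` the clique number.
#'
#' @param x Non-negative numeric vector (typically on the simplex).
#' @param net A `background_network` from [combine_networks()].
#' @param lam Positive balance parameter between the edge (quadratic) and
#'   node (linear) terms.
#' @return The objective value (scalar).
#' @export
objective <- function(x, net, lam) {
  stopifnot(inherits(net, "background_network"))
  x <- as.numeric(x)
  if (length(x) != length(net$f)) {
    stop("x has length ", length(x), " but the network has ",
         length(net$f), " genes", call. = FALSE)
  }
  drop(crossprod(x, net$W %*% x)) + lam * sum(net$f * x)
}

#' Estimate the balance parameter lambda
#'
#' Samples sub-networks as uniformly distributed points on the standard
#' simplex (flat Dirichlet), computes each point's edge score `x' W x` and
#' node score `f' x`, takes each score's magnitude `M` as its mean over
#' the sample, and returns the ratio `lambda = M_e / M_n`. This puts the
#' two terms of the objective on a comparable scale for the data set at
#' hand. `magnitude = "mean_sd"` uses mean plus one standard deviation
#' instead.
#'
#' @param net A `background_network`.
#' @param n_samples Number of simplex points (>= 100).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param magnitude `"mean"` (default) or `"mean_sd"`.
#' @return A positive scalar lambda.
#' @export
estimate_lambda <- function(net, n_samples = 1000L, seed = NULL,
                            magnitude = c("mean", "mean_sd")) {
  magnitude <- match.arg(magnitude)
  stopifnot(inherits(net, "background_network"), n_samples >= 100L)
  k <- length(net$f)
  with_preserved_seed(seed, {
    G <- matrix(stats::rexp(k * n_samples), nrow = k)
    X <- sweep(G, 2L, colSums(G), "/")
    edge <- colSums(X * (net$W %*% X))
    node <- drop(crossprod(X, net$f))
    add_sd <- as.numeric(magnitude == "mean_sd")
    m_e <- mean(edge) + add_sd * stats::sd(edge)
    m_n <- mean(node) + add_sd * stats::sd(node)
    if (m_n == 0) {
      stop("node scores are identically zero; lambda undefined", call. = FALSE)
    }
    m_e / m_n
  })
}

#' Euclidean projection onto the standard simplex
#'
#' Finds the point of the simplex `{x : x >= 0, sum(x) = 1}` nearest to `y`
#' in Euclidean norm: `x_i = max(y_i - nu, 0)` with the dual variable `nu`
#' the root of `sum_i max(y_i - nu, 0) = 1`. The default solver is the
#' exact sort-and-scan algorithm; `method = "bisection"` solves the same
#' dual root-finding problem iteratively and is kept as a cross-check.
#'
#' @param y Finite numeric vector.
#' @param method `"sort"` (exact) or `"bisection"`.
#' @param tol Root tolerance for the bisection method.
#' @return A list with `x` (the projection, named like `y`) and `nu` (the
#'   dual optimal point).
#' @export
#' @examples
#' project_to_simplex(c(0.5, 0.5, 0.5))  # x = (1/3, 1/3, 1/3), nu = 1/6
project_to_simplex <- function(y, method = c("sort", "bisection"),
                               tol = 1e-12) {
  method <- match.arg(method)
  nm <- names(y)
  y <- as.numeric(y)
  stopifnot(all(is.finite(y)))
  k <- length(y)
  if (method == "sort") {
    u <- sort(y, decreasing = TRUE)
    css <- cumsum(u)
    j <- seq_len(k)
    rho <- max(j[u - (css - 1) / j > 0])
    nu <- (css[rho] - 1) / rho
  } else {
    lo <- min(y) - 1 / k
    hi <- max(y)
    g <- function(nu) sum(pmax(y - nu, 0)) - 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    nu <- (lo + hi) / 2
  }
  x <- pmax(y - nu, 0)
  x <- x / sum(x)  # absorb roundoff so the output sums to exactly 1
  names(x) <- nm
  list(x = x, nu = nu)
}

#' Genetic algorithm configuration
#'
#' Defaults follow the method's published settings: 60,000 iterations,
#' counted as objective evaluations (the reading consistent with the
#' method's reported runtimes), mutation rate `1/(k+1)` (resolved when the
#' problem size is known), crossover rate 0.5. Population size (8, as
#' customary for continuous genetic algorithms of this family; 60,000
#' evaluations are then 7,500 generations), tournament selection and the
#' Gaussian mutation scale `0.1 * (x_i + 1/k)` are this implementation's
#' choices, validated on the Motzkin-Straus clique-recovery suite.
#'
#' @param iterations Maximum objective evaluations; divided by
#'   `population_size` to give the number of generations.
#' @param mutation_rate Per-coordinate mutation probability; `NULL` means
#'   `1/(k+1)`.
#' @param crossover_rate Probability of arithmetic crossover, in (0, 1].
#' @param population_size Number of individuals.
#' @param elitism_count Individuals copied unchanged each generation.
#' @param seed Integer seed governing the whole run.
#' @param convergence_window Objective evaluations over which stagnation
#'   of the best objective is assessed (divided by `population_size` like
#'   `iterations`).
#' @param convergence_tol Relative improvement below which the run is
#'   declared converged.
#' @param early_stop Stop at convergence instead of exhausting
#'   `iterations`.
#' @param project_each Project every individual onto the simplex each
#'   generation (default: only the final solution is projected).
#' @param trace_every Record the trace every this many generations.
#' @return A `ga_config` list.
#' @export
ga_config <- function(iterations = 60000L, mutation_rate = NULL,
                      crossover_rate = 0.5, population_size = 8L,
                      elitism_count = 2L, seed = 1L,
                      convergence_window = 10000L, convergence_tol = 1e-6,
                      early_stop = TRUE, project_each = FALSE,
                      trace_every = 1L) {
  stopifnot(iterations >= 1, crossover_rate > 0, crossover_rate <= 1,
            population_size >= 2, elitism_count >= 1,
            convergence_window >= 1, convergence_tol >= 0, trace_every >= 1)
  if (!is.null(mutation_rate)) {
    stopifnot(mutation_rate > 0, mutation_rate <= 1)
  }
  structure(
    list(iterations = as.integer(iterations), mutation_rate = mutation_rate,
         crossover_rate = crossover_rate,
         population_size = as.integer(population_size),
         elitism_count = as.integer(elitism_count), seed = as.integer(seed),
         convergence_window = as.integer(convergence_window),
         convergence_tol = convergence_tol, early_stop = early_stop,
         project_each = project_each, trace_every = as.integer(trace_every)),
    class = "ga_config"
  )
}

#' Maximize the sub-network objective with a continuous genetic algorithm
#'
#' Evolves a population of non-negative vectors inside the L1 ball
#' (feasibility repair: negatives clipped to 0, rescaled when the sum
#' exceeds 1) with tournament selection, arithmetic crossover, per-
#' coordinate Gaussian mutation and elitism. The best individual is
#' projected exactly onto the simplex at the end ([project_to_simplex()]),
#' which sparsifies it. Fully reproducible given `cfg$seed`.
#'
#' @param net A `background_network`.
#' @param lam Positive balance parameter (see [estimate_lambda()]).
#' @param cfg A [ga_config()].
#' @return A `wmaxc_fit` object: list with `x_star` (named simplex vector),
#'   `objective_value`, `lambda_used`, `dual_nu`, `ga_trace` (tibble of
#'   generation, best objective, population variance), `converged`,
#'   `generations_run`, `config`.
#' @export
ga_maximize <- function(net, lam, cfg = ga_config()) {
  stopifnot(inherits(net, "background_network"), lam > 0,
            inherits(cfg, "ga_config"))
  k <- length(net$f)
  if (k == 0L) stop("empty network: k = 0", call. = FALSE)
  mut <- if (is.null(cfg$mutation_rate)) 1 / (k + 1) else cfg$mutation_rate
  with_preserved_seed(cfg$seed, {
    P <- cfg$population_size
    # initial population on the simplex: flat-Dirichlet points plus two
    # informed starts (barycenter and the normalized node-weight profile)
    G <- matrix(stats::rexp(k * P), nrow = k)
    pop <- sweep(G, 2L, colSums(G), "/")
    pop[, 1L] <- rep(1 / k, k)
    if (sum(net$f) > 0) pop[, 2L] <- net$f / sum(net$f)
    generations <- max(1L, as.integer(ceiling(cfg$iterations / P)))
    window <- max(1L, as.integer(ceiling(cfg$convergence_window / P)))
    res <- ga_core(net$W, net$f, lam, pop,
                   iterations = generations, mutation_rate = mut,
                   crossover_rate = cfg$crossover_rate,
                   elitism = cfg$elitism_count,
                   convergence_window = window,
                   convergence_tol = cfg$convergence_tol,
                   early_stop = cfg$early_stop,
                   project_each = cfg$project_each,
                   trace_every = cfg$trace_every)
    proj <- project_to_simplex(drop(res$best))
    x_star <- stats::setNames(proj$x, net$gene_ids)
    structure(
      list(
        x_star = x_star,
        objective_value = objective(x_star, net, lam),
        lambda_used = lam,
        dual_nu = proj$nu,
        ga_trace = tibble::tibble(
          generation = as.integer(res$trace_generation),
          best_objective = res$trace_best,
          population_variance = res$trace_variance
        ),
        converged = res$converged,
        generations_run = res$generations_run,
        config = cfg
      ),
      class = "wmaxc_fit"
    )
  })
}

#' @export
print.wmaxc_fit <- function(x, ...) {
  cat("<wmaxc_fit> objective ", signif(x$objective_value, 6),
      "; lambda ", signif(x$lambda_used, 4),
      "; ", sum(x$x_star > 1e-6), " genes in support; ",
      x$generations_run, " generations (",
      if (x$converged) "converged" else "iteration limit", ")\n", sep = "")
  invisible(x)
}

#' Extract the sub-network from an optimized solution
#'
#' The selected genes are the support of the optimal simplex vector
#' (entries above `eps`); their `x` values are the contribution scores.
#' Genes are ordered by contribution descending, ties broken by gene ID
#' for determinism; the induced edges are the gene pairs of the support
#' with positive background-network weight.
#'
#' @param res A `wmaxc_fit` from [ga_maximize()].
#' @param net The `background_network` the fit was computed on.
#' @param eps Support threshold on contribution mass.
#' @return A `subnetwork` object: list with `genes` (tibble: `gene_id`,
#'   `contribution`) and `edges` (tibble: `from`, `to`, `weight`).
#' @export
extract_subnetwork <- function(res, net, eps = 1e-6) {
  stopifnot(inherits(res, "wmaxc_fit"), inherits(net, "background_network"))
  x <- res$x_star
  sel <- which(x > eps)
  if (length(sel) == 0L) {
    stop("empty support at eps = ", eps, "; try a smaller eps", call. = FALSE)
  }
  genes <- tibble::tibble(
    gene_id = net$gene_ids[sel],
    contribution = unname(x[sel])
  )
  genes <- dplyr::arrange(genes, dplyr::desc(.data$contribution),
                          .data$gene_id)
  Ws <- net$W[sel, sel, drop = FALSE]
  up <- which(upper.tri(Ws) & Ws > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = net$gene_ids[sel][up[, 1L]],
    to = net$gene_ids[sel][up[, 2L]],
    weight = Ws[up]
  )
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(list(genes = genes, edges = edges, eps = eps),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("<subnetwork> ", nrow(x$genes), " genes, ", nrow(x$edges),
      " induced edges\n", sep = "")
  print(utils::head(x$genes, 10))
  invisible(x)
}

#' Identify the condition-specific sub-network
#'
#' The full pipeline: per-condition summaries, fudge-factor estimation,
#' moderated-T node scores, conditional-expectation edge scores, optional
#' PPI distance-based T-scores fused via max-normalized scaling, hard
#' thresholding of the combined weights, data-driven estimation of the
#' balance parameter lambda, genetic-algorithm maximization over the
#' simplex, exact simplex projection, and support extraction.
#'
#' @param expr A [conditioned_expression()] object (condition 1 is the
#'   reference; scores are condition 2 minus condition 1).
#' @param ppi Optional [ppi_network()]; `NULL` runs the expression-only
#'   mode.
#' @param user_scale1,user_scale2 PPI contribution multipliers (see
#'   [combine_networks()]).
#' @param threshold_mode Hard-threshold rule (see
#'   [apply_hard_thresholds()]).
#' @param s0_quantiles Candidate grid for [estimate_s0()]; used only when
#'   the data have at least 20 genes, otherwise `s0 = 0`.
#' @param lambda Balance parameter; `NULL` (default) estimates it with
#'   [estimate_lambda()].
#' @param lambda_samples Simplex samples for the lambda estimate.
#' @param eps Support threshold for [extract_subnetwork()].
#' @param ga A [ga_config()]; its `seed` is overridden by `seed`.
#' @param seed Integer master seed for the whole run (lambda sampling and
#'   GA use seeds derived from it).
#' @return A `wmaxc_result` object: list with `subnetwork`, `fit`, `net`
#'   (thresholded background network), `node_scores`, `weighted_degree`,
#'   `s0`, `lambda`, `mode`, `seed`, `thresholds`.
#' @export
#' @examples
#' study <- simulate_study(simulation_config(k = 40, n = 30, n_sig = 8,
#'                                           seed = 1))
#' res <- wmaxc(study$expr, ga = ga_config(iterations = 300,
#'                                         convergence_window = 100),
#'              seed = 1)
#' glance(res)
wmaxc <- function(expr, ppi = NULL, user_scale1 = 1, user_scale2 = 1,
                  threshold_mode = "mean",
                  s0_quantiles = seq(0, 1, by = 0.05), lambda = NULL,
                  lambda_samples = 1000L, eps = 1e-6, ga = ga_config(),
                  seed = 1L) {
  stopifnot(inherits(expr, "conditioned_expression"))
  seed <- as.integer(seed)
  stats <- summarize_conditions(expr)
  k <- length(stats$gene_ids)
  s0 <- if (k >= 20L) estimate_s0(expr, quantiles = s0_quantiles) else 0
  t <- node_scores(stats, s0 = s0)
  E <- edge_scores(expr, stats, s0 = s0)
  dbt <- if (!is.null(ppi)) dbt_scores(expr, stats, ppi, s0 = s0) else NULL
  raw_net <- combine_networks(E, t, dbt, user_scale1 = user_scale1,
                              user_scale2 = user_scale2)
  thr <- apply_hard_thresholds(raw_net$W, raw_net$f,
                               threshold_mode = threshold_mode)
  net <- background_network(thr$E, thr$t$t, gene_ids = stats$gene_ids,
                            beta1 = raw_net$beta1, beta2 = raw_net$beta2,
                            user_scale1 = user_scale1,
                            user_scale2 = user_scale2)
  if (is.null(lambda)) {
    lambda <- estimate_lambda(net, n_samples = lambda_samples, seed = seed)
  }
  ga$seed <- seed + 1L
  fit <- ga_maximize(net, lambda, ga)
  subnet <- extract_subnetwork(fit, net, eps = eps)
  structure(
    list(
      subnetwork = subnet,
      fit = fit,
      net = net,
      node_scores = t,
      weighted_degree = if (is.null(dbt)) {
        stats::setNames(numeric(k), stats$gene_ids)
      } else {
        dbt$deg
      },
      s0 = s0,
      lambda = lambda,
      mode = if (is.null(ppi)) "expression-only" else "ppi-integrated",
      seed = seed,
      thresholds = c(edge = thr$threshold_edge, node = thr$threshold_node)
    ),
    class = "wmaxc_result"
  )
}

#' @export
print.wmaxc_result <- function(x, ...) {
  cat("<wmaxc_result> mode: ", x$mode, "; s0 = ", signif(x$s0, 4),
      "; lambda = ", signif(x$lambda, 4), "\n", sep = "")
  print(x$subnetwork)
  invisible(x)
}
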