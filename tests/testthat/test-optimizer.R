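test_that("objective evaluates x'Wx + lambda f'x", {
  set.seed(7)
  k <- 5
  W <- random_adjacency(k, 0.6) * runif(k * k)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  f <- runif(k)
  net <- background_network(W, f)
  x <- runif(k)
  x <- x / sum(x)
  # scalar double-loop oracle
  acc <- 0
  for (i in 1:k) for (j in 1:k) acc <- acc + x[i] * W[i, j] * x[j]
  acc <- acc + 0.7 * sum(f * x)
  expect_equal(objective(x, net, 0.7), acc, tolerance = 1e-12)

  # unit vertex: quadratic term vanishes on a zero diagonal
  e3 <- replace(numeric(k), 3, 1)
  expect_equal(objective(e3, net, 0.7), 0.7 * f[3])

  # triangle at the barycenter: 1 - 1/3
  K3 <- matrix(1, 3, 3) - diag(3)
  netK3 <- background_network(K3, numeric(3))
  expect_equal(objective(rep(1 / 3, 3), netK3, 1), 2 / 3)

  expect_error(objective(c(0.5, 0.5), net, 1), "length")
})

test_that("lambda estimation is reproducible and scales correctly", {
  set.seed(12)
  k <- 4
  W <- random_adjacency(k, 0.9)
  f <- c(0.5, 1, 0.2, 0.8)
  net <- background_network(W, f)
  lam <- estimate_lambda(net, n_samples = 1000, seed = 99)
  expect_gt(lam, 0)
  expect_equal(estimate_lambda(net, n_samples = 1000, seed = 99), lam)

  # independent re-implementation of the recipe on the same RNG stream
  set.seed(99)
  G <- matrix(rexp(k * 1000), nrow = k)
  edges <- nodes <- numeric(1000)
  for (s in 1:1000) {
    x <- G[, s] / sum(G[, s])
    edges[s] <- drop(t(x) %*% W %*% x)
    nodes[s] <- sum(f * x)
  }
  expect_equal(lam, mean(edges) / mean(nodes), tolerance = 1e-12)

  # linearity: scaling W scales lambda; scaling f divides it
  expect_equal(estimate_lambda(background_network(3 * W, f), seed = 99),
               3 * lam, tolerance = 1e-12)
  expect_equal(estimate_lambda(background_network(W, 2 * f), seed = 99),
               lam / 2, tolerance = 1e-12)

  expect_error(estimate_lambda(background_network(W, numeric(k)), seed = 1),
               "identically zero")
})

test_that("simplex projection is exact, idempotent and 1-Lipschitz", {
  # symmetry forces uniformity
  p <- project_to_simplex(c(0.5, 0.5, 0.5))
  expect_equal(p$x, rep(1 / 3, 3))
  expect_equal(p$nu, 1 / 6)

  # a point already on the simplex is fixed, with non-positive dual
  y <- c(0.2, 0.3, 0.5)
  p2 <- project_to_simplex(y)
  expect_equal(p2$x, y)
  expect_lte(p2$nu, 0)

  # agreement with the active-set QP oracle on random vectors
  set.seed(5)
  for (rep in 1:100) {
    k <- sample(3:6, 1)
    y <- rnorm(k, sd = 2)
    p <- project_to_simplex(y)
    expect_equal(sum(p$x), 1, tolerance = 1e-12)
    expect_true(all(p$x >= 0))
    expect_equal(p$x, oracle_project_simplex(y), tolerance = 1e-10)
    # idempotence
    expect_equal(project_to_simplex(p$x)$x, p$x, tolerance = 1e-12)
    # bisection solves the same dual root problem
    expect_equal(project_to_simplex(y, method = "bisection")$x, p$x,
                 tolerance = 1e-8)
  }

  # non-expansiveness on random pairs
  set.seed(6)
  for (rep in 1:50) {
    y <- rnorm(8)
    z <- rnorm(8)
    d <- sqrt(sum((project_to_simplex(y)$x - project_to_simplex(z)$x)^2))
    expect_lte(d, sqrt(sum((y - z)^2)) + 1e-12)
  }

  expect_equal(project_to_simplex(c(1.2, 0.1, -0.3))$x,
               oracle_project_simplex(c(1.2, 0.1, -0.3)), tolerance = 1e-10)
})

test_that("the GA recovers planted cliques and dominates naive searches", {
  # unique triangle in a 5-node graph, f = 0, lambda -> 0
  A <- matrix(0, 5, 5)
  tri <- c(1, 2, 3)
  A[tri, tri] <- 1
  A[4, 5] <- A[5, 4] <- 1
  diag(A) <- 0
  net <- background_network(A, numeric(5))
  fit <- ga_maximize(net, lam = 1e-9, ga_config(seed = 4))
  sub <- extract_subnetwork(fit, net)
  expect_setequal(sub$genes$gene_id, paste0("g", tri))
  expect_equal(fit$objective_value, 2 / 3, tolerance = 1e-3)
  expect_equal(nrow(sub$edges), 3L)

  # random indefinite 6-dim problem: the GA beats every vertex and a
  # resolution-0.1 grid search over the simplex
  set.seed(44)
  W <- matrix(rnorm(36), 6, 6)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  f <- abs(rnorm(6))
  net6 <- background_network(W, f)
  fit6 <- ga_maximize(net6, lam = 0.5, ga_config(seed = 4))
  vertex_best <- max(vapply(1:6, function(i) {
    objective(replace(numeric(6), i, 1), net6, 0.5)
  }, numeric(1)))
  grid <- oracle_simplex_grid(6, 10)
  grid_best <- max(apply(grid, 1, objective, net = net6, lam = 0.5))
  expect_gte(fit6$objective_value, vertex_best - 1e-9)
  expect_gte(fit6$objective_value, grid_best - 1e-9)
})

test_that("the GA is deterministic, monotone under elitism, and well-posed", {
  set.seed(3)
  W <- random_adjacency(7, 0.5)
  net <- background_network(W, abs(rnorm(7)))
  cfg <- ga_config(iterations = 8000, seed = 11)
  a <- ga_maximize(net, 0.3, cfg)
  b <- ga_maximize(net, 0.3, cfg)
  expect_identical(a$ga_trace, b$ga_trace)     # bit-identical traces
  expect_identical(a$x_star, b$x_star)
  expect_true(all(diff(a$ga_trace$best_objective) >= 0))
  expect_equal(a$objective_value, objective(a$x_star, net, 0.3))
  expect_equal(sum(a$x_star), 1, tolerance = 1e-12)

  # k = 1: the simplex is a single point
  net1 <- background_network(matrix(0, 1, 1), 2)
  fit1 <- ga_maximize(net1, 1, ga_config(iterations = 64, seed = 1))
  expect_equal(unname(fit1$x_star), 1)
})

test_that("sub-network extraction applies the support threshold", {
  net <- background_network(matrix(0, 3, 3), c(1, 1, 1),
                            gene_ids = c("a", "b", "c"))
  fit <- structure(list(
    x_star = c(a = 0.6, b = 0.4 - 1e-8, c = 1e-8),
    objective_value = 1, lambda_used = 1, dual_nu = 0,
    ga_trace = tibble::tibble(), converged = TRUE, generations_run = 0,
    config = ga_config()
  ), class = "wmaxc_fit")
  sub <- extract_subnetwork(fit, net, eps = 1e-6)
  expect_equal(sub$genes$gene_id, c("a", "b"))   # descending contribution
  expect_equal(nrow(sub$edges), 0L)
  expect_error(extract_subnetwork(fit, net, eps = 2), "empty support")
})
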