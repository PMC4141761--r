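test_that("per-condition summaries match textbook formulas", {
  expr <- toy_expression(k = 4, n1 = 5, n2 = 5, seed = 11)
  st <- summarize_conditions(expr)
  or <- oracle_stats(expr)
  expect_equal(unname(st$mu1), or$mu1, tolerance = 1e-12)
  expect_equal(unname(st$mu2), or$mu2, tolerance = 1e-12)
  expect_equal(unname(st$sd1), or$sd1, tolerance = 1e-12)
  expect_equal(unname(st$sd2), or$sd2, tolerance = 1e-12)
  expect_equal(unname(st$rho1), or$rho1, tolerance = 1e-10)
  expect_equal(unname(st$rho2), or$rho2, tolerance = 1e-10)
  expect_equal(st$p1 + st$p2, 1)
  expect_equal(st$p1, 0.5)

  # a single hand-checked gene: samples (1,2,3) -> mean 2, sd 1
  X <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  st2 <- summarize_conditions(conditioned_expression(X, X))
  expect_equal(unname(st2$mu1), c(2, 5))
  expect_equal(unname(st2$sd1), c(1, 1))
  # identical conditions give identical summaries
  expect_equal(st2$mu1, st2$mu2)
  expect_equal(st2$rho1, st2$rho2)
})

test_that("constant genes get zero correlations instead of errors", {
  X1 <- rbind(flat = rep(1, 5), var = rnorm(5))
  X2 <- rbind(flat = rnorm(5), var = rnorm(5))
  st <- summarize_conditions(conditioned_expression(X1, X2))
  expect_true(st$constant1[["flat"]])
  expect_equal(st$rho1["flat", "var"], 0)
  expect_equal(diag(st$rho1), c(flat = 1, var = 1))
})

test_that("s0 minimizes the windowed CV criterion over the grid", {
  set.seed(42)
  ids <- paste0("g", 1:50)
  X1 <- matrix(rnorm(50 * 10, sd = runif(50, 0.2, 3)), 50, 10,
               dimnames = list(ids, NULL))
  X2 <- matrix(rnorm(50 * 10, mean = rep(c(0, 1), 25),
                     sd = runif(50, 0.2, 3)), 50, 10,
               dimnames = list(ids, NULL))
  expr <- conditioned_expression(X1, X2)
  grid <- seq(0, 1, by = 0.25)
  s0 <- estimate_s0(expr, quantiles = grid)

  # exhaustive evaluation of the same criterion at every grid point
  st <- summarize_conditions(expr)
  s <- oracle_pooled_scale(st$sd1, st$sd2, st$n1, st$n2)
  cands <- unname(quantile(s, grid))
  win <- cut(rank(s, ties.method = "first"), 10, labels = FALSE)
  cv <- vapply(cands, function(c0) {
    t <- (st$mu2 - st$mu1) / (s + c0)
    m <- vapply(split(t, win), mad, numeric(1))
    sd(m) / mean(m)
  }, numeric(1))
  expect_equal(s0, cands[which.min(cv)])
  expect_true(s0 %in% cands)
  expect_gte(s0, 0)

  # degenerate grid collapses to the only candidate
  expect_equal(estimate_s0(expr, quantiles = 0), unname(quantile(s, 0)))
  expect_error(estimate_s0(toy_expression(k = 5), quantiles = grid),
               "at least 20")
})

test_that("node scores are the moderated two-sample statistics", {
  expr <- toy_expression(k = 4, seed = 3)
  st <- summarize_conditions(expr)
  t0 <- node_scores(st, s0 = 0)
  s <- oracle_pooled_scale(st$sd1, st$sd2, st$n1, st$n2)
  expect_equal(t0$t, unname((st$mu2 - st$mu1) / s), tolerance = 1e-12)

  # no mean shift -> zero score for any s0
  X <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
  stz <- summarize_conditions(conditioned_expression(X, X))
  expect_equal(node_scores(stz, s0 = 0.3)$t, rep(0, 4))

  # |T| non-increasing in s0
  mags <- sapply(c(0, 0.1, 0.5, 2), function(s0) abs(node_scores(st, s0)$t))
  expect_true(all(diff(t(mags)) <= 1e-14))
})

test_that("conditional T matches the conditional-normal oracle and its limits", {
  expr <- toy_expression(k = 3, seed = 5)
  st <- summarize_conditions(expr)
  xs <- seq(-2, 8, length.out = 13)
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    expect_equal(conditional_t(xs, i, j, st, s0 = 0.1),
                 vapply(xs, oracle_conditional_t, numeric(1),
                        i = i, j = j, st = st, s0 = 0.1),
                 tolerance = 1e-12)
  }

  # zero correlation in both conditions -> marginal node score, any x
  st0 <- st
  st0$rho1 <- diag(3)
  st0$rho2 <- diag(3)
  tj <- node_scores(st0, s0 = 0.1)$t[2]
  expect_equal(conditional_t(xs, 1, 2, st0, s0 = 0.1), rep(tj, length(xs)))

  # identical conditions -> zero for every x
  X <- matrix(rnorm(15), 3, 5, dimnames = list(paste0("g", 1:3), NULL))
  sti <- summarize_conditions(conditioned_expression(X, X))
  expect_equal(conditional_t(xs, 1, 2, sti, s0 = 0.1), rep(0, length(xs)))
})

test_that("edge scores equal the per-sample loop oracle", {
  for (center in c(TRUE, FALSE)) {
    expr <- toy_expression(k = 3, n1 = 5, n2 = 5, seed = 8)
    E <- edge_scores(expr, s0 = 0.2, center = center)
    expect_equal(E, oracle_edge_scores(expr, s0 = 0.2, center = center),
                 tolerance = 1e-10)
  }
  expr5 <- toy_expression(k = 5, n1 = 6, n2 = 4, seed = 9)
  E5 <- edge_scores(expr5, s0 = 0.05)
  expect_equal(E5, oracle_edge_scores(expr5, s0 = 0.05), tolerance = 1e-10)
  expect_equal(E5, t(E5))
  expect_equal(unname(diag(E5)), rep(0, 5))
  expect_true(all(is.finite(E5)))
})

test_that("null data drives node and edge scores toward zero with n", {
  # the fudge factor matters here: the raw statistic is pivotal, so only
  # the regularized scores concentrate at 0 under the null as n grows;
  # averaged over seeds so a single unlucky draw cannot flip the sign
  mean_abs <- function(n, seed, s0 = 0.5) {
    set.seed(seed)
    k <- 15
    ids <- paste0("g", 1:k)
    draw <- function() matrix(rnorm(k * n), k, n, dimnames = list(ids, NULL))
    expr <- conditioned_expression(draw(), draw())
    st <- summarize_conditions(expr)
    E <- edge_scores(expr, st, s0 = s0)
    c(t = mean(abs(node_scores(st, s0)$t)), e = mean(abs(E[upper.tri(E)])))
  }
  small <- rowMeans(vapply(21:23, function(s) mean_abs(20, s), numeric(2)))
  large <- rowMeans(vapply(21:23, function(s) mean_abs(200, s), numeric(2)))
  expect_lt(large[["t"]], small[["t"]])
  expect_lt(large[["e"]], small[["e"]])
  expect_lt(large[["t"]], 0.2)
  expect_lt(large[["e"]], 0.2)
})

test_that("hard thresholds keep ties, zero the weak, and never mutate inputs", {
  ids <- paste0("g", 1:4)
  E <- matrix(0, 4, 4, dimnames = list(ids, ids))
  E[upper.tri(E)] <- c(0.1, 0.2, 0.3, 0.4, 0.1, 0.3)
  E <- E + t(E)
  t <- tibble::tibble(gene_id = ids, t = c(-0.1, 0.5, 0.2, 1.2))
  E_orig <- E

  thr <- apply_hard_thresholds(E, t, binarize = FALSE)
  expect_identical(E, E_orig)   # input untouched
  # survivors enumerated by hand: mean of positive |E| entries
  m <- mean(c(0.1, 0.2, 0.3, 0.4, 0.1, 0.3))
  expect_equal(thr$threshold_edge, m)
  kept <- abs(E_orig) >= m
  expect_equal(thr$E > 0, kept)
  expect_equal(thr$E[kept], abs(E_orig)[kept])
  # node rule: mean absolute score, ties survive
  expect_equal(thr$threshold_node, mean(abs(t$t)))
  expect_equal(thr$t$t, ifelse(abs(t$t) >= mean(abs(t$t)), abs(t$t), 0))

  # binarized variant has the same survivor pattern with unit weights
  thrb <- apply_hard_thresholds(E, t)
  expect_true(all(thrb$E %in% c(0, 1)))
  expect_equal(thrb$E > 0, thr$E > 0)
  expect_true(all(thrb$t$t %in% c(0, 1)))

  # all entries equal: threshold equals the common value, everything kept
  Eq <- matrix(0.3, 3, 3) - diag(0.3, 3)
  thr_eq <- apply_hard_thresholds(Eq, rep(0.7, 3), binarize = FALSE)
  expect_equal(sum(thr_eq$E == 0.3), 6)
  expect_equal(thr_eq$t$t, rep(0.7, 3))

  # all-zero input comes back unchanged
  z <- apply_hard_thresholds(matrix(0, 3, 3), rep(0, 3))
  expect_equal(unname(z$E), matrix(0, 3, 3))
  expect_equal(z$t$t, rep(0, 3))
})
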