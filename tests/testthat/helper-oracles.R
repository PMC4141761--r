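# Independent oracles and small fixture builders. Everything here
# re-derives quantities from first principles (explicit loops, textbook
# formulas, brute force) so tests never share a code path with the
# implementation they check.

toy_expression <- function(k = 4, n1 = 5, n2 = 5, seed = 1) {
  set.seed(seed)
  ids <- paste0("g", seq_len(k))
  X1 <- matrix(rnorm(k * n1, mean = seq_len(k), sd = 1), k, n1,
               dimnames = list(ids, NULL))
  X2 <- matrix(rnorm(k * n2, mean = seq_len(k) + 0.5, sd = 1.5), k, n2,
               dimnames = list(ids, NULL))
  conditioned_expression(X1, X2)
}

# textbook per-gene statistics via explicit loops
oracle_stats <- function(expr) {
  k <- length(expr$gene_ids)
  mean_of <- function(v) sum(v) / length(v)
  sd_of <- function(v) sqrt(sum((v - mean_of(v))^2) / (length(v) - 1))
  cor_of <- function(a, b) {
    sum((a - mean_of(a)) * (b - mean_of(b))) /
      ((length(a) - 1) * sd_of(a) * sd_of(b))
  }
  out <- list(mu1 = numeric(k), mu2 = numeric(k), sd1 = numeric(k),
              sd2 = numeric(k), rho1 = diag(k), rho2 = diag(k))
  for (i in seq_len(k)) {
    out$mu1[i] <- mean_of(expr$X1[i, ])
    out$mu2[i] <- mean_of(expr$X2[i, ])
    out$sd1[i] <- sd_of(expr$X1[i, ])
    out$sd2[i] <- sd_of(expr$X2[i, ])
  }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) {
      out$rho1[i, j] <- cor_of(expr$X1[i, ], expr$X1[j, ])
      out$rho2[i, j] <- cor_of(expr$X2[i, ], expr$X2[j, ])
    }
  }
  out
}

# pooled SAM-style scale, written out
oracle_pooled_scale <- function(sd1, sd2, n1, n2) {
  sqrt((1 / n1 + 1 / n2) *
         ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

# conditional T of gene j given gene i at value x, from the bivariate
# normal conditional moments, written out scalar-by-scalar
oracle_conditional_t <- function(x, i, j, st, s0) {
  clamp <- function(r) min(max(r, -1 + 1e-8), 1 - 1e-8)
  r1 <- if (st$sd1[i] > 0) clamp(st$rho1[i, j]) else 0
  r2 <- if (st$sd2[i] > 0) clamp(st$rho2[i, j]) else 0
  m1 <- st$mu1[j] +
    (if (st$sd1[i] > 0) r1 * st$sd1[j] / st$sd1[i] else 0) * (x - st$mu1[i])
  m2 <- st$mu2[j] +
    (if (st$sd2[i] > 0) r2 * st$sd2[j] / st$sd2[i] else 0) * (x - st$mu2[i])
  v1 <- st$sd1[j] * sqrt(1 - r1^2)
  v2 <- st$sd2[j] * sqrt(1 - r2^2)
  (m2 - m1) / (oracle_pooled_scale(v1, v2, st$n1, st$n2) + s0)
}

# edge-score matrix by brute-force looping over genes and pooled samples
oracle_edge_scores <- function(expr, s0, center = TRUE) {
  st <- summarize_conditions(expr)
  k <- length(expr$gene_ids)
  tmarg <- vapply(seq_len(k), function(j) {
    (st$mu2[j] - st$mu1[j]) /
      (oracle_pooled_scale(st$sd1[j], st$sd2[j], st$n1, st$n2) + s0)
  }, numeric(1))
  M <- matrix(0, k, k)
  for (i in seq_len(k)) {
    xs <- c(expr$X1[i, ], expr$X2[i, ])
    for (j in seq_len(k)) {
      vals <- vapply(xs, oracle_conditional_t, numeric(1),
                     i = i, j = j, st = st, s0 = s0)
      M[i, j] <- mean(vals) - if (center) tmarg[j] else 0
    }
  }
  E <- (M + t(M)) / 2
  diag(E) <- 0
  dimnames(E) <- list(expr$gene_ids, expr$gene_ids)
  E
}

# clique number by brute force over all vertex subsets (k <= 16)
oracle_clique_number <- function(A) {
  k <- nrow(A)
  best <- 1L
  for (code in seq_len(2^k - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    m <- length(idx)
    if (m <= best) next
    sub <- A[idx, idx, drop = FALSE]
    if (all(sub[upper.tri(sub)] == 1)) best <- m
  }
  best
}

# Euclidean projection onto the simplex by active-set enumeration
# (k <= 12): for each candidate support S, x_S = y_S + (1 - sum y_S)/|S|;
# keep feasible candidates, return the one nearest to y.
oracle_project_simplex <- function(y) {
  k <- length(y)
  best <- NULL
  best_d <- Inf
  for (code in seq_len(2^k - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    x <- numeric(k)
    x[S] <- y[S] + (1 - sum(y[S])) / length(S)
    if (any(x[S] < -1e-12)) next
    x[x < 0] <- 0
    d <- sum((x - y)^2)
    if (d < best_d - 1e-15) {
      best_d <- d
      best <- x
    }
  }
  best
}

# all points of the simplex grid at resolution 1/steps (compositions)
oracle_simplex_grid <- function(k, steps = 10) {
  compose <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    out <- NULL
    for (first in 0:total) {
      rest <- compose(total - first, parts - 1)
      out <- rbind(out, cbind(first, rest))
    }
    out
  }
  compose(steps, k) / steps
}

# random undirected graph adjacency on k nodes
random_adjacency <- function(k, p) {
  A <- matrix(0, k, k)
  A[upper.tri(A)] <- rbinom(k * (k - 1) / 2, 1, p)
  A + t(A)
}

# small simulated study used across tests
scaled_study <- function(seed, k = 300, n_sig = 60) {
  simulate_study(simulation_config(k = k, n = 50, n_sig = n_sig,
                                   a = 0.5, b = 0.8, seed = seed))
}
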