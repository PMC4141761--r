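#' Per-gene, per-condition summary statistics
#'
#' Computes the sample means, standard deviations and within-condition
#' Pearson correlation matrices that every downstream score is built from,
#' together with the mixture weights `p1 = n1/(n1+n2)` and
#' `p2 = n2/(n1+n2)` of the two-condition sampling mixture.
#'
#' Genes that are constant within a condition get correlation 0 with every
#' partner in that condition (recorded in `constant1`/`constant2`) rather
#' than raising an error.
#'
#' @param expr A [conditioned_expression()] object.
#' @return A `gene_stats` object: list with `mu1`, `mu2`, `sd1`, `sd2`
#'   (length-k vectors), `rho1`, `rho2` (k x k correlation matrices),
#'   `n1`, `n2`, `p1`, `p2`, `constant1`, `constant2` (logical flags) and
#'   `gene_ids`.
#' @export
summarize_conditions <- function(expr) {
  stopifnot(inherits(expr, "conditioned_expression"))
  k <- length(expr$gene_ids)
  n1 <- ncol(expr$X1)
  n2 <- ncol(expr$X2)
  mu1 <- rowMeans(expr$X1)
  mu2 <- rowMeans(expr$X2)
  sd1 <- apply(expr$X1, 1L, stats::sd)
  sd2 <- apply(expr$X2, 1L, stats::sd)
  constant1 <- sd1 == 0
  constant2 <- sd2 == 0
  rho1 <- condition_cor(expr$X1, constant1)
  rho2 <- condition_cor(expr$X2, constant2)
  structure(
    list(
      gene_ids = expr$gene_ids,
      mu1 = mu1, mu2 = mu2, sd1 = sd1, sd2 = sd2,
      rho1 = rho1, rho2 = rho2,
      n1 = n1, n2 = n2,
      p1 = n1 / (n1 + n2), p2 = n2 / (n1 + n2),
      constant1 = constant1, constant2 = constant2
    ),
    class = "gene_stats"
  )
}

condition_cor <- function(X, constant) {
  rho <- suppressWarnings(stats::cor(t(X)))
  rho[constant, ] <- 0
  rho[, constant] <- 0
  diag(rho) <- 1
  rho[!is.finite(rho)] <- 0
  rho
}

#' @export
print.gene_stats <- function(x, ...) {
  cat("<gene_stats> ", length(x$gene_ids), " genes; n1 = ", x$n1,
      ", n2 = ", x$n2, "\n", sep = "")
  invisible(x)
}

# SAM-style pooled two-sample scale of the mean difference:
# s_i = sqrt((1/n1 + 1/n2) * ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))
pooled_scale <- function(sd1, sd2, n1, n2) {
  sqrt((1 / n1 + 1 / n2) *
         ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Estimate the fudge factor s0 of the moderated T-statistic
#'
#' The offset `s0` added to the denominator of the moderated T-statistic is
#' chosen, SAM-style, to minimize the coefficient of variation of the
#' statistic's spread across genes: candidate values are quantiles of the
#' per-gene pooled scale `s_i`; for each candidate the genes are split into
#' decile windows of `s_i`, the median absolute deviation of T is computed
#' within each window, and the candidate minimizing the coefficient of
#' variation of those MADs wins. Deterministic given the input.
#'
#' @param expr A [conditioned_expression()] object with at least 20 genes.
#' @param quantiles Candidate grid of quantiles of the `s_i` distribution,
#'   each in `[0, 1]`.
#' @param n_windows Number of `s_i`-percentile windows used for the spread
#'   estimate.
#' @return The selected `s0` (a non-negative scalar, an element of the
#'   candidate grid).
#' @export
estimate_s0 <- function(expr, quantiles = seq(0, 1, by = 0.05),
                        n_windows = 10L) {
  stopifnot(inherits(expr, "conditioned_expression"))
  if (any(quantiles < 0 | quantiles > 1)) {
    stop("quantile grid must lie in [0, 1]", call. = FALSE)
  }
  stats <- summarize_conditions(expr)
  k <- length(stats$gene_ids)
  if (k < 20L) stop("s0 estimation needs at least 20 genes", call. = FALSE)
  s <- pooled_scale(stats$sd1, stats$sd2, stats$n1, stats$n2)
  if (all(s == 0)) {
    stop("all pooled scales are zero; s0 cannot be estimated", call. = FALSE)
  }
  diff <- stats$mu2 - stats$mu1
  candidates <- unname(stats::quantile(s, probs = quantiles, type = 7))
  windows <- cut(rank(s, ties.method = "first"),
                 breaks = n_windows, labels = FALSE)
  cv_of <- function(s0) {
    t <- diff / (s + s0)
    mads <- vapply(split(t, windows), stats::mad, numeric(1))
    m <- mean(mads)
    if (m == 0) return(Inf)
    stats::sd(mads) / m
  }
  cvs <- vapply(candidates, cv_of, numeric(1))
  # ties resolved toward the smallest candidate for determinism
  candidates[which.min(cvs)]
}

#' Moderated T-statistics for every gene
#'
#' The node score of the background network: the two-sample mean difference
#' (condition 2 minus condition 1) over a SAM-style pooled scale plus the
#' fudge factor `s0`. Large positive values mean up-regulation in condition
#' 2, large negative values down-regulation.
#'
#' @param stats A `gene_stats` object from [summarize_conditions()].
#' @param s0 Non-negative fudge factor (see [estimate_s0()]).
#' @return A tibble with columns `gene_id` and `t`.
#' @export
node_scores <- function(stats, s0 = 0) {
  stopifnot(inherits(stats, "gene_stats"), s0 >= 0)
  s <- pooled_scale(stats$sd1, stats$sd2, stats$n1, stats$n2)
  denom <- s + s0
  num <- stats$mu2 - stats$mu1
  t <- ifelse(denom > 0, num / denom,
              ifelse(num == 0, 0, num / .Machine$double.eps))
  t[!is.finite(t)] <- 0
  tibble::tibble(gene_id = stats$gene_ids, t = unname(t))
}

# clamp correlations away from +/-1 so conditional variances stay positive
clamp_rho <- function(rho, eps = 1e-8) {
  pmin(pmax(rho, -1 + eps), 1 - eps)
}

#' Conditional T-statistic of gene j given gene i
#'
#' Under a per-condition bivariate-normal model, the conditional
#' distribution of gene `j` given that gene `i` takes the value `x` has
#' mean `mu_j + rho * (sd_j / sd_i) * (x - mu_i)` and standard deviation
#' `sd_j * sqrt(1 - rho^2)`. Substituting these conditional moments of each
#' condition into the moderated T formula gives the conditional T-statistic
#' `T_{j|i}(x)`, the building block of the differential co-expression edge
#' score.
#'
#' If gene `i` is constant in a condition its correlation is treated as 0
#' there, so the conditional moments fall back to the marginal ones.
#'
#' @param x Scalar (or vector of) value(s) of gene `i` to condition on.
#' @param i,j Gene indices (positions in `stats$gene_ids`).
#' @param stats A `gene_stats` object.
#' @param s0 Fudge factor, the same one used for node scores.
#' @return `T_{j|i}(x)`, same length as `x`.
#' @export
conditional_t <- function(x, i, j, stats, s0 = 0) {
  stopifnot(inherits(stats, "gene_stats"))
  r1 <- if (stats$constant1[i]) 0 else clamp_rho(stats$rho1[i, j])
  r2 <- if (stats$constant2[i]) 0 else clamp_rho(stats$rho2[i, j])
  slope1 <- if (stats$sd1[i] > 0) r1 * stats$sd1[j] / stats$sd1[i] else 0
  slope2 <- if (stats$sd2[i] > 0) r2 * stats$sd2[j] / stats$sd2[i] else 0
  m1 <- stats$mu1[j] + slope1 * (x - stats$mu1[i])
  m2 <- stats$mu2[j] + slope2 * (x - stats$mu2[i])
  v1 <- stats$sd1[j] * sqrt(1 - r1^2)
  v2 <- stats$sd2[j] * sqrt(1 - r2^2)
  s <- pooled_scale(v1, v2, stats$n1, stats$n2)
  denom <- s + s0
  num <- m2 - m1
  if (denom > 0) num / denom else ifelse(num == 0, 0, num / .Machine$double.eps)
}

#' Differential co-expression edge scores
#'
#' The edge score of a gene pair contrasts the conditional T-statistic
#' `T_{j|i}(x)` with the marginal node score `T_j`: it is the expectation,
#' over the two-condition mixture density of gene `i`, of
#' `T_{j|i}(x) - T_j`, computed numerically as the empirical average over
#' all `n1 + n2` observed samples of gene `i` (pooling the samples
#' realizes the mixture weights `p1`, `p2` automatically). Centering at
#' the marginal makes the score a pure co-expression-change measure: when
#' conditioning on gene `i` tells nothing about gene `j` (zero correlation
#' in both conditions) the conditional statistic equals the marginal one
#' and the edge score vanishes, so a differentially expressed gene does
#' not bleed its node signal into every incident edge. Because
#' conditioning is not symmetric, the matrix is symmetrized by averaging
#' the two directions; the diagonal is forced to zero.
#'
#' `center = FALSE` gives the uncentered expectation of `T_{j|i}` itself.
#'
#' @param expr A [conditioned_expression()] object.
#' @param stats Matching `gene_stats`; computed if missing.
#' @param s0 Fudge factor shared with [node_scores()].
#' @param center Subtract the marginal node score inside the expectation
#'   (default `TRUE`).
#' @return A symmetric k x k numeric matrix with zero diagonal, dimnames
#'   the gene IDs.
#' @export
edge_scores <- function(expr, stats = summarize_conditions(expr), s0 = 0,
                        center = TRUE) {
  stopifnot(inherits(expr, "conditioned_expression"),
            inherits(stats, "gene_stats"))
  k <- length(stats$gene_ids)
  n1 <- stats$n1
  n2 <- stats$n2
  # T_{j|i}(x) is affine in x for fixed (i, j), so its empirical average
  # over the pooled samples equals the statistic evaluated at the pooled
  # sample mean of gene i (verified against the per-sample loop in tests).
  xbar <- (rowSums(expr$X1) + rowSums(expr$X2)) / (n1 + n2)
  rho1 <- clamp_rho(stats$rho1)
  rho2 <- clamp_rho(stats$rho2)
  rho1[stats$constant1, ] <- 0
  rho2[stats$constant2, ] <- 0
  M <- matrix(0, k, k)
  for (i in seq_len(k)) {
    slope1 <- if (stats$sd1[i] > 0) rho1[i, ] * stats$sd1 / stats$sd1[i] else
      numeric(k)
    slope2 <- if (stats$sd2[i] > 0) rho2[i, ] * stats$sd2 / stats$sd2[i] else
      numeric(k)
    m1 <- stats$mu1 + slope1 * (xbar[i] - stats$mu1[i])
    m2 <- stats$mu2 + slope2 * (xbar[i] - stats$mu2[i])
    v1 <- stats$sd1 * sqrt(1 - rho1[i, ]^2)
    v2 <- stats$sd2 * sqrt(1 - rho2[i, ]^2)
    s <- pooled_scale(v1, v2, n1, n2)
    denom <- s + s0
    num <- m2 - m1
    ti <- ifelse(denom > 0, num / denom,
                 ifelse(num == 0, 0, num / .Machine$double.eps))
    M[i, ] <- ti   # row i holds E[T_{j|i}] over samples of gene i
  }
  if (center) {
    tmarg <- node_scores(stats, s0 = s0)$t
    M <- sweep(M, 2L, tmarg, "-")  # E[T_{j|i} - T_j]
  }
  E <- (M + t(M)) / 2
  diag(E) <- 0
  E[!is.finite(E)] <- 0
  dimnames(E) <- list(stats$gene_ids, stats$gene_ids)
  E
}

#' Sparsify edge and node scores with hard thresholds
#'
#' Converts scores to absolute values and zeroes the weak ones so that
#' non-significant genes and pairs cannot tilt the continuous objective
#' toward local maxima. The default rule keeps an entry when it is at least
#' the mean of the positive absolute entries (edges) or the mean absolute
#' node score (nodes); ties with the threshold survive. Thresholds are
#' computed once from the input, so the surviving pattern is monotone.
#'
#' With `binarize = TRUE` (the default) surviving entries are set to 1:
#' the hard threshold reduces the weighted background network to its
#' strong-edge skeleton, the unweighted graph on which the maximum-clique
#' relaxation operates in its classical form. A uniformly scored planted
#' module then enters the objective as a quasi-clique of unit weights
#' rather than as a block of noisy magnitudes, which is what lets the
#' simplex maximizer spread over the whole module instead of collapsing
#' onto its few highest-scoring members. `binarize = FALSE` keeps the
#' absolute scores of the survivors.
#'
#' @param E Edge score matrix (any signs; absolute values are taken).
#' @param t Node scores: the tibble from [node_scores()] or a bare numeric
#'   vector.
#' @param threshold_mode `"mean"` (default) or `"half_max"`, an alternative
#'   rule thresholding at half the maximum absolute score.
#' @param binarize Replace surviving entries by 1 (default `TRUE`).
#' @return A list with elements `E` (thresholded edge matrix) and
#'   `t` (tibble with columns `gene_id`, `t` of thresholded node
#'   scores), plus the two thresholds. Inputs are not modified.
#' @export
apply_hard_thresholds <- function(E, t, threshold_mode = c("mean", "half_max"),
                                  binarize = TRUE) {
  threshold_mode <- match.arg(threshold_mode)
  tvec <- if (is.data.frame(t)) t$t else as.numeric(t)
  ids <- if (is.data.frame(t)) t$gene_id else rownames(E)
  if (is.null(ids)) ids <- paste0("g", seq_along(tvec))
  absE <- abs(E)
  diag(absE) <- 0
  abst <- abs(tvec)
  pos <- absE[upper.tri(absE)]
  pos <- pos[pos > 0]
  thr_e <- switch(threshold_mode,
                  mean = if (length(pos)) mean(pos) else 0,
                  half_max = max(absE) / 2)
  thr_t <- switch(threshold_mode,
                  mean = mean(abst),
                  half_max = max(abst) / 2)
  absE[absE < thr_e] <- 0
  abst[abst < thr_t] <- 0
  if (binarize) {
    absE <- (absE > 0) * 1
    abst <- (abst > 0) * 1
  }
  list(
    E = absE,
    t = tibble::tibble(gene_id = ids, t = abst),
    threshold_edge = thr_e,
    threshold_node = thr_t
  )
}
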