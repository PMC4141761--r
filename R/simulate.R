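#' Configuration of a planted-module simulation study
#'
#' Describes a two-condition multivariate-normal study with a planted
#' module: a reference data set and a case data set share per-gene
#' baseline means (uniform on `mean_range`) and standard deviations
#' (uniform on `sd_range`), and a mildly correlated baseline correlation
#' structure from a random low-rank factor model. In the case condition
#' the `n_sig` planted ("significant") genes get a mean shift `a` and
#' pairwise correlation raised to `b`.
#'
#' The default sizes mirror the benchmark design this module emulates:
#' 1,000 genes, 50 samples per condition, 200 planted genes, baseline
#' means on `[-0.5, 0.5]`. Baseline SDs are drawn from `[0.05, 0.5]`
#' (positivity enforced). Effect presets `weak`, `medium`, `strong`
#' correspond to `(a, b)` of (0.2, 0.5), (0.35, 0.65), (0.5, 0.8).
#'
#' @param k Number of genes.
#' @param n Samples per condition.
#' @param n_sig Number of planted genes (`0 < n_sig <= k`).
#' @param a Mean shift added to planted-gene means in the case condition.
#' @param b Pairwise correlation imposed among planted genes, in `[0, 1)`.
#' @param mean_range,sd_range Baseline ranges (length-2 numeric).
#' @param n_factors Factors of the baseline correlation model.
#' @param seed Integer seed.
#' @param preset `"weak"`, `"medium"` or `"strong"`; overrides `a`, `b`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(k = 1000L, n = 50L, n_sig = 200L, a = 0.5,
                              b = 0.8, mean_range = c(-0.5, 0.5),
                              sd_range = c(0.05, 0.5), n_factors = 5L,
                              seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("weak", "medium", "strong"))
    ab <- switch(preset, weak = c(0.2, 0.5), medium = c(0.35, 0.65),
                 strong = c(0.5, 0.8))
    a <- ab[1]
    b <- ab[2]
  }
  stopifnot(k >= 2, n >= 2, n_sig > 0, n_sig <= k, b >= 0, b < 1,
            length(mean_range) == 2L, length(sd_range) == 2L,
            all(sd_range > 0), n_factors >= 1)
  structure(
    list(k = as.integer(k), n = as.integer(n), n_sig = as.integer(n_sig),
         a = a, b = b, mean_range = mean_range, sd_range = sd_range,
         n_factors = as.integer(n_factors), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# nearest-PD repair: clip eigenvalues at `floor`, rescale to unit diagonal
repair_correlation <- function(R, floor = 1e-6) {
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < floor) {
    vals <- pmax(ev$values, floor)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
  }
  diag(R) <- 1
  (R + t(R)) / 2
}

# draw n samples (columns) from N(mu, diag(sd) R diag(sd)) via Cholesky
rmvn <- function(n, mu, sd, R) {
  k <- length(mu)
  L <- chol(R)  # upper triangular: R = t(L) %*% L
  Z <- matrix(stats::rnorm(k * n), nrow = k)
  X <- crossprod(L, Z) * sd + mu
  X
}

#' Simulate a planted-module two-condition study
#'
#' Draws the reference and case data sets described by a
#' [simulation_config()]. Both conditions share the baseline means,
#' standard deviations and factor-model correlation structure; the case
#' condition shifts the planted genes' means by `a` and sets their
#' pairwise correlations to `b`. The modified correlation matrix is
#' repaired to the nearest positive-definite correlation matrix
#' (eigenvalue clipping at 1e-6, rescaled to unit diagonal) before
#' sampling. Deterministic per seed.
#'
#' @param cfg A [simulation_config()].
#' @return A `simulated_study` object: list with `expr` (a
#'   [conditioned_expression()], condition 1 = reference, condition 2 =
#'   case), `truth` (character vector of planted gene IDs),
#'   `truth_idx` (their indices) and `config`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_preserved_seed(cfg$seed, {
    k <- cfg$k
    ids <- sprintf("g%04d", seq_len(k))
    mu <- stats::runif(k, cfg$mean_range[1], cfg$mean_range[2])
    sd <- stats::runif(k, cfg$sd_range[1], cfg$sd_range[2])
    U <- matrix(stats::runif(k * cfg$n_factors, -0.3, 0.3), nrow = k)
    R0 <- tcrossprod(U)
    diag(R0) <- 1
    R0 <- repair_correlation(R0)
    sig <- sort(sample.int(k, cfg$n_sig))
    R1 <- R0
    R1[sig, sig] <- cfg$b
    diag(R1) <- 1
    R1 <- repair_correlation(R1)
    mu_case <- mu
    mu_case[sig] <- mu_case[sig] + cfg$a
    X_ref <- rmvn(cfg$n, mu, sd, R0)
    X_case <- rmvn(cfg$n, mu_case, sd, R1)
    rownames(X_ref) <- ids
    rownames(X_case) <- ids
    colnames(X_ref) <- sprintf("ref%02d", seq_len(cfg$n))
    colnames(X_case) <- sprintf("case%02d", seq_len(cfg$n))
    structure(
      list(
        expr = conditioned_expression(X_ref, X_case),
        truth = ids[sig],
        truth_idx = sig,
        config = cfg
      ),
      class = "simulated_study"
    )
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> ", x$config$k, " genes x ", x$config$n,
      " + ", x$config$n, " samples; ", length(x$truth),
      " planted genes (a = ", x$config$a, ", b = ", x$config$b, ")\n",
      sep = "")
  invisible(x)
}

#' Recovery metrics of a selected gene set against the planted truth
#'
#' Standard confusion counts and ratios: recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, F-measure `2PR/(P+R)`. An empty selection has undefined
#' precision, reported as 0 with `empty_selection = TRUE`.
#'
#' @param selected Character vector (or set) of selected gene IDs.
#' @param truth Character vector of planted gene IDs.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `subnetwork_size`,
#'   `recall`, `precision`, `f_measure`, `empty_selection`.
#' @export
#' @examples
#' evaluate_selection(c("a", "b", "c"), c("a", "b", "d"))
evaluate_selection <- function(selected, truth) {
  selected <- unique(as.character(selected))
  truth <- unique(as.character(truth))
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  fn <- length(setdiff(truth, selected))
  empty <- length(selected) == 0L
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (!empty) tp / (tp + fp) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, subnetwork_size = tp + fp,
    recall = recall, precision = precision, f_measure = f,
    empty_selection = empty
  )
}

#' Fold enrichment of a selection in a reference gene set
#'
#' The over-representation of known reference (e.g. disease) genes in a
#' selection: `(recovered / selected) / (reference / universe)`.
#'
#' @param n_recovered Reference genes recovered by the selection.
#' @param n_selected Size of the selection (>= 1).
#' @param n_reference Reference genes present in the universe (>= 1).
#' @param n_universe All genes in the network.
#' @return The fold-enrichment scalar.
#' @export
#' @examples
#' fold_enrichment(57, 643, 315, 8721)  # ~2.454
fold_enrichment <- function(n_recovered, n_selected, n_reference,
                            n_universe) {
  if (n_selected < 1 || n_reference < 1 || n_universe < 1) {
    stop("counts must be positive", call. = FALSE)
  }
  if (n_universe < max(n_selected, n_reference)) {
    stop("universe smaller than the sets it contains", call. = FALSE)
  }
  (n_recovered / n_selected) / (n_reference / n_universe)
}
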