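#' Undirected protein-protein interaction network
#'
#' Stores an undirected edge list in canonical form: IDs are stripped of
#' surrounding whitespace and matched case-sensitively, each pair is stored
#' with `from < to`, duplicate edges are collapsed and self-interactions
#' removed (with a message giving the count).
#'
#' @param from,to Character vectors of interacting gene IDs, or `from` may
#'   be a two-column data frame.
#' @return A `ppi_network` object: a tibble with columns `from`, `to`.
#' @export
ppi_network <- function(from, to = NULL) {
  if (is.data.frame(from)) {
    stopifnot(ncol(from) >= 2L)
    to <- as.character(from[[2]])
    from <- as.character(from[[1]])
  }
  from <- trimws(as.character(from))
  to <- trimws(as.character(to))
  stopifnot(length(from) == length(to))
  self <- from == to
  if (any(self)) {
    message(sum(self), " self-interaction(s) removed")
    from <- from[!self]
    to <- to[!self]
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  edges <- dplyr::distinct(tibble::tibble(from = a, to = b))
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(edges, class = c("ppi_network", class(tibble::tibble())))
}

#' Read a PPI edge list from a two-column TSV file
#'
#' A header row is detected and skipped when its first field matches common
#' header words (or when `header = TRUE` is forced).
#'
#' @param path Path to a tab-separated two-column edge list.
#' @param header `NA` (auto-detect), `TRUE` or `FALSE`.
#' @return A [ppi_network()] object.
#' @export
read_ppi <- function(path, header = NA) {
  df <- readr::read_tsv(path, col_names = FALSE, col_types = "cc",
                        progress = FALSE)
  if (is.na(header)) {
    first <- tolower(trimws(unlist(df[1, ])))
    header <- any(first %in% c("from", "to", "gene1", "gene2", "source",
                               "target", "genea", "geneb"))
  }
  if (isTRUE(header)) df <- df[-1, , drop = FALSE]
  ppi_network(df[[1]], df[[2]])
}

#' Distance-based T-scores for PPI interactions
#'
#' For each interacting pair the score contrasts the per-sample RMS
#' (root-mean-square) Euclidean distance between the two genes' expression
#' vectors in the case condition with the same distance in the reference
#' condition, scaled by the geometric averages of the two genes' standard
#' deviations in each condition plus the fudge factor:
#' `DBT_ij = (d_C - d_N) / (g_N + g_C + s0)` with
#' `g_N = sqrt(sd1_i * sd1_j)`, `g_C = sqrt(sd2_i * sd2_j)`. Dividing each
#' Euclidean distance by the square root of the sample count makes the two
#' conditions comparable when `n1 != n2`. Interactions activated or lost in
#' the case condition get large absolute scores; pairs whose distance is
#' unchanged score near zero.
#'
#' PPI genes absent from the expression data are dropped (a warning reports
#' the count of dropped edges).
#'
#' @param expr A [conditioned_expression()] object.
#' @param stats Matching `gene_stats`; computed if missing.
#' @param ppi A [ppi_network()].
#' @param s0 Fudge factor shared with the expression scores.
#' @return A `dbt_matrix` object: list with `dbt` (sparse symmetric k x k
#'   [Matrix::sparseMatrix()], nonzero only on retained PPI pairs), `deg`
#'   (weighted degree, `deg_i = sum_j |dbt_ij|`), `gene_ids`,
#'   `n_edges_used`, `n_edges_dropped`.
#' @export
dbt_scores <- function(expr, stats = summarize_conditions(expr), ppi,
                       s0 = 0) {
  stopifnot(inherits(expr, "conditioned_expression"),
            inherits(ppi, "ppi_network"))
  ids <- expr$gene_ids
  idx <- stats::setNames(seq_along(ids), ids)
  keep <- ppi$from %in% ids & ppi$to %in% ids
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    warning(n_dropped, " PPI edge(s) dropped: gene absent from expression data",
            call. = FALSE)
  }
  edges <- ppi[keep, , drop = FALSE]
  k <- length(ids)
  n1 <- ncol(expr$X1)
  n2 <- ncol(expr$X2)
  i <- idx[edges$from]
  j <- idx[edges$to]
  if (nrow(edges) > 0L) {
    dN <- sqrt(rowSums((expr$X1[i, , drop = FALSE] -
                          expr$X1[j, , drop = FALSE])^2) / n1)
    dC <- sqrt(rowSums((expr$X2[i, , drop = FALSE] -
                          expr$X2[j, , drop = FALSE])^2) / n2)
    gN <- sqrt(stats$sd1[i] * stats$sd1[j])
    gC <- sqrt(stats$sd2[i] * stats$sd2[j])
    denom <- gN + gC + s0
    val <- ifelse(denom > 0, (dC - dN) / denom, 0)
  } else {
    val <- numeric(0)
  }
  dbt <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = c(val, val),
    dims = c(k, k), dimnames = list(ids, ids)
  )
  structure(
    list(
      dbt = dbt,
      deg = stats::setNames(Matrix::rowSums(abs(dbt)), ids),
      gene_ids = ids,
      n_edges_used = nrow(edges),
      n_edges_dropped = n_dropped
    ),
    class = "dbt_matrix"
  )
}

#' Construct a background network from explicit weights
#'
#' The weight parameters of the sub-network objective: a symmetric
#' edge-weight matrix `W` with zero diagonal and a node-weight vector `f`.
#' Normally produced by [combine_networks()] (optionally followed by
#' [apply_hard_thresholds()]); this constructor is for assembling one
#' directly, e.g. from a known adjacency matrix.
#'
#' @param W Symmetric numeric matrix, zero diagonal, finite.
#' @param f Numeric vector, one weight per gene.
#' @param gene_ids Gene identifiers; defaults to `rownames(W)` or
#'   `g1...gk`.
#' @param beta1,beta2 Effective PPI scaling coefficients (bookkeeping).
#' @param user_scale1,user_scale2 User-chosen multipliers (bookkeeping).
#' @return A `background_network` object.
#' @export
background_network <- function(W, f, gene_ids = NULL, beta1 = 0, beta2 = 0,
                               user_scale1 = 1, user_scale2 = 1) {
  W <- as.matrix(W)
  f <- as.numeric(f)
  k <- length(f)
  stopifnot(nrow(W) == k, ncol(W) == k, all(is.finite(W)), all(is.finite(f)))
  if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric", call. = FALSE)
  if (any(diag(W) != 0)) stop("W must have a zero diagonal", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- rownames(W)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(k))
  gene_ids <- as.character(gene_ids)
  stopifnot(length(gene_ids) == k)
  dimnames(W) <- list(gene_ids, gene_ids)
  structure(
    list(W = W, f = stats::setNames(f, gene_ids), gene_ids = gene_ids,
         beta1 = beta1, beta2 = beta2,
         user_scale1 = user_scale1, user_scale2 = user_scale2),
    class = "background_network"
  )
}

#' Fuse expression scores and PPI scores into the background network
#'
#' Builds the weight parameters of the sub-network objective:
#' `W_ij = |E_ij| + beta1 * |DBT_ij|` and `f_i = |T_i| + beta2 * deg_i`,
#' where `beta1 = user_scale1 * max|E| / max|DBT|` and
#' `beta2 = user_scale2 * max|T| / max(deg)`, so that at `user_scale = 1`
#' the PPI term's largest entry matches the expression term's largest
#' entry. With `dbt = NULL` (expression-only mode) `W = |E|`, `f = |T|`.
#'
#' @param E Edge score matrix (possibly already thresholded).
#' @param t Node scores: tibble from [node_scores()] or numeric vector.
#' @param dbt A `dbt_matrix` from [dbt_scores()], or `NULL`.
#' @param user_scale1,user_scale2 Non-negative multipliers applied on top
#'   of the max-normalization; 0 removes the PPI contribution.
#' @return A `background_network` object: list with dense `W` (symmetric,
#'   non-negative, zero diagonal), `f` (non-negative), `gene_ids`, the
#'   effective `beta1`, `beta2` and the user scales.
#' @export
combine_networks <- function(E, t, dbt = NULL, user_scale1 = 1,
                             user_scale2 = 1) {
  stopifnot(user_scale1 >= 0, user_scale2 >= 0)
  tvec <- if (is.data.frame(t)) t$t else as.numeric(t)
  ids <- if (is.data.frame(t)) t$gene_id else rownames(E)
  W <- abs(E)
  diag(W) <- 0
  f <- abs(tvec)
  beta1 <- beta2 <- 0
  if (!is.null(dbt)) {
    stopifnot(inherits(dbt, "dbt_matrix"))
    if (!identical(as.character(dbt$gene_ids), as.character(ids))) {
      stop("gene sets/order of scores and DBT matrix differ", call. = FALSE)
    }
    max_dbt <- max(abs(dbt$dbt))
    if (max_dbt == 0) {
      if (dbt$n_edges_used > 0L) {
        warning("all DBT scores are zero; PPI contribution disabled",
                call. = FALSE)
      }
    } else {
      beta1 <- user_scale1 * max(W) / max_dbt
      W <- W + beta1 * abs(as.matrix(dbt$dbt))
    }
    max_deg <- max(dbt$deg)
    if (max_deg > 0) {
      beta2 <- user_scale2 * max(f) / max_deg
      f <- f + beta2 * dbt$deg
    }
  }
  background_network(W, f, gene_ids = ids, beta1 = beta1, beta2 = beta2,
                     user_scale1 = user_scale1, user_scale2 = user_scale2)
}

#' @export
print.background_network <- function(x, ...) {
  cat("<background_network> ", length(x$gene_ids), " genes; ",
      sum(x$W[upper.tri(x$W)] > 0), " positive edges; beta1 = ",
      signif(x$beta1, 4), ", beta2 = ", signif(x$beta2, 4), "\n", sep = "")
  invisible(x)
}

#' Sparsity of a PPI network over a gene universe
#'
#' The percentage of gene pairs that interact:
#' `100 * |edges| / (k * (k - 1) / 2)`.
#'
#' @param ppi A [ppi_network()] or a bare edge count.
#' @param k Number of genes in the universe (at least 2).
#' @return The sparsity percentage.
#' @export
#' @examples
#' ppi_sparsity(33771, 8721)  # ~0.0888
ppi_sparsity <- function(ppi, k) {
  if (k < 2) stop("need at least 2 genes", call. = FALSE)
  m <- if (inherits(ppi, "ppi_network") || is.data.frame(ppi)) nrow(ppi)
       else as.numeric(ppi)
  100 * m / (k * (k - 1) / 2)
}

#' Randomly degrade a PPI network while preserving edge count
#'
#' Removes a fraction of the existing edges uniformly at random and adds
#' the same number of uniformly chosen absent (non-self) pairs over the
#' network's node set, emulating a lower-quality interactome for
#' robustness studies.
#'
#' @param ppi A [ppi_network()].
#' @param fraction Fraction of edges to rewire, in (0, 1); at least one
#'   edge must be affected.
#' @param seed Integer seed for reproducibility.
#' @return A [ppi_network()] with the same number of edges.
#' @export
rewire_ppi <- function(ppi, fraction, seed = NULL) {
  stopifnot(inherits(ppi, "ppi_network"), fraction > 0, fraction < 1)
  m <- nrow(ppi)
  n_move <- round(fraction * m)
  if (n_move < 1L) stop("fraction too small: no edge would be rewired",
                        call. = FALSE)
  nodes <- sort(unique(c(ppi$from, ppi$to)))
  k <- length(nodes)
  if (k * (k - 1) / 2 - m < n_move) {
    stop("network too dense: not enough absent pairs to add", call. = FALSE)
  }
  with_preserved_seed(seed, {
    drop_idx <- sample.int(m, n_move)
    kept <- ppi[-drop_idx, , drop = FALSE]
    existing <- paste(ppi$from, ppi$to, sep = "\r")
    new_from <- character(0)
    new_to <- character(0)
    guard <- 0L
    while (length(new_from) < n_move) {
      need <- n_move - length(new_from)
      a <- nodes[sample.int(k, 2L * need, replace = TRUE)]
      b <- nodes[sample.int(k, 2L * need, replace = TRUE)]
      ok <- a != b
      lo <- pmin(a[ok], b[ok])
      hi <- pmax(a[ok], b[ok])
      key <- paste(lo, hi, sep = "\r")
      fresh <- !(key %in% existing) & !duplicated(key)
      lo <- lo[fresh]
      hi <- hi[fresh]
      key <- key[fresh]
      take <- seq_len(min(need, length(lo)))
      new_from <- c(new_from, lo[take])
      new_to <- c(new_to, hi[take])
      existing <- c(existing, key[take])
      guard <- guard + 1L
      if (guard > 10000L) stop("failed to sample absent pairs", call. = FALSE)
    }
    ppi_network(c(kept$from, new_from), c(kept$to, new_to))
  })
}

# evaluate `code` under `seed` without disturbing the caller's RNG state
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
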