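#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-gene results of a sub-network run
#'
#' @param x A `wmaxc_result` from [wmaxc()].
#' @param ... Unused.
#' @return A tibble with one row per gene: `gene_id`, `contribution`
#'   (0 for unselected genes), `node_score` (signed moderated T),
#'   `weighted_degree` (0 in expression-only mode), `selected`; sorted by
#'   contribution descending.
#' @export
tidy.wmaxc_result <- function(x, ...) {
  contrib <- x$fit$x_star
  out <- tibble::tibble(
    gene_id = x$net$gene_ids,
    contribution = unname(contrib),
    node_score = x$node_scores$t,
    weighted_degree = unname(x$weighted_degree),
    selected = x$net$gene_ids %in% x$subnetwork$genes$gene_id
  )
  dplyr::arrange(out, dplyr::desc(.data$contribution), .data$gene_id)
}

#' One-row summary of a sub-network run
#'
#' @param x A `wmaxc_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_selected`, `n_edges`,
#'   `objective`, `lambda`, `s0`, `beta1`, `beta2`, `converged`,
#'   `generations`, `mode`, `seed`.
#' @export
glance.wmaxc_result <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$net$gene_ids),
    n_selected = nrow(x$subnetwork$genes),
    n_edges = nrow(x$subnetwork$edges),
    objective = x$fit$objective_value,
    lambda = x$lambda,
    s0 = x$s0,
    beta1 = x$net$beta1,
    beta2 = x$net$beta2,
    converged = x$fit$converged,
    generations = x$fit$generations_run,
    mode = x$mode,
    seed = x$seed
  )
}

#' Tidy a genetic-algorithm trace
#'
#' @param x A `wmaxc_fit` from [ga_maximize()].
#' @param ... Unused.
#' @return The trace tibble: `generation`, `best_objective`,
#'   `population_variance`.
#' @export
tidy.wmaxc_fit <- function(x, ...) x$ga_trace

#' @rdname tidy.wmaxc_fit
#' @export
glance.wmaxc_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective_value,
    lambda = x$lambda_used,
    dual_nu = x$dual_nu,
    support_size = sum(x$x_star > 1e-6),
    converged = x$converged,
    generations = x$generations_run
  )
}

#' Plot a genetic-algorithm convergence trace
#'
#' Best objective per generation (top) and population objective variance
#' on a log scale (bottom).
#'
#' @param object A `wmaxc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wmaxc_fit <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$ga_trace,
                            cols = c("best_objective", "population_variance"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL,
                  title = "GA convergence") +
    ggplot2::theme_minimal()
}

#' Plot the contribution profile of a sub-network run
#'
#' Selected genes' contribution scores, descending; the support threshold
#' is implicit in which genes appear.
#'
#' @param object A `wmaxc_result`.
#' @param top Show at most this many genes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wmaxc_result <- function(object, top = 50, ...) {
  g <- utils::head(object$subnetwork$genes, top)
  g$gene_id <- factor(g$gene_id, levels = rev(g$gene_id))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$contribution, y = .data$gene_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "contribution score", y = NULL,
                  title = "Sub-network gene contributions") +
    ggplot2::theme_minimal()
}
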