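#' Write the results of a sub-network run to a directory
#'
#' Emits four files: `genes.tsv` (ranked gene table: gene, contribution,
#' node score, weighted degree), `subnetwork.sif` (induced edges in SIF
#' format, interaction type `coexp`), `subnetwork.graphml` (the same graph
#' with contribution and weight attributes) and `manifest.yaml` (the run
#' configuration, seed, s0, lambda, beta1/beta2, objective value and
#' convergence flag, sufficient to reproduce the run).
#'
#' @param result A `wmaxc_result` from [wmaxc()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "wmaxc_result"))
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  paths <- c(
    genes = file.path(out_dir, "genes.tsv"),
    sif = file.path(out_dir, "subnetwork.sif"),
    graphml = file.path(out_dir, "subnetwork.graphml"),
    manifest = file.path(out_dir, "manifest.yaml")
  )

  ranked <- dplyr::filter(tidy(result), .data$selected)
  ranked <- dplyr::select(ranked, "gene_id", "contribution", "node_score",
                          "weighted_degree")
  readr::write_tsv(ranked, paths[["genes"]], progress = FALSE)

  edges <- result$subnetwork$edges
  sif <- sprintf("%s\tcoexp\t%s", edges$from, edges$to)
  writeLines(sif, paths[["sif"]])

  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = result$subnetwork$genes
  )
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")

  cfg <- result$fit$config
  manifest <- list(
    mode = result$mode,
    condition_labels = c(reference = "normal", case = "cancer"),
    sign_convention = "case minus reference (condition 2 minus condition 1)",
    seed = result$seed,
    s0 = result$s0,
    lambda = result$lambda,
    beta1 = result$net$beta1,
    beta2 = result$net$beta2,
    user_scale1 = result$net$user_scale1,
    user_scale2 = result$net$user_scale2,
    thresholds = as.list(result$thresholds),
    eps = result$subnetwork$eps,
    objective = result$fit$objective_value,
    converged = result$fit$converged,
    generations_run = result$fit$generations_run,
    ga = cfg[setdiff(names(cfg), "mutation_rate")],
    n_selected = nrow(result$subnetwork$genes),
    n_edges = nrow(result$subnetwork$edges)
  )
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}

#' Write a simulated study in the package's input format
#'
#' Reference and case matrices go to `reference.tsv` and `case.tsv`
#' ([read_expression()]-compatible), the planted gene IDs to
#' `truth_genes.txt`, one per line.
#'
#' @param study A `simulated_study` from [simulate_study()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "simulated_study"))
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  paths <- c(
    reference = file.path(out_dir, "reference.tsv"),
    case = file.path(out_dir, "case.tsv"),
    truth = file.path(out_dir, "truth_genes.txt")
  )
  write_expression(study$expr, paths[["reference"]], paths[["case"]])
  writeLines(study$truth, paths[["truth"]])
  invisible(paths)
}
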