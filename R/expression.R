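#' Paired two-condition expression data
#'
#' Bundles two expression matrices over a shared, identically ordered gene
#' set: `X1` for the reference ("normal") condition and `X2` for the
#' contrasted ("cancer") condition. All downstream scores use the sign
#' convention condition 2 minus condition 1.
#'
#' @param X1,X2 Numeric matrices, genes in rows, samples in columns. Row
#'   names (or `gene_ids`) identify genes; the two matrices must cover the
#'   same genes. Each condition needs at least 2 samples and no missing
#'   values (imputation is the caller's responsibility).
#' @param gene_ids Optional character vector of gene identifiers overriding
#'   row names.
#'
#' @return A `conditioned_expression` object: a list with elements
#'   `gene_ids`, `X1`, `X2`.
#' @export
#' @examples
#' x1 <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
#' x2 <- matrix(rnorm(24), 4, 6, dimnames = list(paste0("g", 1:4), NULL))
#' conditioned_expression(x1, x2)
conditioned_expression <- function(X1, X2, gene_ids = NULL) {
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  if (is.null(gene_ids)) {
    gene_ids <- rownames(X1)
  }
  if (is.null(gene_ids)) {
    stop("gene identifiers required (row names or `gene_ids`)", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene IDs: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(X1) != length(gene_ids) || nrow(X2) != length(gene_ids)) {
    stop("X1 and X2 must have one row per gene ID", call. = FALSE)
  }
  if (!is.null(rownames(X2))) {
    if (!setequal(rownames(X2), gene_ids)) {
      missing <- setdiff(gene_ids, rownames(X2))
      extra <- setdiff(rownames(X2), gene_ids)
      stop("gene sets differ between conditions; missing from condition 2: ",
           paste(utils::head(missing, 5), collapse = ", "),
           "; extra: ", paste(utils::head(extra, 5), collapse = ", "),
           call. = FALSE)
    }
    X2 <- X2[gene_ids, , drop = FALSE]
  }
  rownames(X1) <- gene_ids
  rownames(X2) <- gene_ids
  if (ncol(X1) < 2L || ncol(X2) < 2L) {
    stop("each condition needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(X1) || anyNA(X2) || !all(is.finite(X1)) || !all(is.finite(X2))) {
    stop("expression matrices must be finite with no missing values",
         call. = FALSE)
  }
  structure(
    list(gene_ids = gene_ids, X1 = X1, X2 = X2),
    class = "conditioned_expression"
  )
}

#' @export
print.conditioned_expression <- function(x, ...) {
  cat("<conditioned_expression> ", length(x$gene_ids), " genes; ",
      ncol(x$X1), " + ", ncol(x$X2), " samples (condition 1 + 2)\n", sep = "")
  invisible(x)
}

#' Read two-condition expression matrices from TSV files
#'
#' Each file is a tab-separated matrix with gene IDs in the first column and
#' a header row of sample IDs. Genes present in both files are kept (in the
#' order of the first file); genes missing from either file are dropped with
#' a message. Completely disjoint gene sets are an error.
#'
#' @param path1 Path to the condition-1 (reference/"normal") matrix.
#' @param path2 Path to the condition-2 (case/"cancer") matrix.
#' @return A [conditioned_expression()] object.
#' @export
read_expression <- function(path1, path2) {
  X1 <- read_expression_matrix(path1)
  X2 <- read_expression_matrix(path2)
  shared <- intersect(rownames(X1), rownames(X2))
  if (length(shared) == 0L) {
    stop("no shared gene IDs between '", path1, "' and '", path2, "'",
         call. = FALSE)
  }
  dropped <- setdiff(union(rownames(X1), rownames(X2)), shared)
  if (length(dropped) > 0L) {
    message(length(dropped), " gene(s) absent from one condition dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  }
  conditioned_expression(X1[shared, , drop = FALSE], X2[shared, , drop = FALSE])
}

read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2L) {
    stop("'", path, "' must have a gene-ID column plus sample columns",
         call. = FALSE)
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene IDs in '", path, "': ",
         paste(unique(ids[duplicated(ids)])[1:min(5, sum(duplicated(ids)))],
               collapse = ", "), call. = FALSE)
  }
  vals <- df[-1]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(col), numeric(nrow(df)))
  )
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L)
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell in '", path, "' at gene '", ids[bad[1]],
         "', sample column '", names(vals)[bad[2]], "'", call. = FALSE)
  }
  rownames(num) <- ids
  colnames(num) <- names(vals)
  num
}

#' Write a conditioned expression object to two TSV files
#'
#' Inverse of [read_expression()]; used by the simulation workflow to emit
#' matrices in the package's input format.
#'
#' @param expr A [conditioned_expression()] object.
#' @param path1,path2 Output paths for condition 1 and condition 2.
#' @return The input, invisibly.
#' @export
write_expression <- function(expr, path1, path2) {
  stopifnot(inherits(expr, "conditioned_expression"))
  write_one <- function(X, path, prefix) {
    cn <- colnames(X)
    if (is.null(cn)) cn <- paste0(prefix, seq_len(ncol(X)))
    df <- tibble::as_tibble(as.data.frame(X), .name_repair = ~cn)
    df <- dplyr::bind_cols(tibble::tibble(gene = rownames(X)), df)
    readr::write_tsv(df, path, progress = FALSE)
  }
  write_one(expr$X1, path1, "N")
  write_one(expr$X2, path2, "C")
  invisible(expr)
}
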