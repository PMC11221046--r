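#' Coerce a tabular expression data set to a genes-by-samples matrix
#'
#' The pipeline's natural input is a data frame with one row per gene: a gene
#' identifier column followed by one numeric column per sample. This helper
#' validates that layout and returns the internal matrix representation used
#' by the network-construction stage.
#'
#' @param x A data frame (first column gene ids, remaining columns samples),
#'   or an already-formed numeric matrix with rownames.
#' @param id_col Name or position of the gene-identifier column (default 1).
#' @param genes_in_columns If `TRUE`, `x` is transposed first (samples in
#'   rows, genes in columns).
#' @param na_action How to treat rows containing non-finite values:
#'   `"drop"` removes them with a warning, `"error"` aborts naming the genes.
#'
#' @return A numeric matrix (genes x samples) with unique rownames.
#' @export
as_expression_matrix <- function(x, id_col = 1L, genes_in_columns = FALSE,
                                 na_action = c("drop", "error")) {
  na_action <- match.arg(na_action)
  if (is.data.frame(x)) {
    ids <- as.character(x[[id_col]])
    pos <- if (is.numeric(id_col)) id_col else match(id_col, names(x))
    values <- as.matrix(x[, -pos, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- ids
  } else if (is.matrix(x)) {
    values <- x
    storage.mode(values) <- "double"
    if (is.null(rownames(values))) {
      stop("matrix input must carry gene identifiers as rownames", call. = FALSE)
    }
  } else {
    stop("`x` must be a data frame or a matrix", call. = FALSE)
  }
  if (genes_in_columns) values <- t(values)
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  bad <- !apply(is.finite(values), 1L, all)
  if (any(bad)) {
    if (na_action == "error") {
      stop("non-finite expression values in genes: ",
           paste(utils::head(rownames(values)[bad], 5L), collapse = ", "),
           call. = FALSE)
    }
    warning(sum(bad), " gene(s) with non-finite values dropped", call. = FALSE)
    values <- values[!bad, , drop = FALSE]
  }
  if (nrow(values) < 3L) stop("need at least 3 genes", call. = FALSE)
  if (ncol(values) < 2L) stop("need at least 2 samples", call. = FALSE)
  values
}

#' Read an expression table from TSV/CSV
#'
#' @param path File path; delimiter is inferred from the extension
#'   (`.csv` vs anything else = tab).
#' @inheritParams as_expression_matrix
#' @return A genes-by-samples numeric matrix.
#' @export
read_expression <- function(path, genes_in_columns = FALSE,
                            na_action = c("drop", "error")) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  as_expression_matrix(df, genes_in_columns = genes_in_columns,
                       na_action = na_action)
}

#' Scale every gene's expression profile to unit Euclidean norm
#'
#' Each row of the expression matrix is divided by its L2 norm, so all
#' downstream pairwise distances live on the unit sphere and the Gaussian
#' kernel bandwidth becomes a simple statistic of the data.
#'
#' @param ge Genes-by-samples numeric matrix (see [as_expression_matrix()]).
#' @return A matrix of the same shape whose rows all have Euclidean norm 1.
#' @export
normalize_genes <- function(ge) {
  if (!is.matrix(ge)) ge <- as_expression_matrix(ge)
  nrm <- sqrt(rowSums(ge^2))
  zero <- nrm == 0
  if (any(zero)) {
    stop("cannot normalize all-zero gene(s): ",
         paste(utils::head(rownames(ge)[zero], 5L), collapse = ", "),
         call. = FALSE)
  }
  ge / nrm
}
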