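#' Estimate the Gaussian kernel bandwidth from the data
#'
#' Returns the variance of the squared Euclidean distances over all unordered
#' gene pairs of the row-normalized expression matrix. This single statistic
#' sets the kernel bandwidth, so network construction needs no user-chosen
#' soft-thresholding power.
#'
#' @param g Row-normalized expression matrix (see [normalize_genes()]).
#' @param estimator `"population"` (divide by the number of pairs, default)
#'   or `"sample"` (divide by pairs - 1).
#' @return A positive scalar, the bandwidth gamma^2.
#' @export
estimate_bandwidth <- function(g, estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  if (nrow(g) < 3L) stop("need at least 3 genes", call. = FALSE)
  d2 <- as.vector(stats::dist(g))^2
  mu <- mean(d2)
  v <- if (estimator == "population") mean((d2 - mu)^2) else stats::var(d2)
  if (v <= 0 || !is.finite(v)) {
    stop("pairwise distances have zero variance; supply `bandwidth_sq` manually",
         call. = FALSE)
  }
  v
}

#' Gaussian-kernel similarity matrix
#'
#' Pairwise similarity s_ij = exp(-||g_i - g_j||^2 / (2 gamma^2)) between
#' row-normalized gene profiles. Values lie in (0, 1], with 1 on the
#' diagonal.
#'
#' @param g Row-normalized expression matrix.
#' @param bandwidth_sq Positive kernel bandwidth gamma^2; by default
#'   estimated from the data via [estimate_bandwidth()].
#' @return A symmetric m x m similarity matrix with unit diagonal, carrying
#'   the bandwidth in attribute `"bandwidth_sq"`.
#' @export
gaussian_similarity <- function(g, bandwidth_sq = NULL) {
  if (is.null(bandwidth_sq)) bandwidth_sq <- estimate_bandwidth(g)
  if (!is.numeric(bandwidth_sq) || length(bandwidth_sq) != 1L ||
      !is.finite(bandwidth_sq) || bandwidth_sq <= 0) {
    stop("`bandwidth_sq` must be a positive scalar", call. = FALSE)
  }
  # ||g_i - g_j||^2 = |g_i|^2 + |g_j|^2 - 2 g_i.g_j ; rows are unit norm but
  # the identity is computed generally so the function works on any matrix.
  sq <- rowSums(g^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(g)
  d2[d2 < 0] <- 0
  s <- exp(-d2 / (2 * bandwidth_sq))
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(rownames(g), rownames(g))
  attr(s, "bandwidth_sq") <- bandwidth_sq
  s
}

#' Topological-overlap enhancement of a similarity matrix
#'
#' Adds second-order neighbourhood information: the adjacency between genes i
#' and j combines their direct similarity with the similarity of their shared
#' neighbours,
#' \deqn{a_{ij} = (l_{ij} + s_{ij}) / (\min(k_i, k_j) + 1 - s_{ij})}
#' where \eqn{l_{ij} = \sum_{u \notin \{i,j\}} s_{iu} s_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} s_{iu}} (diagonal excluded, the standard TOM
#' convention, which keeps all entries in [0, 1]). The diagonal of the result
#' is zero.
#'
#' @param s Symmetric similarity matrix with entries in [0, 1].
#' @return A symmetric adjacency matrix with zero diagonal, entries in [0, 1].
#' @export
tom_enhance <- function(s) {
  if (!is.matrix(s) || nrow(s) != ncol(s)) {
    stop("`s` must be a square matrix", call. = FALSE)
  }
  if (max(abs(s - t(s))) > 1e-8) stop("`s` must be symmetric", call. = FALSE)
  if (min(s) < -1e-12 || max(s) > 1 + 1e-12) {
    stop("similarity entries must lie in [0, 1]", call. = FALSE)
  }
  s0 <- s
  diag(s0) <- 0
  # (s0 %*% s0)[i,j] = sum_u s_iu s_uj with the u = i and u = j terms zeroed
  # by the zero diagonal, i.e. exactly l_ij under the exclusion convention.
  l <- s0 %*% s0
  k <- rowSums(s0)
  denom <- outer(k, k, pmin) + 1 - s0
  a <- (l + s0) / denom
  diag(a) <- 0
  a <- (a + t(a)) / 2
  a[a < 0] <- 0
  a[a > 1] <- 1
  dimnames(a) <- dimnames(s)
  a
}

#' Build the TOM-enhanced co-expression network
#'
#' Convenience wrapper running row normalization, bandwidth estimation,
#' Gaussian-kernel similarity and topological-overlap enhancement in order.
#'
#' @inheritParams as_expression_matrix
#' @param ge Genes-by-samples expression data (matrix or data frame).
#' @param bandwidth_sq Optional bandwidth override; estimated when `NULL`.
#' @param max_genes Guard against accidental huge dense matrices; a warning
#'   is emitted above this many genes (default 20000).
#' @return A list of class `"coex_network"` with elements `similarity`,
#'   `adjacency`, `bandwidth_sq` and `gene_ids`.
#' @export
build_network <- function(ge, bandwidth_sq = NULL, max_genes = 20000L,
                          na_action = c("drop", "error")) {
  if (!is.matrix(ge)) ge <- as_expression_matrix(ge, na_action = na_action)
  if (nrow(ge) > max_genes) {
    warning("network has ", nrow(ge), " genes; dense storage needs ~",
            round(nrow(ge)^2 * 8 / 1e9, 1), " GB", call. = FALSE)
  }
  g <- normalize_genes(ge)
  s <- gaussian_similarity(g, bandwidth_sq = bandwidth_sq)
  a <- tom_enhance(s)
  structure(
    list(similarity = s, adjacency = a,
         bandwidth_sq = attr(s, "bandwidth_sq"),
         gene_ids = rownames(ge)),
    class = "coex_network"
  )
}

#' @export
print.coex_network <- function(x, ...) {
  cat("Co-expression network:", length(x$gene_ids), "genes\n")
  cat("  kernel bandwidth gamma^2 =", format(x$bandwidth_sq, digits = 4), "\n")
  off <- x$adjacency[upper.tri(x$adjacency)]
  cat("  adjacency range [", format(min(off), digits = 3), ", ",
      format(max(off), digits = 3), "]\n", sep = "")
  invisible(x)
}
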