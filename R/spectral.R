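#' Spectral decomposition of the random-walk operator
#'
#' Computes the leading eigenpairs of the row-stochastic random-walk operator
#' D^-1 A through its symmetric similarity transform
#' D^-1/2 A D^-1/2 (same eigenvalues; eigenvectors mapped back by D^-1/2).
#' Eigenvectors are then post-processed for clustering: each column is
#' centered by subtracting the scalar 1' D y / m, rescaled so that
#' y' D y = 1, and the first (trivial, constant) column is dropped.
#'
#' @param a Symmetric adjacency matrix with zero diagonal and positive
#'   degrees (see [tom_enhance()]).
#' @param n_eig Number of eigenpairs to compute; default
#'   `min(m, max(2 * k_max + 2, 50))` with `k_max = 40`.
#' @param k_max Largest cluster count the eigengap search should support.
#' @param solver `"dense"` (base `eigen`, default for m <= 500),
#'   `"iterative"` (RSpectra partial solver, default above), or `"auto"`.
#' @param centering `"printed"` divides the centering scalar by m;
#'   `"weighted_mean"` divides by the total degree (the D-weighted mean).
#' @return An object of class `"coex_spectrum"`: list with `values`
#'   (eigenvalues, descending), `vectors` (m x (n_eig - 1) processed
#'   eigenvector matrix, trivial column removed), `degrees`, `n_computed`
#'   and `gene_ids`.
#' @export
spectral_decompose <- function(a, n_eig = NULL, k_max = 40L,
                               solver = c("auto", "dense", "iterative"),
                               centering = c("printed", "weighted_mean")) {
  solver <- match.arg(solver)
  centering <- match.arg(centering)
  if (inherits(a, "coex_network")) a <- a$adjacency
  m <- nrow(a)
  if (is.null(n_eig)) n_eig <- min(m, max(2L * k_max + 2L, 50L))
  n_eig <- as.integer(n_eig)
  if (n_eig < 3L || n_eig > m) stop("`n_eig` must be in [3, m]", call. = FALSE)
  d <- rowSums(a)
  if (any(d <= 0)) {
    stop("isolated gene(s) with zero degree: ",
         paste(utils::head(rownames(a)[d <= 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (solver == "auto") solver <- if (m <= 500L) "dense" else "iterative"
  ds <- 1 / sqrt(d)
  msym <- a * tcrossprod(ds)          # D^-1/2 A D^-1/2
  msym <- (msym + t(msym)) / 2
  if (solver == "dense") {
    es <- eigen(msym, symmetric = TRUE)
    lambda <- es$values[seq_len(n_eig)]
    vec <- es$vectors[, seq_len(n_eig), drop = FALSE]
  } else {
    es <- RSpectra::eigs_sym(msym, k = n_eig, which = "LA")
    if (length(es$values) < n_eig) {
      stop("iterative eigensolver failed to converge (",
           length(es$values), "/", n_eig, " eigenpairs)", call. = FALSE)
    }
    ord <- order(es$values, decreasing = TRUE)
    lambda <- es$values[ord]
    vec <- es$vectors[, ord, drop = FALSE]
  }
  y <- vec * ds                        # back-transform to D^-1 A eigenvectors
  # sign fixing: largest-magnitude entry positive, for reproducibility
  for (j in seq_len(ncol(y))) {
    piv <- which.max(abs(y[, j]))
    if (y[piv, j] < 0) y[, j] <- -y[, j]
  }
  denom <- if (centering == "printed") m else sum(d)
  ctr <- as.vector(crossprod(d, y)) / denom    # 1' D y / m per column
  y <- sweep(y, 2L, ctr, "-")
  scl <- sqrt(colSums(d * y^2))                # y' D y
  scl[scl == 0] <- 1
  y <- sweep(y, 2L, scl, "/")
  structure(
    list(values = lambda,
         vectors = y[, -1L, drop = FALSE],
         degrees = d,
         n_computed = n_eig,
         gene_ids = rownames(a)),
    class = "coex_spectrum"
  )
}

#' @export
print.coex_spectrum <- function(x, ...) {
  cat("Spectral decomposition:", length(x$degrees), "genes,",
      x$n_computed, "eigenpairs\n")
  cat("  leading eigenvalues:",
      paste(format(utils::head(x$values, 6), digits = 4), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Candidate cluster counts from eigengap heuristics
#'
#' Three heuristics locate a gap in the (descending) eigenvalue spectrum of
#' the random-walk operator: the additive gap `lambda_i - lambda_{i+1}`, the
#' relative gap `(1 - lambda_{i+1}) / (1 - lambda_i)`, and the second-order
#' gap (difference of consecutive relative gaps). Each argmax over
#' i = 2 ... n_computed - 2 is a candidate number of clusters.
#'
#' @param sd A `"coex_spectrum"` object from [spectral_decompose()].
#' @param eps Floor applied to `1 - lambda` denominators; a repeated unit
#'   eigenvalue (disconnected network) triggers a warning, not an error.
#' @return A list of class `"coex_candidates"` with integer elements `k_ag`,
#'   `k_rg`, `k_sg` and a tibble `profiles` holding the three gap curves.
#' @export
candidate_ks <- function(sd, eps = 1e-12) {
  lambda <- sd$values
  p <- length(lambda)
  if (p < 5L) stop("need at least 5 computed eigenvalues", call. = FALSE)
  idx <- 2:(p - 2L)
  one_minus <- 1 - lambda
  if (any(one_minus[idx] < eps)) {
    warning("repeated unit eigenvalue in the search range: ",
            "network appears disconnected; ratios floored at eps",
            call. = FALSE)
  }
  om <- pmax(one_minus, eps)
  ag <- lambda[idx] - lambda[idx + 1L]
  rg_all <- om[seq_len(p - 1L) + 1L] / om[seq_len(p - 1L)]  # rg_i for i=1..p-1
  rg <- rg_all[idx]
  sg <- rg_all[idx] - rg_all[idx + 1L]
  k_ag <- idx[which.max(ag)]
  k_rg <- idx[which.max(rg)]
  k_sg <- idx[which.max(sg)]
  structure(
    list(k_ag = k_ag, k_rg = k_rg, k_sg = k_sg,
         profiles = tibble::tibble(
           index = idx,
           additive = ag,
           relative = rg,
           second_order = sg
         )),
    class = "coex_candidates"
  )
}

#' @export
print.coex_candidates <- function(x, ...) {
  cat("Candidate cluster counts: additive =", x$k_ag,
      "| relative =", x$k_rg, "| second-order =", x$k_sg, "\n")
  invisible(x)
}
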