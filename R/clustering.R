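#' Row-normalized spectral embedding for a given cluster count
#'
#' Takes the first `2k` retained eigenvector columns (largest eigenvalues
#' first, trivial vector already dropped) and scales every gene's row to unit
#' Euclidean norm, placing genes on the unit sphere where k-means separates
#' angular structure.
#'
#' @param sd A `"coex_spectrum"` object.
#' @param k Target number of clusters; `2k` must not exceed the number of
#'   retained eigenvector columns.
#' @return A list of class `"coex_embedding"`: `values` (m x 2k matrix with
#'   unit-norm rows), `k`, `gene_ids`.
#' @export
build_embedding <- function(sd, k) {
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (2L * k > ncol(sd$vectors)) {
    stop("2k = ", 2L * k, " exceeds the ", ncol(sd$vectors),
         " retained eigenvector columns", call. = FALSE)
  }
  y <- sd$vectors[, seq_len(2L * k), drop = FALSE]
  nrm <- sqrt(rowSums(y^2))
  zero <- nrm == 0
  if (any(zero)) {
    stop("degenerate zero embedding row for gene(s): ",
         paste(utils::head(sd$gene_ids[zero], 5L), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(values = y / nrm, k = k, gene_ids = sd$gene_ids),
    class = "coex_embedding"
  )
}

# kmeans++ seeding: D^2-weighted center choice, classic Arthur-Vassilvitskii
kmeanspp_centers <- function(x, k) {
  m <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(m, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], m, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[j + 1L] <- sample.int(m, 1L)
    } else {
      centers[j + 1L] <- sample.int(m, 1L, prob = d2)
    }
    dn <- rowSums((x - matrix(x[centers[j + 1L], ], m, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  x[centers, , drop = FALSE]
}

# first-occurrence canonical relabeling: cluster 1 contains the first gene
canonical_relabel <- function(labels) {
  first <- unique(labels)
  match(labels, first)
}

#' Cluster the spectral embedding with seeded k-means
#'
#' Lloyd iterations with kmeans++ initialization, repeated over `restarts`
#' random starts; the solution with the smallest total within-cluster sum of
#' squares wins. Labels are relabeled canonically (cluster 1 is the cluster
#' of the first gene) so runs are reproducible and comparable.
#'
#' @param e A `"coex_embedding"` object.
#' @param k Number of clusters (>= 2, < number of genes).
#' @param seed Integer seed controlling initialization.
#' @param restarts Number of kmeans++ restarts (default 50).
#' @param iter_max Maximum Lloyd iterations per start (default 300).
#' @return A list of class `"coex_clustering"`: `labels` (integers 1..k,
#'   named by gene), `k`, `tot_withinss`, `gene_ids`.
#' @export
run_kmeans <- function(e, k = e$k, seed = 1L, restarts = 50L, iter_max = 300L) {
  k <- as.integer(k)
  x <- e$values
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (nrow(x) <= k) stop("need more genes than clusters", call. = FALSE)
  best <- NULL
  for (attempt in 0:4) {
    fits <- withr::with_seed(as.integer(seed) + attempt, {
      lapply(seq_len(restarts), function(i) {
        ctr <- kmeanspp_centers(x, k)
        fit <- suppressWarnings(
          stats::kmeans(x, centers = ctr, iter.max = iter_max,
                        algorithm = "Lloyd")
        )
        fit
      })
    })
    ok <- vapply(fits, function(f) length(unique(f$cluster)) == k, logical(1))
    if (any(ok)) {
      fits <- fits[ok]
      tw <- vapply(fits, function(f) f$tot.withinss, numeric(1))
      best <- fits[[which.min(tw)]]
      break
    }
  }
  if (is.null(best)) {
    stop("k-means produced an empty cluster in every restart", call. = FALSE)
  }
  labels <- canonical_relabel(best$cluster)
  names(labels) <- e$gene_ids
  structure(
    list(labels = labels, k = k, tot_withinss = best$tot.withinss,
         gene_ids = e$gene_ids),
    class = "coex_clustering"
  )
}

#' @export
print.coex_clustering <- function(x, ...) {
  cat("Clustering: k =", x$k, "| sizes:",
      paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Graph conductance of one cluster
#'
#' The weight of edges leaving the cluster divided by the cluster volume
#' (sum of member degrees). Low conductance means a well-separated cluster.
#'
#' @param a Adjacency matrix (zero diagonal).
#' @param labels Integer label vector over all nodes.
#' @param cluster Label of the cluster to score.
#' @return Conductance in [0, 1].
#' @export
conductance <- function(a, labels, cluster) {
  if (inherits(a, "coex_network")) a <- a$adjacency
  inside <- labels == cluster
  if (!any(inside)) stop("cluster ", cluster, " not present", call. = FALSE)
  vol <- sum(a[inside, , drop = FALSE])
  if (vol <= 0) stop("cluster ", cluster, " has zero volume", call. = FALSE)
  cut <- sum(a[inside, !inside, drop = FALSE])
  cut / vol
}

#' Conductance of every cluster in a clustering
#'
#' @param a Adjacency matrix or `"coex_network"`.
#' @param clustering A `"coex_clustering"` object (or integer label vector).
#' @return A tibble with columns `cluster`, `size`, `conductance`.
#' @export
cluster_conductances <- function(a, clustering) {
  if (inherits(a, "coex_network")) a <- a$adjacency
  labels <- if (inherits(clustering, "coex_clustering")) clustering$labels
            else clustering
  ks <- sort(unique(labels))
  tibble::tibble(
    cluster = ks,
    size = vapply(ks, function(k) sum(labels == k), integer(1)),
    conductance = vapply(ks, function(k) conductance(a, labels, k), numeric(1))
  )
}

#' Cluster each candidate k and pick its minimum-conductance test cluster
#'
#' For every distinct candidate cluster count, builds the 2k-column
#' embedding, runs seeded k-means, scores every cluster's conductance, and
#' marks the minimum-conductance cluster as that candidate's *test cluster*
#' (ties broken by the smallest cluster label). Duplicate candidate values
#' are computed once and shared.
#'
#' @param a Adjacency matrix or `"coex_network"`.
#' @param sd A `"coex_spectrum"` object.
#' @param ck A `"coex_candidates"` object (or a named list/vector with
#'   entries `k_ag`, `k_rg`, `k_sg`).
#' @param seed Integer seed passed to [run_kmeans()].
#' @param restarts,iter_max Passed to [run_kmeans()].
#' @return A named list (`ag`, `rg`, `sg`) of lists, each with `k`,
#'   `clustering`, `conductances` (tibble), `test_cluster` (label) and
#'   `test_genes` (character vector).
#' @export
select_test_clusters <- function(a, sd, ck, seed = 1L, restarts = 50L,
                                 iter_max = 300L) {
  if (inherits(a, "coex_network")) a <- a$adjacency
  ks <- c(ag = ck$k_ag, rg = ck$k_rg, sg = ck$k_sg)
  cache <- list()
  out <- list()
  for (mth in names(ks)) {
    k <- as.integer(ks[[mth]])
    key <- as.character(k)
    if (is.null(cache[[key]])) {
      e <- build_embedding(sd, k)
      cl <- run_kmeans(e, k, seed = seed, restarts = restarts,
                       iter_max = iter_max)
      cond <- cluster_conductances(a, cl)
      test <- cond$cluster[which.min(cond$conductance)]  # ties: smallest label
      cache[[key]] <- list(
        k = k, embedding = e, clustering = cl, conductances = cond,
        test_cluster = test,
        test_genes = cl$gene_ids[cl$labels == test]
      )
    }
    out[[mth]] <- cache[[key]]
  }
  out
}

#' Fix the number of clusters by enrichment of the test clusters
#'
#' Each candidate's test cluster carries an enrichment quality score (sum of
#' -log10 p over its retained ontology terms); the candidate whose test
#' cluster scores highest wins. Ties follow the precedence additive >
#' relative > second-order. If no test cluster has any enriched term, the
#' minimum-conductance test cluster decides, with a warning.
#'
#' @param test_results Output of [select_test_clusters()].
#' @param qualities Named numeric vector of test-cluster quality scores with
#'   names `ag`, `rg`, `sg` (see [cluster_quality()]).
#' @return A list with `k`, `method` (tag `"ag"`, `"rg"` or `"sg"`),
#'   `clustering`, `embedding`, `conductances`, `quality`.
#' @export
choose_k <- function(test_results, qualities) {
  mths <- c("ag", "rg", "sg")
  q <- qualities[mths]
  if (all(q == 0)) {
    warning("no test cluster has enriched terms; ",
            "falling back to minimum conductance", call. = FALSE)
    cond <- vapply(mths, function(m) {
      tr <- test_results[[m]]
      tr$conductances$conductance[tr$conductances$cluster == tr$test_cluster]
    }, numeric(1))
    pick <- mths[which.min(cond)]
  } else {
    pick <- mths[which.max(q)]   # which.max keeps the first = ag > rg > sg
  }
  tr <- test_results[[pick]]
  list(k = tr$k, method = pick, clustering = tr$clustering,
       embedding = tr$embedding, conductances = tr$conductances,
       quality = unname(q[pick]))
}
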