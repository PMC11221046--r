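#' Run the full co-expression module detection pipeline
#'
#' Executes the five stages end to end: (I) network construction
#' (row normalization, Gaussian-kernel similarity with data-driven
#' bandwidth, topological-overlap enhancement); (II) spectral decomposition
#' of the random-walk operator, eigengap candidates for the cluster count,
#' k-means per candidate, and selection of k by the enrichment of each
#' candidate's minimum-conductance test cluster; (III) per-cluster
#' over/under-representation analysis; (IV) semi-labeling of genes into a
#' remarkable training set; (V) supervised re-classification of the
#' unremarkable genes into final modules. Both the initial clusters and the
#' final modules are returned.
#'
#' @param expr Expression data: a data frame (`gene_id` first column,
#'   samples after) or a genes-by-samples matrix with rownames.
#' @param annotation Annotation data: a data frame (gene, term, optional
#'   namespace), a `"coex_annotation"`, or a file path readable by
#'   [read_annotation()].
#' @param seed Integer seed driving every stochastic step (k-means starts,
#'   cross-validation folds).
#' @param k Optional user-forced cluster count; skips the eigengap
#'   candidates and the enrichment-based selection.
#' @param bandwidth_sq Optional Gaussian-kernel bandwidth override.
#' @param n_eig Number of eigenpairs to compute (see
#'   [spectral_decompose()]).
#' @param restarts,iter_max k-means restarts and Lloyd iteration cap.
#' @param p_cutoff Enrichment retention threshold (default 0.05).
#' @param top_fraction Pooled top fraction of records defining remarkable
#'   genes (default 0.10).
#' @param classifier `"knn"` (default) or `"logistic"`.
#' @param quality_directions Record directions entering quality scores and
#'   the semi-labeling pool (default both).
#' @param centering Eigenvector centering rule (see [spectral_decompose()]).
#' @return An object of class `"coex_fit"`; see [tidy.coex_fit()] and
#'   [glance.coex_fit()] for tabular views.
#' @export
coex_pipeline <- function(expr, annotation, seed = 1L, k = NULL,
                          bandwidth_sq = NULL, n_eig = NULL,
                          restarts = 50L, iter_max = 300L,
                          p_cutoff = 0.05, top_fraction = 0.10,
                          classifier = c("knn", "logistic"),
                          quality_directions = c("over", "under"),
                          centering = c("printed", "weighted_mean")) {
  classifier <- match.arg(classifier)
  centering <- match.arg(centering)
  seed <- as.integer(seed)

  ge <- if (is.matrix(expr)) expr else as_expression_matrix(expr)
  net <- build_network(ge, bandwidth_sq = bandwidth_sq)
  ann <- if (inherits(annotation, "coex_annotation")) annotation
         else if (is.character(annotation) && length(annotation) == 1L)
           read_annotation(annotation, rownames(ge))
         else as_annotation(annotation, rownames(ge))

  sd <- spectral_decompose(net$adjacency, n_eig = n_eig,
                           centering = centering)

  if (is.null(k)) {
    ck <- candidate_ks(sd)
    tests <- select_test_clusters(net$adjacency, sd, ck, seed = seed,
                                  restarts = restarts, iter_max = iter_max)
    qualities <- vapply(c("ag", "rg", "sg"), function(mth) {
      tr <- tests[[mth]]
      # enrich the test cluster alone against the full universe
      tab <- suppressWarnings(
        enrich_clusters(stats::setNames(
          ifelse(tr$clustering$labels == tr$test_cluster, 1L, 2L),
          tr$clustering$gene_ids), ann, p_cutoff = p_cutoff)
      )
      rec <- tab[tab$cluster == 1L, , drop = FALSE]
      cluster_quality(rec, directions = quality_directions)
    }, numeric(1))
    pick <- choose_k(tests, qualities)
  } else {
    ck <- NULL
    e <- build_embedding(sd, k)
    cl <- run_kmeans(e, k, seed = seed, restarts = restarts,
                     iter_max = iter_max)
    pick <- list(k = as.integer(k), method = "user", clustering = cl,
                 embedding = e,
                 conductances = cluster_conductances(net$adjacency, cl),
                 quality = NA_real_)
  }

  enr <- enrich_clusters(pick$clustering, ann, p_cutoff = p_cutoff)
  sl <- semi_label(enr, pick$clustering, ann, top_fraction = top_fraction,
                   directions = quality_directions)
  ms <- train_and_classify(pick$embedding, sl, kind = classifier,
                           seed = seed, initial_labels = pick$clustering$labels)
  refinement <- summarize_refinement(pick$clustering, sl, ms)
  final_enr <- enrich_clusters(ms$labels, ann, p_cutoff = p_cutoff)

  structure(
    list(network = net, spectrum = sd, candidates = ck,
         k = pick$k, method = pick$method,
         clustering = pick$clustering, embedding = pick$embedding,
         conductances = pick$conductances,
         enrichment = enr, semilabel = sl, modules = ms,
         final_enrichment = final_enr,
         refinement = refinement,
         params = list(seed = seed, p_cutoff = p_cutoff,
                       top_fraction = top_fraction, classifier = classifier,
                       restarts = restarts, iter_max = iter_max,
                       bandwidth_sq = net$bandwidth_sq)),
    class = "coex_fit"
  )
}

#' @export
print.coex_fit <- function(x, ...) {
  cat("Co-expression module fit\n")
  cat("  genes:", length(x$network$gene_ids),
      "| k =", x$k, paste0("(", x$method, ")"),
      "-> k' =", x$modules$k_prime, "\n")
  cat("  unremarkable:", sprintf("%.1f%%", x$refinement$pct_unremarkable),
      "| labels changed:", sprintf("%.1f%%", x$refinement$pct_changed), "\n")
  cat("  module sizes:",
      paste(tabulate(x$modules$labels, x$modules$k_prime), collapse = ", "),
      "\n")
  invisible(x)
}

#' Gene-level results of a pipeline fit
#'
#' @param x A `"coex_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per gene: `gene_id`, `cluster` (initial),
#'   `remarkable`, `module` (final).
#' @exportS3Method generics::tidy
#' @export tidy.coex_fit
tidy.coex_fit <- function(x, ...) {
  ids <- x$clustering$gene_ids
  tibble::tibble(
    gene_id = ids,
    cluster = unname(x$clustering$labels[ids]),
    remarkable = ids %in% names(x$semilabel$remarkable),
    module = unname(x$modules$labels[ids])
  )
}

#' One-row summary of a pipeline fit
#'
#' @param x A `"coex_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `method`, `k_prime`, `pct_unremarkable`,
#'   `pct_changed`, `classifier`, `hyperparameter`, `framework_quality`.
#' @exportS3Method generics::glance
#' @export glance.coex_fit
glance.coex_fit <- function(x, ...) {
  qf <- if (nrow(x$final_enrichment) > 0) {
    framework_quality(x$final_enrichment)$framework_quality
  } else NA_real_
  tibble::tibble(
    k = x$k, method = x$method, k_prime = x$modules$k_prime,
    pct_unremarkable = x$refinement$pct_unremarkable,
    pct_changed = x$refinement$pct_changed,
    classifier = x$modules$classifier_kind,
    hyperparameter = x$modules$chosen_hyperparam,
    framework_quality = qf
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
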