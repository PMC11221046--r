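#' Classify unremarkable genes from the remarkable training set
#'
#' Trains a classifier on the embedding rows of the remarkable genes
#' (labels 1..k') and predicts a module for every unremarkable gene.
#' The default k-nearest-neighbours classifier selects its neighbour count
#' over the grid `20:(20 + 2k)` when `2k <= 30`, else `20:30` (capped at
#' one less than the training-set size, re-floored at 1 with a warning when
#' the training set is tiny), by stratified cross-validated accuracy; ties
#' prefer the smaller count. The alternative is one-vs-rest ridge logistic
#' regression at a fixed penalty. Remarkable genes always keep their
#' training labels.
#'
#' @param e A `"coex_embedding"` (the one belonging to the chosen k).
#' @param sl A `"coex_semilabel"` object.
#' @param kind `"knn"` (default) or `"logistic"`.
#' @param seed Integer seed for cross-validation fold assignment.
#' @param nfolds Cross-validation folds for the neighbour grid (default 5,
#'   reduced when a class is smaller than the fold count).
#' @param initial_labels Optional named integer vector of initial cluster
#'   labels, used to compute `changed_fraction`; `NA` when omitted.
#' @return A list of class `"coex_modules"`: `labels` (named integer vector
#'   over all genes, values in 1..k'), `k_prime`, `classifier_kind`,
#'   `chosen_hyperparam`, `changed_fraction` (share of unremarkable genes
#'   whose final label differs from their initial cluster's mapped label;
#'   genes from dropped clusters always count as changed).
#' @export
train_and_classify <- function(e, sl, kind = c("knn", "logistic"),
                               seed = 1L, nfolds = 5L,
                               initial_labels = NULL) {
  kind <- match.arg(kind)
  k_prime <- sl$k_prime
  if (k_prime < 1L) stop("no classes to train on", call. = FALSE)
  x <- e$values
  rownames(x) <- e$gene_ids
  train_ids <- names(sl$remarkable)
  test_ids <- sl$unremarkable
  y <- sl$remarkable

  labels <- stats::setNames(integer(length(e$gene_ids)), e$gene_ids)
  labels[train_ids] <- y
  chosen <- NA_real_

  if (k_prime == 1L) {
    warning("single surviving class; all genes assigned module 1",
            call. = FALSE)
    labels[] <- 1L
  } else if (length(test_ids) == 0L) {
    # nothing to classify
  } else if (kind == "knn") {
    xtr <- x[train_ids, , drop = FALSE]
    xte <- x[test_ids, , drop = FALSE]
    twok <- ncol(x)
    hi <- if (twok <= 30L) 20L + twok else 30L
    grid <- 20L:hi
    cap <- length(train_ids) - 1L
    grid <- grid[grid <= cap]
    if (length(grid) == 0L) {
      warning("training set smaller than the neighbour grid; ",
              "re-flooring the grid at 1", call. = FALSE)
      grid <- seq_len(max(1L, min(cap, hi)))
    }
    acc <- withr::with_seed(as.integer(seed), {
      folds <- stratified_folds(y, nfolds)
      vapply(grid, function(nn) {
        hits <- 0L; tot <- 0L
        for (f in sort(unique(folds))) {
          tr <- folds != f
          if (length(unique(y[tr])) < 2L) next
          nn_f <- min(nn, sum(tr) - 1L)
          pred <- class::knn(xtr[tr, , drop = FALSE],
                             xtr[!tr, , drop = FALSE],
                             factor(y[tr]), k = nn_f)
          hits <- hits + sum(as.integer(as.character(pred)) == y[!tr])
          tot <- tot + sum(!tr)
        }
        if (tot == 0L) 0 else hits / tot
      }, numeric(1))
    })
    chosen <- grid[which.max(acc)]       # ties -> smaller neighbour count
    pred <- withr::with_seed(as.integer(seed) + 1L,
      class::knn(xtr, xte, factor(y), k = chosen))
    labels[test_ids] <- as.integer(as.character(pred))
  } else {
    xtr <- x[train_ids, , drop = FALSE]
    xte <- x[test_ids, , drop = FALSE]
    # one-vs-rest ridge logistic; fixed penalty strength 1.0 in the
    # 1/(n C) parameterization common to sklearn-style solvers
    lam <- 1 / length(train_ids)
    scores <- sapply(seq_len(k_prime), function(cls) {
      fit <- glmnet::glmnet(xtr, factor(y == cls), family = "binomial",
                            alpha = 0, lambda = lam)
      as.vector(stats::predict(fit, xte, type = "response"))
    })
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = length(test_ids))
    labels[test_ids] <- apply(scores, 1L, which.max)
    chosen <- lam
  }

  changed <- if (length(test_ids) == 0L) 0 else if (is.null(initial_labels)) {
    NA_real_
  } else {
    mapped_init <- unname(sl$label_map[as.character(initial_labels[test_ids])])
    mean(is.na(mapped_init) | mapped_init != labels[test_ids])
  }
  structure(
    list(labels = labels, k_prime = k_prime, classifier_kind = kind,
         chosen_hyperparam = chosen,
         changed_fraction = changed),
    class = "coex_modules"
  )
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(y, nfolds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  folds
}

#' @export
print.coex_modules <- function(x, ...) {
  cat("Final modules: k' =", x$k_prime, "| classifier:", x$classifier_kind,
      if (!is.na(x$chosen_hyperparam))
        paste0("(hyperparameter ", format(x$chosen_hyperparam, digits = 3), ")"),
      "\n  sizes:", paste(tabulate(x$labels, x$k_prime), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize the semi-supervised refinement
#'
#' Reports the share of unremarkable genes (%UNR), the share of unremarkable
#' genes whose label changed relative to their initial cluster's mapped
#' label (%CH), the cluster counts before and after refinement, and module
#' sizes.
#'
#' @param clustering The initial `"coex_clustering"`.
#' @param sl The `"coex_semilabel"` object.
#' @param ms The `"coex_modules"` object.
#' @return A one-row tibble: `k`, `k_prime`, `pct_unremarkable`,
#'   `pct_changed`, `all_remarkable` (flag: %CH undefined, reported as 0),
#'   plus a `sizes` list-column.
#' @export
summarize_refinement <- function(clustering, sl, ms) {
  labels <- clustering$labels
  m <- length(labels)
  n_unrem <- length(sl$unremarkable)
  mapped_init <- unname(sl$label_map[as.character(labels[sl$unremarkable])])
  changed <- if (n_unrem == 0L) 0 else {
    mean(is.na(mapped_init) | mapped_init != ms$labels[sl$unremarkable])
  }
  tibble::tibble(
    k = clustering$k,
    k_prime = sl$k_prime,
    pct_unremarkable = 100 * n_unrem / m,
    pct_changed = 100 * changed,
    all_remarkable = n_unrem == 0L,
    sizes = list(tabulate(ms$labels, ms$k_prime))
  )
}
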