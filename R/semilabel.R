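#' Split genes into remarkable and unremarkable sets
#'
#' Pools all retained enrichment records across clusters, selects the
#' `ceiling(top_fraction * total)` records with the smallest p-values (ties
#' at the boundary broken by cluster then term id), and marks a gene
#' *remarkable* when, within its own cluster, it is annotated to at least
#' one selected record of that cluster. Remarkable genes inherit their
#' cluster's label and form the training set for the re-classification
#' step; clusters left without remarkable genes are dropped and the
#' survivors relabeled contiguously, giving the refined cluster count k'.
#'
#' @param table A `"coex_enrichment"` tibble from [enrich_clusters()].
#' @param clustering A `"coex_clustering"` object or named label vector.
#' @param ann The `"coex_annotation"` used for enrichment.
#' @param top_fraction Fraction of pooled records to select (default 0.10).
#' @param directions Which record directions participate in the pool.
#' @return A list of class `"coex_semilabel"`: `remarkable` (named integer
#'   vector, training labels in 1..k'), `unremarkable` (character vector),
#'   `k_prime`, `label_map` (named integer: original cluster -> 1..k'),
#'   `selected` (tibble of the selected records).
#' @export
semi_label <- function(table, clustering, ann, top_fraction = 0.10,
                       directions = c("over", "under")) {
  if (!(is.numeric(top_fraction) && top_fraction > 0 && top_fraction <= 1)) {
    stop("`top_fraction` must be in (0, 1]", call. = FALSE)
  }
  labels <- if (inherits(clustering, "coex_clustering")) clustering$labels
            else clustering
  pool <- table[table$direction %in% directions, , drop = FALSE]
  n_sel <- ceiling(top_fraction * nrow(pool))
  if (n_sel == 0L) {
    stop("no enrichment records to select from; ",
         "increase `top_fraction` or the enrichment `p_cutoff`",
         call. = FALSE)
  }
  ord <- order(pool$p_value, pool$cluster, pool$term)
  selected <- pool[ord[seq_len(n_sel)], , drop = FALSE]

  ann_tbl <- ann$table
  remark <- character(0)
  for (cl in unique(selected$cluster)) {
    terms_cl <- selected$term[selected$cluster == cl]
    genes_cl <- names(labels)[labels == cl]
    hit <- ann_tbl$gene[ann_tbl$term %in% terms_cl & ann_tbl$gene %in% genes_cl]
    remark <- c(remark, unique(hit))
  }
  remark <- unique(remark)
  universe <- names(labels)
  unrem <- setdiff(universe, remark)

  kept <- sort(unique(labels[remark]))
  label_map <- stats::setNames(seq_along(kept), kept)
  remarkable <- stats::setNames(
    label_map[as.character(labels[remark])], remark
  )
  structure(
    list(remarkable = remarkable,
         unremarkable = unrem,
         k_prime = length(kept),
         label_map = label_map,
         selected = selected),
    class = "coex_semilabel"
  )
}

#' @export
print.coex_semilabel <- function(x, ...) {
  m <- length(x$remarkable) + length(x$unremarkable)
  cat("Semi-labeling: k' =", x$k_prime, "|",
      length(x$remarkable), "remarkable /", length(x$unremarkable),
      "unremarkable genes (",
      sprintf("%.1f%%", 100 * length(x$unremarkable) / m), "unremarkable )\n")
  invisible(x)
}
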