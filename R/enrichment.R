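#' Build an annotation set from a gene-to-term table
#'
#' @param x A data frame with columns gene id, term id and (optionally)
#'   ontology namespace (`BP`, `CC` or `MF`); extra columns are ignored.
#' @param universe Character vector of gene ids forming the testing universe
#'   (typically all genes in the expression data). The mapping is restricted
#'   to this universe.
#' @return A list of class `"coex_annotation"`: `table` (tibble gene/term/
#'   namespace, unique rows), `universe`, and `terms` (tibble term/namespace/
#'   size over the restricted universe).
#' @export
as_annotation <- function(x, universe) {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    stop("annotation must be a data frame with >= 2 columns", call. = FALSE)
  }
  tbl <- tibble::tibble(
    gene = as.character(x[[1L]]),
    term = as.character(x[[2L]]),
    namespace = if (ncol(x) >= 3L) as.character(x[[3L]]) else "BP"
  )
  bad_ns <- !tbl$namespace %in% c("BP", "CC", "MF")
  if (any(bad_ns)) {
    stop("unknown ontology namespace: ",
         paste(unique(tbl$namespace[bad_ns]), collapse = ", "), call. = FALSE)
  }
  universe <- unique(as.character(universe))
  tbl <- dplyr::distinct(dplyr::filter(tbl, .data$gene %in% universe))
  if (nrow(tbl) == 0L) {
    stop("annotation has zero overlap with the gene universe", call. = FALSE)
  }
  terms <- dplyr::summarise(dplyr::group_by(tbl, .data$term, .data$namespace),
                            size = dplyr::n(), .groups = "drop")
  structure(list(table = tbl, universe = universe, terms = terms),
            class = "coex_annotation")
}

#' @export
print.coex_annotation <- function(x, ...) {
  cov <- length(unique(x$table$gene)) / length(x$universe)
  cat("Annotation:", nrow(x$terms), "terms over",
      length(x$universe), "genes (coverage ",
      sprintf("%.1f%%", 100 * cov), ")\n", sep = " ")
  invisible(x)
}

#' Load a gene-to-term annotation file
#'
#' Accepts a 2/3-column TSV (gene, term, optional namespace) or a GAF 2.x
#' file (17-column, `!` comment lines, `NOT`-qualified rows skipped; the
#' aspect column `P`/`C`/`F` maps to `BP`/`CC`/`MF`).
#'
#' @param path File path.
#' @param universe Character vector of gene ids to restrict to.
#' @return A `"coex_annotation"` object; a coverage summary is messaged.
#' @export
read_annotation <- function(path, universe) {
  first <- readLines(path, n = 50L)
  is_gaf <- any(grepl("^!gaf-version", first)) ||
    (length(strsplit(first[!startsWith(first, "!")][1], "\t")[[1]]) >= 15L)
  if (is_gaf) {
    df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                            comment.char = "!", stringsAsFactors = FALSE,
                            fill = TRUE)
    keep <- !grepl("(^|\\|)NOT($|\\|)", df[[4L]])
    aspect <- c(P = "BP", C = "CC", F = "MF")[df[[9L]]]
    df <- data.frame(gene = df[[3L]], term = df[[5L]],
                     namespace = aspect, stringsAsFactors = FALSE)[keep, ]
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
    has_header <- !df[1, 1] %in% universe
    if (has_header) df <- df[-1, , drop = FALSE]
  }
  ann <- as_annotation(df, universe)
  message("annotation covers ",
          sprintf("%.1f%%", 100 * length(unique(ann$table$gene)) /
                    length(ann$universe)),
          " of the ", length(ann$universe), "-gene universe")
  ann
}

# tail probability of X ~ Hypergeometric(N, K, n) at overlap x; shared by
# hypergeom_test and enrich_clusters so both report identical p-values
hyper_p <- function(x, K, N, n, direction) {
  p <- if (direction == "over") {
    stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(x, K, N - K, n, lower.tail = TRUE)
  }
  pmin(p, 1)
}

#' Exact hypergeometric over/under-representation test
#'
#' With universe size N, term size K, cluster size n and overlap x, tests
#' over-representation (p = P[X >= x]) or under-representation
#' (p = P[X <= x]) under X ~ Hypergeometric(N, K, n). Also reports the
#' sample odds ratio x (N - K - n + x) / ((K - x)(n - x)) (0 when x = 0,
#' `Inf` when a complementary cell is empty) and the expected overlap nK/N.
#'
#' @param cluster_genes,term_genes,universe Character vectors of gene ids;
#'   cluster and term genes must be subsets of the universe.
#' @param direction `"over"` or `"under"`.
#' @return A one-row tibble: `p_value`, `odds_ratio`, `expected_count`,
#'   `count`, `size`.
#' @export
hypergeom_test <- function(cluster_genes, term_genes, universe,
                           direction = c("over", "under")) {
  direction <- match.arg(direction)
  universe <- unique(universe)
  cluster_genes <- unique(cluster_genes)
  term_genes <- unique(term_genes)
  if (!all(cluster_genes %in% universe) || !all(term_genes %in% universe)) {
    stop("cluster and term genes must be subsets of the universe",
         call. = FALSE)
  }
  N <- length(universe); K <- length(term_genes); n <- length(cluster_genes)
  if (K == 0L || n == 0L) stop("empty term or cluster", call. = FALSE)
  x <- length(intersect(cluster_genes, term_genes))
  p <- hyper_p(x, K, N, n, direction)
  orat <- if (x == 0L) 0 else {
    den <- (K - x) * (n - x)
    if (den == 0L) Inf else x * (N - K - n + x) / den
  }
  tibble::tibble(
    p_value = p,
    odds_ratio = orat,
    expected_count = n * K / N,
    count = x,
    size = K
  )
}

#' Per-cluster ontology enrichment table
#'
#' Runs the six queries (over/under-representation crossed with the BP, CC
#' and MF namespaces) for every cluster: each term with at least one
#' annotated gene in the cluster is tested in both directions, and records
#' with p <= `p_cutoff` are retained, sorted by p within cluster.
#'
#' @param clustering A `"coex_clustering"` object or a named integer label
#'   vector (names = gene ids).
#' @param ann A `"coex_annotation"` object.
#' @param p_cutoff Retention threshold on the raw p-value (default 0.05).
#' @param adjust If `TRUE`, Benjamini-Hochberg-adjust p-values per cluster
#'   and direction before filtering (off by default; raw p-values are the
#'   pipeline's working currency).
#' @param min_size_flag Terms with fewer than this many annotated genes are
#'   flagged in the `small_term` column (never silently dropped).
#' @return A tibble of class `"coex_enrichment"` with columns `cluster`,
#'   `term`, `namespace`, `direction`, `p_value`, `odds_ratio`,
#'   `expected_count`, `count`, `size`, `small_term`.
#' @export
enrich_clusters <- function(clustering, ann, p_cutoff = 0.05, adjust = FALSE,
                            min_size_flag = 2L) {
  labels <- if (inherits(clustering, "coex_clustering")) clustering$labels
            else clustering
  if (is.null(names(labels))) stop("labels must be named by gene", call. = FALSE)
  if (!(is.numeric(p_cutoff) && p_cutoff > 0 && p_cutoff <= 1)) {
    stop("`p_cutoff` must be in (0, 1]", call. = FALSE)
  }
  universe <- ann$universe
  ann_tbl <- ann$table
  term_genes <- split(ann_tbl$gene, ann_tbl$term)
  term_ns <- stats::setNames(ann$terms$namespace, ann$terms$term)
  N <- length(universe)
  K_all <- lengths(term_genes)
  out <- list()
  for (cl in sort(unique(labels))) {
    genes <- names(labels)[labels == cl]
    n <- length(genes)
    ann_here <- ann_tbl[ann_tbl$gene %in% genes, ]
    if (nrow(ann_here) == 0L) {
      warning("cluster ", cl, " has no annotated genes", call. = FALSE)
      next
    }
    x_counts <- table(ann_here$term)
    terms <- names(x_counts)
    K <- K_all[terms]
    x <- as.integer(x_counts)
    p_over <- hyper_p(x, K, N, n, "over")
    p_under <- hyper_p(x, K, N, n, "under")
    orat <- ifelse(x == 0L, 0,
                   ifelse((K - x) * (n - x) == 0L, Inf,
                          x * (N - K - n + x) / ((K - x) * (n - x))))
    rec <- tibble::tibble(
      cluster = cl,
      term = rep(terms, 2L),
      namespace = unname(term_ns[rep(terms, 2L)]),
      direction = rep(c("over", "under"), each = length(terms)),
      p_value = pmin(c(p_over, p_under), 1),
      odds_ratio = rep(orat, 2L),
      expected_count = rep(n * K / N, 2L),
      count = rep(x, 2L),
      size = rep(unname(K), 2L)
    )
    if (adjust) {
      rec <- dplyr::mutate(dplyr::group_by(rec, .data$direction),
                           p_value = stats::p.adjust(.data$p_value, "BH"))
      rec <- dplyr::ungroup(rec)
    }
    rec <- rec[rec$p_value <= p_cutoff, , drop = FALSE]
    rec <- rec[order(rec$p_value, rec$term, rec$direction), , drop = FALSE]
    out[[length(out) + 1L]] <- rec
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    cluster = integer(), term = character(), namespace = character(),
    direction = character(), p_value = numeric(), odds_ratio = numeric(),
    expected_count = numeric(), count = integer(), size = integer()
  )
  res$small_term <- res$size < min_size_flag
  class(res) <- c("coex_enrichment", class(res))
  res
}

#' Enrichment quality of one cluster
#'
#' The sum of -log10 p over a cluster's retained enrichment records; an
#' empty record set scores 0. Used both to validate candidate cluster
#' counts and as the per-module quality in evaluation.
#'
#' @param records A tibble of enrichment records (rows of the table from
#'   [enrich_clusters()], already restricted to one cluster), or a numeric
#'   vector of p-values.
#' @param directions Which record directions contribute (default both).
#' @return A non-negative scalar.
#' @export
cluster_quality <- function(records, directions = c("over", "under")) {
  p <- if (is.numeric(records)) records else {
    if (nrow(records) == 0L) return(0)
    records$p_value[records$direction %in% directions]
  }
  if (length(p) == 0L) return(0)
  sum(-log10(p))
}
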