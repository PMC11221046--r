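#' Per-module and framework enrichment quality
#'
#' Module j's quality is the mean of -log10 p over its n_j retained terms,
#' and the framework quality Q_f is the mean of those module qualities over
#' modules with at least one retained term (empty modules are excluded from
#' the mean, their count logged).
#'
#' @param table A `"coex_enrichment"` tibble (any table with `cluster` and
#'   `p_value` columns works).
#' @return A list of class `"coex_report"`: `module_quality` (tibble
#'   `module`, `n_terms`, `quality`), `framework_quality` (Q_f),
#'   `pooled_mean` (mean of -log10 p over all records pooled), `pooled_p`
#'   (sorted), `top100_p`, plus the prominent-module fields of
#'   [prominent_module()].
#' @export
framework_quality <- function(table) {
  if (nrow(table) == 0L) stop("empty enrichment table", call. = FALSE)
  mq <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table), module = .data$cluster),
    n_terms = dplyr::n(),
    quality = mean(-log10(.data$p_value)),
    .groups = "drop"
  )
  n_empty <- length(setdiff(unique(table$cluster), mq$module))
  if (n_empty > 0) message(n_empty, " module(s) without retained terms ",
                           "excluded from the framework mean")
  pooled <- sort(table$p_value)
  prom <- prominent_module(table)
  structure(
    list(module_quality = mq,
         framework_quality = mean(mq$quality),
         pooled_mean = mean(-log10(pooled)),
         pooled_p = pooled,
         top100_p = utils::head(pooled, 100L),
         prominent = prom$module,
         prominent_top10_p = prom$top10_p,
         prominent_top100_terms = prom$top100_terms),
    class = "coex_report"
  )
}

#' @export
print.coex_report <- function(x, ...) {
  cat("Enrichment report:", nrow(x$module_quality), "modules | Q_f =",
      format(x$framework_quality, digits = 4), "\n")
  cat("  prominent module:", x$prominent, "(min p =",
      format(min(x$pooled_p), digits = 3), ")\n")
  invisible(x)
}

#' Prominent module and its top term lists
#'
#' The prominent module is the one containing the most significant
#' (globally smallest) p-value; ties go to the smaller module id. Returns
#' its ten most significant p-values and its top-100 unique term ids (a
#' term tested in both directions counts once, keeping its smaller p).
#'
#' @param table An enrichment tibble with `cluster`, `term`, `p_value`.
#' @return A list: `module`, `top10_p`, `top100_terms`.
#' @export
prominent_module <- function(table) {
  if (nrow(table) == 0L) stop("empty enrichment table", call. = FALSE)
  best <- table[order(table$p_value, table$cluster), ][1L, ]
  mod <- best$cluster
  rec <- table[table$cluster == mod, , drop = FALSE]
  uniq <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(rec), .data$term),
                           p_value = min(.data$p_value), .groups = "drop")
  uniq <- uniq[order(uniq$p_value, uniq$term), ]
  list(module = mod,
       top10_p = utils::head(sort(rec$p_value), 10L),
       top100_terms = utils::head(uniq$term, 100L))
}

#' Overlap between two frameworks' top term sets
#'
#' Number of term ids shared by the two reports' top-100 unique term lists
#' of their prominent modules.
#'
#' @param report_a,report_b `"coex_report"` objects (or lists carrying a
#'   `prominent_top100_terms` character vector).
#' @return An integer in [0, 100].
#' @export
term_overlap <- function(report_a, report_b) {
  length(intersect(report_a$prominent_top100_terms,
                   report_b$prominent_top100_terms))
}
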