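#' Eigenvalue spectrum and eigengap profiles
#'
#' Scree-style diagnostic: the leading eigenvalues of the random-walk
#' operator with the three eigengap profiles underneath, so the chosen
#' cluster count can be judged by eye.
#'
#' @param sd A `"coex_spectrum"` object.
#' @param ck Optional `"coex_candidates"` object; when supplied the three
#'   candidate counts are marked.
#' @param n_show Number of leading eigenvalues to display (default 30).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(sd, ck = NULL, n_show = 30L) {
  n_show <- min(n_show, length(sd$values))
  df <- tibble::tibble(index = seq_len(n_show),
                       eigenvalue = sd$values[seq_len(n_show)])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$eigenvalue)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "index", y = "eigenvalue",
                  title = "Random-walk operator spectrum") +
    ggplot2::theme_minimal()
  if (!is.null(ck)) {
    marks <- tibble::tibble(
      k = c(ck$k_ag, ck$k_rg, ck$k_sg),
      method = c("additive", "relative", "second-order")
    )
    p <- p + ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$k, colour = .data$method),
      linetype = "dashed"
    ) + ggplot2::labs(colour = "eigengap")
  }
  p
}

#' Per-cluster conductance bars
#'
#' @param conductances A tibble from [cluster_conductances()] (or a
#'   `"coex_fit"`, whose chosen clustering's conductances are used).
#' @return A ggplot object.
#' @export
plot_conductance <- function(conductances) {
  if (inherits(conductances, "coex_fit")) {
    conductances <- conductances$conductances
  }
  ggplot2::ggplot(conductances,
                  ggplot2::aes(factor(.data$cluster), .data$conductance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cluster", y = "conductance",
                  title = "Cluster separation (lower is better)") +
    ggplot2::theme_minimal()
}

#' Enrichment significance per module
#'
#' Jittered -log10 p-values of the retained records of each module,
#' mirroring the usual enrichment-distribution diagnostic.
#'
#' @param table A `"coex_enrichment"` tibble (or a `"coex_fit"`, whose
#'   final-module enrichment is used).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(table) {
  if (inherits(table, "coex_fit")) table <- table$final_enrichment
  ggplot2::ggplot(tibble::as_tibble(table),
                  ggplot2::aes(factor(.data$cluster), -log10(.data$p_value))) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5, size = 1) +
    ggplot2::labs(x = "module", y = expression(-log[10]~p),
                  title = "Module enrichment") +
    ggplot2::theme_minimal()
}

#' @rdname plot_spectrum
#' @param object A `"coex_spectrum"` object.
#' @param ... Passed on to [plot_spectrum()].
#' @exportS3Method ggplot2::autoplot
autoplot.coex_spectrum <- function(object, ...) plot_spectrum(object, ...)

#' @rdname plot_enrichment
#' @param object A `"coex_enrichment"` table.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.coex_enrichment <- function(object, ...) plot_enrichment(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
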