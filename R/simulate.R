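#' Planted-module simulation design
#'
#' Describes a synthetic study: block-structured expression (each module's
#' genes share a latent sample profile) plus a matched annotation set in
#' which each module is over-represented for its own signature terms on a
#' background of unrelated terms. The defaults define a 4 x 100-gene,
#' 30-sample study with within-module correlation 0.8 and leading signature
#' coverage 0.6.
#'
#' @param m_per_module Integer vector of module sizes.
#' @param n_samples Number of samples.
#' @param within_corr Target correlation between genes of the same module,
#'   in (0, 1).
#' @param n_terms_per_module Signature terms planted per module.
#' @param term_coverage Coverage of a module's strongest signature term
#'   (fraction of its genes annotated).
#' @param coverage_taper Per-term multipliers on `term_coverage` for the
#'   module's successive signature terms; defaults to a linear ladder from
#'   1 down to 0.4, emulating the spread of term significance seen in real
#'   annotation sets (set to `rep(1, n_terms_per_module)` for uniform
#'   coverage).
#' @param signature_background Number of out-of-module genes each signature
#'   term additionally annotates (default 0).
#' @param background_terms Number of unrelated terms annotating genes
#'   uniformly at random.
#' @param background_size Integer range (length 2) of background term sizes.
#' @param seed Integer seed making the whole design reproducible.
#' @return A list of class `"coex_design"`.
#' @export
planted_design <- function(m_per_module = c(100L, 100L, 100L, 100L),
                           n_samples = 30L,
                           within_corr = 0.8,
                           n_terms_per_module = 5L,
                           term_coverage = 0.6,
                           coverage_taper = NULL,
                           signature_background = 0L,
                           background_terms = 200L,
                           background_size = c(10L, 40L),
                           seed = 1L) {
  if (!(within_corr > 0 && within_corr < 1)) {
    stop("`within_corr` must be in (0, 1)", call. = FALSE)
  }
  if (!(term_coverage > 0 && term_coverage <= 1)) {
    stop("`term_coverage` must be in (0, 1]", call. = FALSE)
  }
  if (is.null(coverage_taper)) {
    coverage_taper <- seq(1, 0.4, length.out = n_terms_per_module)
  }
  if (length(coverage_taper) != n_terms_per_module) {
    stop("`coverage_taper` must have one entry per signature term",
         call. = FALSE)
  }
  structure(
    list(m_per_module = as.integer(m_per_module),
         n_samples = as.integer(n_samples),
         within_corr = within_corr,
         n_terms_per_module = as.integer(n_terms_per_module),
         term_coverage = term_coverage,
         coverage_taper = coverage_taper,
         signature_background = as.integer(signature_background),
         background_terms = as.integer(background_terms),
         background_size = as.integer(background_size),
         seed = as.integer(seed)),
    class = "coex_design"
  )
}

#' Simulate a planted-module expression matrix
#'
#' Each module m gets a latent sample profile z_m; every member gene is
#' `sqrt(rho) * z_m + sqrt(1 - rho) * noise`, giving within-module
#' correlation `rho = within_corr`. The latent profiles are drawn Gaussian
#' and then orthogonalized (QR) so that between-module correlations are
#' near zero by construction rather than only in expectation — with few
#' samples, independent draws can be correlated enough by chance to merge
#' two modules, which is not what a planted design is meant to emulate.
#' Generation is O(m n) and deterministic given the design seed.
#'
#' @param design A `"coex_design"` from [planted_design()].
#' @return A list: `expression` (tibble, `gene_id` + one column per sample),
#'   `labels` (named integer vector of true module memberships).
#' @export
simulate_expression <- function(design) {
  sizes <- design$m_per_module
  m <- sum(sizes)
  n <- design$n_samples
  rho <- design$within_corr
  if (length(sizes) > n) {
    stop("cannot plant more modules than samples: mutually uncorrelated ",
         "latent profiles need n_samples >= number of modules", call. = FALSE)
  }
  withr::with_seed(design$seed, {
    mat <- matrix(0, m, n)
    labels <- rep(seq_along(sizes), sizes)
    # orthogonalized latent profiles, rescaled to unit sample variance
    z_raw <- matrix(stats::rnorm(n * length(sizes)), n, length(sizes))
    z_all <- qr.Q(qr(z_raw)) * sqrt(n)
    row <- 0L
    for (b in seq_along(sizes)) {
      z <- z_all[, b]
      for (i in seq_len(sizes[b])) {
        row <- row + 1L
        mat[row, ] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
      }
    }
    gene_ids <- sprintf("g%04d", seq_len(m))
    rownames(mat) <- gene_ids
    colnames(mat) <- sprintf("s%02d", seq_len(n))
    names(labels) <- gene_ids
    list(
      expression = tibble::as_tibble(mat, rownames = "gene_id"),
      labels = labels
    )
  })
}

#' Simulate a matched synthetic annotation set
#'
#' Plants `n_terms_per_module` signature terms per module: the leading term
#' annotates a `term_coverage` fraction of the module's genes and successive
#' terms taper linearly to 40% of that coverage (deterministic counts,
#' random gene subsets), so each module carries a spread of strongly to
#' moderately over-represented terms, as real annotation sets do. Background
#' terms annotate uniform random genes. Term ids use a synthetic "SYN:"
#' vocabulary and namespaces rotate over BP/CC/MF so all six enrichment
#' queries are exercised.
#'
#' @param design A `"coex_design"`.
#' @param labels Named integer vector of true module labels (from
#'   [simulate_expression()]).
#' @param degrade_modules Integer vector of module ids whose signature terms
#'   are withheld (the module keeps only background annotation), emulating a
#'   biologically incoherent cluster.
#' @return A tibble (`gene`, `term`, `namespace`) of class
#'   `"coex_synthetic_annotation"`, with the signature-term map in attribute
#'   `"signature_terms"`.
#' @export
simulate_annotation <- function(design, labels, degrade_modules = integer(0)) {
  genes <- names(labels)
  mods <- sort(unique(labels))
  ns_cycle <- c("BP", "CC", "MF")
  withr::with_seed(design$seed + 1L, {
    rows <- list()
    sig_map <- list()
    term_no <- 0L
    taper <- design$coverage_taper
    for (b in mods) {
      members <- genes[labels == b]
      if (b %in% degrade_modules) next
      for (t in seq_len(design$n_terms_per_module)) {
        term_no <- term_no + 1L
        id <- sprintf("SYN:%07d", term_no)
        n_cov <- max(1L, round(design$term_coverage * taper[t] *
                                 length(members)))
        ann_genes <- sample(members, n_cov)
        if (design$signature_background > 0L) {
          outside <- setdiff(genes, members)
          ann_genes <- c(ann_genes,
                         sample(outside, min(design$signature_background,
                                             length(outside))))
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene = ann_genes, term = id,
          namespace = ns_cycle[(term_no - 1L) %% 3L + 1L]
        )
        sig_map[[id]] <- b
      }
    }
    for (t in seq_len(design$background_terms)) {
      term_no <- term_no + 1L
      id <- sprintf("SYN:%07d", term_no)
      sz <- sample(design$background_size[1]:design$background_size[2], 1L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = sample(genes, sz), term = id,
        namespace = ns_cycle[(term_no - 1L) %% 3L + 1L]
      )
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "signature_terms") <- sig_map
    class(out) <- c("coex_synthetic_annotation", class(out))
    out
  })
}
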