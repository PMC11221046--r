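# embedding with two well-separated clouds on the unit circle
cloud_embedding <- function(n_per = 40L, seed = 1L, spread = 0.05) {
  withr::with_seed(seed, {
    ang <- c(rnorm(n_per, 0, spread), rnorm(n_per, pi, spread))
    x <- cbind(cos(ang), sin(ang))
    fake_embedding(x, k = 1L, ids = sprintf("g%03d", seq_len(2L * n_per)))
  })
}

make_sl <- function(ids, labels_all, train_idx) {
  kept <- sort(unique(labels_all[train_idx]))
  map <- setNames(seq_along(kept), kept)
  structure(list(
    remarkable = setNames(map[as.character(labels_all[train_idx])],
                          ids[train_idx]),
    unremarkable = ids[-train_idx],
    k_prime = length(kept),
    label_map = map,
    selected = tibble::tibble()), class = "coex_semilabel")
}

test_that("points near a training cloud inherit its label", {
  e <- cloud_embedding()
  ids <- e$gene_ids
  truth <- rep(1:2, each = 40)
  train <- c(1:30, 41:70)              # withhold 10 per cloud
  sl <- make_sl(ids, truth, train)
  ms <- train_and_classify(e, sl, seed = 3L,
                           initial_labels = setNames(truth, ids))
  expect_identical(unname(ms$labels[ids[31:40]]), rep(1L, 10))
  expect_identical(unname(ms$labels[ids[71:80]]), rep(2L, 10))
  # training labels never change
  expect_identical(ms$labels[names(sl$remarkable)], sl$remarkable)
  expect_equal(ms$changed_fraction, 0)
})

test_that("classification is deterministic given the seed", {
  e <- cloud_embedding(seed = 7L, spread = 0.4)
  truth <- rep(1:2, each = 40)
  sl <- make_sl(e$gene_ids, truth, c(1:25, 41:65))
  ms1 <- train_and_classify(e, sl, seed = 11L)
  ms2 <- train_and_classify(e, sl, seed = 11L)
  expect_identical(ms1$labels, ms2$labels)
  expect_identical(ms1$chosen_hyperparam, ms2$chosen_hyperparam)
})

test_that("degenerate cases: no unremarkable genes, single class", {
  e <- cloud_embedding()
  truth <- rep(1:2, each = 40)
  sl_all <- make_sl(e$gene_ids, truth, seq_len(80))
  ms <- train_and_classify(e, sl_all, seed = 1L,
                           initial_labels = setNames(truth, e$gene_ids))
  expect_identical(unname(ms$labels), truth)
  expect_equal(ms$changed_fraction, 0)

  sl_one <- make_sl(e$gene_ids, rep(1L, 80), 1:40)
  expect_warning(ms1 <- train_and_classify(e, sl_one, seed = 1L), "single")
  expect_true(all(ms1$labels == 1L))
})

test_that("tiny training sets re-floor the neighbour grid with a warning", {
  e <- cloud_embedding(n_per = 8L)
  truth <- rep(1:2, each = 8)
  sl <- make_sl(e$gene_ids, truth, c(1:4, 9:12))   # 8 training points < 20
  expect_warning(ms <- train_and_classify(e, sl, seed = 2L), "floor")
  expect_lte(ms$chosen_hyperparam, 7)
  expect_identical(unname(ms$labels[5:8]), rep(1L, 4))
})

test_that("logistic one-vs-rest also separates the clouds", {
  e <- cloud_embedding()
  truth <- rep(1:2, each = 40)
  sl <- make_sl(e$gene_ids, truth, c(1:30, 41:70))
  ms <- train_and_classify(e, sl, kind = "logistic", seed = 5L)
  expect_identical(unname(ms$labels), truth)
  expect_identical(ms$classifier_kind, "logistic")
})

test_that("withheld labels on the planted embedding are recovered", {
  d <- planted_design(seed = 51L)
  sim <- simulate_expression(d)
  net <- build_network(as_expression_matrix(sim$expression))
  sd <- spectral_decompose(net$adjacency)
  e <- build_embedding(sd, 4L)
  accs <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      hide <- sample(400L, 80L)     # withhold 20% of genes
      sl <- make_sl(e$gene_ids, unname(sim$labels), setdiff(1:400, hide))
      ms <- train_and_classify(e, sl, seed = s)
      mean(ms$labels[e$gene_ids[hide]] == sim$labels[hide])
    })
  }, numeric(1))
  expect_true(all(accs >= 0.9))
})

test_that("refinement summary reports %UNR and %CH arithmetic", {
  ids <- sprintf("g%02d", 1:10)
  clustering <- structure(list(labels = setNames(rep(1:2, each = 5), ids),
                               k = 2L, gene_ids = ids),
                          class = "coex_clustering")
  sl <- structure(list(remarkable = setNames(c(1L, 1L, 2L, 2L, 2L),
                                             ids[c(1, 2, 6, 7, 8)]),
                       unremarkable = ids[c(3, 4, 5, 9, 10)],
                       k_prime = 2L,
                       label_map = setNames(1:2, 1:2)),
                  class = "coex_semilabel")
  ms <- structure(list(labels = setNames(rep(1:2, each = 5), ids),
                       k_prime = 2L, classifier_kind = "knn",
                       chosen_hyperparam = 20),
                  class = "coex_modules")
  out <- summarize_refinement(clustering, sl, ms)
  expect_equal(out$pct_unremarkable, 50)
  expect_equal(out$pct_changed, 0)
  expect_false(out$all_remarkable)

  # one relabeled unremarkable gene -> 20% changed
  ms$labels[ids[3]] <- 2L
  expect_equal(summarize_refinement(clustering, sl, ms)$pct_changed, 20)

  # all remarkable: %CH reported as 0 with the flag set
  sl_all <- sl
  sl_all$remarkable <- setNames(rep(1:2, each = 5), ids)
  sl_all$unremarkable <- character(0)
  out_all <- summarize_refinement(clustering, sl_all, ms)
  expect_equal(out_all$pct_unremarkable, 0)
  expect_equal(out_all$pct_changed, 0)
  expect_true(out_all$all_remarkable)

  # genes of a dropped cluster count as changed wherever they land
  sl_drop <- sl
  sl_drop$label_map <- setNames(1L, 1L)   # cluster 2 dropped
  sl_drop$k_prime <- 1L
  sl_drop$remarkable <- setNames(c(1L, 1L), ids[1:2])
  sl_drop$unremarkable <- ids[3:10]
  ms_drop <- ms
  ms_drop$labels <- setNames(rep(1L, 10), ids)
  ms_drop$k_prime <- 1L
  out_drop <- summarize_refinement(clustering, sl_drop, ms_drop)
  # unremarkable = g03..g10; the five cluster-2 genes have no mapped label
  expect_equal(out_drop$pct_changed, 100 * 5 / 8)
})
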