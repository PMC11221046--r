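test_that("annotation tables parse, restrict and deduplicate", {
  df <- data.frame(gene = c("g1", "g2", "g3", "g3", "g9"),
                   term = c("T1", "T1", "T2", "T2", "T1"))
  ann <- as_annotation(df, universe = c("g1", "g2", "g3", "g4"))
  expect_equal(nrow(ann$table), 3L)   # duplicate collapsed, g9 outside
  expect_setequal(unique(ann$table$gene), c("g1", "g2", "g3"))
  expect_equal(ann$terms$size[ann$terms$term == "T1"], 2L)
  expect_error(as_annotation(df, universe = c("x1", "x2")), "overlap")
})

test_that("TSV and GAF annotation files load, skipping NOT qualifiers", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("g1\tT1\tBP", "g2\tT1\tBP", "g3\tT2\tMF"), tsv)
  ann <- suppressMessages(read_annotation(tsv, c("g1", "g2", "g3", "g4")))
  expect_equal(nrow(ann$table), 3L)
  expect_equal(sort(unique(ann$table$namespace)), c("BP", "MF"))

  gaf <- tempfile(fileext = ".gaf")
  row <- function(gene, term, qual, aspect) {
    paste(c("DB", paste0("ID", gene), gene, qual, term, "REF", "IEA", "",
            aspect, "", "", "protein", "taxon:9606", "20200101", "DB",
            "", ""), collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.2",
               row("g1", "GO:0000001", "", "P"),
               row("g2", "GO:0000001", "NOT", "P"),
               row("g3", "GO:0000002", "involved_in", "F")), gaf)
  ann2 <- suppressMessages(read_annotation(gaf, c("g1", "g2", "g3")))
  expect_equal(nrow(ann2$table), 2L)       # NOT-qualified row skipped
  expect_false("g2" %in% ann2$table$gene)
  expect_equal(ann2$table$namespace[ann2$table$gene == "g3"], "MF")
})

test_that("hypergeometric worked example and trivial tails are exact", {
  uni <- sprintf("u%02d", 1:20)
  term <- uni[1:5]
  clus <- uni[c(1:5, 6:10)]          # x = 5, n = 10
  over <- hypergeom_test(clus, term, uni, "over")
  expect_equal(over$p_value, 3003 / 184756, tolerance = 1e-12)
  expect_equal(over$expected_count, 2.5)
  expect_identical(over$count, 5L)

  # x = 0: over-representation p is the certain event
  clus0 <- uni[6:15]
  over0 <- hypergeom_test(clus0, term, uni, "over")
  expect_equal(over0$p_value, 1)
  expect_equal(over0$odds_ratio, 0)
})

test_that("hypergeometric p matches the tail-sum oracle on random set cases", {
  set.seed(31)
  for (rep in 1:50) {
    N <- sample(5:40, 1)
    uni <- sprintf("u%02d", seq_len(N))
    K <- sample(N, 1); n <- sample(N, 1)
    term <- sample(uni, K)
    clus <- sample(uni, n)
    x <- length(intersect(term, clus))
    for (dir in c("over", "under")) {
      got <- hypergeom_test(clus, term, uni, dir)
      expect_equal(got$p_value, hyper_tail_oracle(x, K, N, n, dir),
                   tolerance = 1e-12)
    }
    # odds ratio conventions
    got <- hypergeom_test(clus, term, uni, "over")
    den <- (K - x) * (n - x)
    if (x == 0) expect_equal(got$odds_ratio, 0)
    else if (den == 0) expect_identical(got$odds_ratio, Inf)
    else expect_equal(got$odds_ratio, x * (N - K - n + x) / den)
  }
})

test_that("over-p decreases and under-p increases in the overlap", {
  N <- 30; K <- 8; n <- 12
  uni <- sprintf("u%02d", seq_len(N))
  term <- uni[1:K]
  for (x in 1:K) {
    clus <- c(uni[seq_len(x)], uni[(K + 1):(K + n - x)])
    over_now <- hypergeom_test(clus, term, uni, "over")$p_value
    under_now <- hypergeom_test(clus, term, uni, "under")$p_value
    if (x > 1) {
      expect_lte(over_now, over_prev + 1e-15)
      expect_gte(under_now, under_prev - 1e-15)
    }
    # shared atom: the two tails overlap at P[X = x]
    expect_gte(over_now + under_now, 1 - 1e-12)
    over_prev <- over_now; under_prev <- under_now
  }
})

test_that("enrich_clusters retains everything at cutoff 1 and sorts by p", {
  set.seed(32)
  genes <- sprintf("g%03d", 1:60)
  labels <- setNames(rep(1:2, each = 30), genes)
  ann <- as_annotation(
    data.frame(gene = sample(genes, 120, replace = TRUE),
               term = sample(paste0("T", 1:8), 120, replace = TRUE),
               ns = sample(c("BP", "CC", "MF"), 120, replace = TRUE)),
    universe = genes)
  tab <- enrich_clusters(labels, ann, p_cutoff = 1)
  # every (cluster, term-with-overlap, direction) appears exactly once
  for (cl in 1:2) {
    present <- unique(ann$table$term[ann$table$gene %in% genes[labels == cl]])
    expect_equal(sum(tab$cluster == cl), 2L * length(present))
    p_cl <- tab$p_value[tab$cluster == cl]
    expect_true(!is.unsorted(p_cl))
  }
  expect_true(all(tab$count <= tab$size))
  # at most one record per (cluster, term, direction)
  expect_false(any(duplicated(tab[, c("cluster", "term", "direction")])))
})

test_that("enrichment is invariant under consistent gene renaming", {
  set.seed(33)
  genes <- sprintf("g%03d", 1:40)
  labels <- setNames(sample(1:2, 40, TRUE), genes)
  df <- data.frame(gene = sample(genes, 80, TRUE),
                   term = sample(paste0("T", 1:5), 80, TRUE))
  tab1 <- enrich_clusters(labels, as_annotation(df, genes), p_cutoff = 1)
  ren <- setNames(sprintf("x%03d", 1:40), genes)
  labels2 <- setNames(labels, ren[names(labels)])
  df2 <- transform(df, gene = ren[gene])
  tab2 <- enrich_clusters(labels2, as_annotation(df2, unname(ren)),
                          p_cutoff = 1)
  expect_equal(tab1$p_value, tab2$p_value)
  expect_equal(tab1$term, tab2$term)
})

test_that("random label permutation destroys planted enrichment", {
  set.seed(34)
  d <- planted_design(m_per_module = c(40L, 40L), n_samples = 10L,
                      n_terms_per_module = 2L, background_terms = 0L,
                      seed = 34L)
  sim <- simulate_expression(d)
  ann <- as_annotation(simulate_annotation(d, sim$labels),
                       names(sim$labels))
  planted_min <- min(enrich_clusters(sim$labels, ann, p_cutoff = 1)$p_value)
  expect_lt(planted_min, 1e-8)
  hits <- 0L
  for (i in 1:40) {
    perm <- setNames(sample(sim$labels), names(sim$labels))
    tab <- enrich_clusters(perm, ann, p_cutoff = 1)
    if (min(tab$p_value[tab$direction == "over"]) > 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 0.95 * 40 - 3)  # ~95% of permutations lose significance
})

test_that("cluster quality is the sum of -log10 p", {
  expect_equal(cluster_quality(c(1e-3, 1e-5)), 8)
  expect_equal(cluster_quality(numeric(0)), 0)
  expect_equal(cluster_quality(c(1e-3, 1e-5, 0.1)), 9)
  rec <- tibble::tibble(p_value = c(1e-2, 1e-4),
                        direction = c("over", "under"))
  expect_equal(cluster_quality(rec), 6)
  expect_equal(cluster_quality(rec, directions = "over"), 2)
  expect_equal(cluster_quality(rec[0, ]), 0)
})
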