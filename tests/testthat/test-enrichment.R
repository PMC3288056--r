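test_that("EASE score jackknifes one list hit and is conservative", {
  expect_equal(ease_score(0, 10, 20, 100), 1)
  expect_equal(ease_score(1, 10, 20, 100), 1)  # jackknifed count is 0
  # equals brute-force tail enumeration from k - 1
  expect_equal(ease_score(8, 20, 50, 1000),
               oracle_hyper_tail(7, 20, 50, 1000), tolerance = 1e-12)
  # conservative relative to plain Fisher for k >= 1
  set.seed(1)
  for (rep in 1:200) {
    N <- sample(5:80, 1); n <- sample(1:N, 1); K <- sample(1:N, 1)
    k <- sample(seq_len(min(n, K)), 1)
    expect_gte(ease_score(k, K, n, N), fisher_exact(k, K, n, N))
  }
  expect_error(ease_score(10, 5, 8, 20), "margins")
})

test_that("one-tailed Fisher matches closed forms, enumeration and fisher.test", {
  expect_equal(fisher_exact(3, 3, 3, 3), 1)       # degenerate table
  expect_equal(fisher_exact(3, 3, 3, 10), 1 / 120)
  set.seed(2)
  for (rep in 1:100) {
    N <- sample(4:40, 1); n <- sample(1:N, 1); K <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(fisher_exact(k, K, n, N), oracle_hyper_tail(k, K, n, N),
                 tolerance = 1e-10)
  }
  # cross-check against stats::fisher.test one-sided p on a 2x2 table
  k <- 8; K <- 20; n <- 50; N <- 1000
  ft <- fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                    alternative = "greater")
  expect_equal(fisher_exact(k, K, n, N), ft$p.value, tolerance = 1e-9)
})

test_that("fold enrichment is frequency ratio against the universe", {
  expect_equal(fold_enrichment(5, 50, 100, 1000), 1)  # k/n == K/N
  expect_equal(fold_enrichment(31, 31, 1817, 1817 * 5), 5)
  expect_error(fold_enrichment(0, 0, 10, 100), "undefined")
  set.seed(3)
  for (rep in 1:50) {
    N <- sample(10:1000, 1); n <- sample(1:N, 1); K <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(fold_enrichment(k, K, n, N), (k / n) / (K / N))
  }
})

test_that("Benjamini-Hochberg equals the quadratic brute force", {
  expect_equal(benjamini_hochberg(0.03), 0.03)   # single p unchanged
  expect_equal(benjamini_hochberg(rep(0.2, 7)), rep(0.2, 7))
  set.seed(4)
  for (rep in 1:20) {
    p <- runif(20)
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))                       # never below raw
    expect_identical(order(adj[order(p)]),           # monotone in p order
                     seq_along(p))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrich builds margins, filters, and adjusts per category", {
  universe <- sprintf("U%03d", 1:100)
  lst <- universe[1:20]
  terms <- list(
    annotation_set("hit", "planted", c(universe[1:10], universe[90:99]),
                   "biological_process"),
    annotation_set("small", "below threshold",
                   c(universe[1:4], universe[50:60]),
                   "biological_process"),
    annotation_set("cc", "other category", universe[5:30],
                   "cellular_component"))
  res <- enrich(lst, terms, universe = universe, min_count = 5,
                ease_max = 0.5)
  expect_false("small" %in% res$term_id)  # k = 4 < min_count
  hit <- res[res$term_id == "hit", ]
  expect_equal(hit$k, 10)
  expect_equal(hit$K, 20)
  expect_equal(hit$n, 20)
  expect_equal(hit$N, 100)
  expect_equal(hit$pct, 50)
  expect_equal(hit$fold, (10 / 20) / (20 / 100))
  # Benjamini is computed within category over all tested terms
  tested <- attr(res, "tested")
  bp <- tested[tested$category == "biological_process", ]
  expect_equal(bp$benjamini, benjamini_hochberg(bp$p_ease))
  cc <- tested[tested$category == "cellular_component", ]
  expect_equal(cc$benjamini, benjamini_hochberg(cc$p_ease))
  # sorted by EASE ascending
  expect_false(is.unsorted(res$p_ease))
})

test_that("percent count reports list-share of protein species", {
  universe <- sprintf("U%04d", 1:3000)
  lst <- universe[1:1817]
  term <- annotation_set("t", "pathway-sized term",
                         c(lst[1:31], universe[2900:3000]), "pathway")
  res <- enrich(lst, list(term), universe = universe, min_count = 5,
                ease_max = 1)
  expect_equal(res$k, 31)
  expect_equal(res$n, 1817)
  expect_equal(res$pct, 1.7)
})

test_that("a term planted at fold 3 is recovered as significant", {
  sim <- simulate_annotations(universe_size = 3000, list_size = 300,
                              n_terms = 100, term_size = 150,
                              planted_folds = 3, seed = 99)
  res <- enrich(sim$list_symbols, sim$terms, universe = sim$universe,
                min_count = 5, ease_max = 0.1)
  planted <- res[res$term_id == sim$planted, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$k, round(3 * 150 * 300 / 3000))
  expect_lt(planted$benjamini, 0.05)
})

test_that("a uniformly random list yields essentially no discoveries", {
  set.seed(5)
  false_frac <- replicate(20, {
    seed <- sample.int(1e6, 1)
    sim <- simulate_annotations(universe_size = 1000, list_size = 100,
                                n_terms = 50, term_size = 50,
                                planted_folds = numeric(), seed = seed)
    tested <- attr(enrich(sim$list_symbols, sim$terms,
                          universe = sim$universe, min_count = 1,
                          ease_max = 1), "tested")
    mean(tested$benjamini < 0.05)
  })
  expect_lte(mean(false_frac), 0.05)
})

test_that("symbols outside the universe are dropped with a message", {
  universe <- c("Aaa", "Bbb", "Ccc")
  term <- annotation_set("t", "d", c("Aaa", "Bbb"))
  expect_message(
    res <- enrich(c("Aaa", "Zzz"), list(term), universe = universe,
                  min_count = 1, ease_max = 1),
    "outside the universe")
  expect_equal(res$n, 1)
  expect_error(enrich(character(), list(term), universe = character()),
               "empty")
})
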