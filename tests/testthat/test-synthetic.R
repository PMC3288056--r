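small_truth <- function(seed = 1, ...) {
  synthetic_truth(n_true = 200, n_contaminant = 40, n_matrix = 10,
                  depth = 2e4, depth_hss = 2e4, depth_laminin = 1000,
                  universe_size = 400, list_size = 100, n_terms = 20,
                  term_size = 40, seed = seed, ...)
}

test_that("generation is fully reproducible from the seed", {
  a <- generate_dataset(small_truth(seed = 5))
  b <- generate_dataset(small_truth(seed = 5))
  expect_identical(as.data.frame(a$counts), as.data.frame(b$counts))
  expect_identical(a$annotations$terms, b$annotations$terms)
  expect_identical(lapply(a$panels, as.data.frame),
                   lapply(b$panels, as.data.frame))
  c <- generate_dataset(small_truth(seed = 6))
  expect_false(identical(as.data.frame(a$counts), as.data.frame(c$counts)))
})

test_that("column sums equal the configured depths exactly", {
  truth <- small_truth(seed = 2)
  ds <- generate_dataset(truth)
  expect_equal(sum(ds$counts$gcp), truth$depth)
  expect_equal(sum(ds$counts$hss), truth$depth_hss)
  expect_equal(sum(ds$counts$laminin), truth$depth_laminin)
})

test_that("phi = 0 sends no gross spectra to contaminants", {
  truth <- small_truth(seed = 3, phi = 0)
  ds <- generate_dataset(truth)
  cont <- ds$counts$symbol %in% truth$contaminants
  expect_true(all(ds$counts$gcp[cont] == 0))
})

test_that("with no backgrounds the net proteome is the gross proteome", {
  truth <- synthetic_truth(n_true = 200, n_contaminant = 2, n_matrix = 0,
                           phi = 0, depth = 2e4, depth_hss = 1000,
                           depth_laminin = 0, seed = 4)
  ds <- generate_dataset(truth)
  net <- subtract_background(ds$counts, 0)
  pos <- ds$counts$symbol[ds$counts$gcp > 0]
  expect_setequal(names(net$net_counts), pos)
})

test_that("empirical contaminant share of gross spectra matches phi", {
  shares <- vapply(1:10, function(s) {
    truth <- synthetic_truth(seed = s)  # defaults: phi 0.3, depth 1e5
    ds <- generate_dataset(truth)
    cont <- ds$counts$symbol %in% truth$contaminants
    sum(ds$counts$gcp[cont]) / sum(ds$counts$gcp)
  }, 0)
  expect_true(all(abs(shares - 0.3) < 0.02))
})

test_that("perfect subtraction on noise-free counts excludes all contaminants", {
  # deterministic expected counts instead of a multinomial draw
  p_true <- (1:50)^-1.1; p_true <- p_true / sum(p_true)
  p_hss <- (1:10)^-1.1; p_hss <- p_hss / sum(p_hss)
  phi <- 0.3; depth <- 1e4
  hss_cont <- depth * p_hss
  tab <- spectral_count_table(
    protein_id = c(sprintf("T%02d", 1:50), sprintf("C%02d", 1:10)),
    symbol = c(sprintf("T%02d", 1:50), sprintf("C%02d", 1:10)),
    gcp = c(depth * (1 - phi) * p_true, phi * hss_cont),
    laminin = rep(0, 60),
    hss = c(rep(0, 50), hss_cont))
  net <- subtract_background(tab, phi)
  expect_setequal(names(net$excluded), sprintf("C%02d", 1:10))
  expect_setequal(names(net$net_counts), sprintf("T%02d", 1:50))
})

test_that("planted annotation terms realize their target fold", {
  sim <- simulate_annotations(universe_size = 1000, list_size = 200,
                              n_terms = 5, term_size = 100,
                              planted_folds = c(2, 3), seed = 10)
  for (i in 1:2) {
    k <- sum(sim$list_symbols %in% sim$terms[[sim$planted[i]]]$members)
    expect_equal(k, round(c(2, 3)[i] * 100 * 200 / 1000))
  }
  expect_error(
    simulate_annotations(universe_size = 100, list_size = 90,
                         term_size = 60, planted_folds = 10, seed = 1),
    "inconsistent")
})

test_that("recovery metrics summarize a full synthetic run", {
  truth <- small_truth(seed = 12)
  ds <- generate_dataset(truth)
  cal <- compute_calibration_multipliers(ds$counts, truth$calibration_ids)
  net <- subtract_background(ds$counts, cal$mean)
  res <- enrich(ds$annotations$list_symbols, ds$annotations$terms,
                universe = ds$annotations$universe, min_count = 5,
                ease_max = 1)
  rec <- evaluate_recovery(net, cal, res, truth,
                           annotations = ds$annotations)
  expect_lt(rec$multiplier_rel_error, 0.25)       # small fixture, noisier
  expect_gte(rec$contaminant_sensitivity, 0)
  expect_lte(rec$contaminant_sensitivity, 1)
  expect_gt(rec$true_retention, 0.9)
  expect_gt(rec$contaminant_spectra_eliminated, 0.9)
  expect_equal(rec$planted_recovery, 1)           # fold-3 term found
  expect_lte(rec$false_recovery, 0.1)
})
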