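calib_table <- function() {
  spectral_count_table(c("p1", "p2", "p3"), c("Alb", "Afp", "Gap43"),
                       gcp = c(29, 34, 500), laminin = c(0, 0, 10),
                       hss = c(100, 100, 0))
}

test_that("calibration multipliers zero each calibration protein", {
  cal <- compute_calibration_multipliers(calib_table(), c("Alb", "Afp"))
  expect_equal(unname(cal$per_protein), c(0.29, 0.34))
  expect_equal(cal$mean, 0.315)

  # a protein with equal gcp and hss counts gives multiplier 1
  tab <- spectral_count_table("p1", "Alb", gcp = 50, laminin = 0, hss = 50)
  expect_equal(compute_calibration_multipliers(tab, "Alb")$mean, 1)

  # each protein's own multiplier makes its raw net exactly zero
  tab2 <- random_table(10, seed = 11)
  tab2$hss <- tab2$hss + 1  # keep multipliers defined
  for (i in c(2, 5, 9)) {
    cal_i <- compute_calibration_multipliers(tab2, tab2$symbol[i])
    net <- subtract_background(tab2, cal_i$mean)
    expect_equal(unname(net$raw_net[tab2$symbol[i]]), 0)
    expect_true(tab2$symbol[i] %in% names(net$excluded))
  }
})

test_that("calibration errors name the offending protein", {
  expect_error(compute_calibration_multipliers(calib_table(), "Tf"), "Tf")
  expect_error(compute_calibration_multipliers(calib_table(), "Gap43"),
               "hss count is 0.*Gap43")
  expect_error(compute_calibration_multipliers(calib_table(), character()),
               "at least one")
})

test_that("estimated multiplier recovers the zeroing root at depth", {
  # brute-force oracle: solve net(m) = 0 for the calibration protein
  truth <- synthetic_truth(seed = 42)
  ds <- generate_dataset(truth)
  cal <- compute_calibration_multipliers(ds$counts, truth$calibration_ids)
  for (id in truth$calibration_ids) {
    i <- match(id, ds$counts$symbol)
    f <- function(m) ds$counts$gcp[i] - ds$counts$laminin[i] -
      m * ds$counts$hss[i]
    root <- uniroot(f, c(0, 10))$root
    expect_equal(unname(cal$per_protein[id]), root, tolerance = 1e-8)
  }
  expect_lt(abs(cal$mean - truth$zeroing_ratio) / truth$zeroing_ratio, 0.1)
})

test_that("background subtraction arithmetic and exclusion rule", {
  tab <- spectral_count_table(c("p1", "p2"), c("A", "B"),
                              gcp = c(100, 30), laminin = c(10, 0),
                              hss = c(100, 100))
  net <- subtract_background(tab, 0.315)
  expect_equal(unname(net$net_counts["A"]), 58.5)
  expect_false("B" %in% names(net$net_counts))
  expect_equal(unname(net$excluded["B"]), -1.5)  # raw value kept
  expect_equal(net$total_net_spectra, 58.5)
})

test_that("subtraction matches an independent per-row recomputation", {
  tab <- random_table(20, seed = 3)
  m <- 0.315
  net <- subtract_background(tab, m)
  for (i in seq_len(20)) {
    raw <- tab$gcp[i] - tab$laminin[i] - m * tab$hss[i]
    sym <- tab$symbol[i]
    if (raw > 0) {
      expect_equal(unname(net$net_counts[sym]), raw)
    } else {
      expect_true(sym %in% names(net$excluded))
    }
  }
})

test_that("subtraction invariants: identity at m=0, bounds, monotonicity", {
  tab <- random_table(30, seed = 8)
  tab$laminin <- rep(0, 30)
  net0 <- subtract_background(tab, 0)
  pos <- tab$symbol[tab$gcp > 0]
  expect_setequal(names(net0$net_counts), pos)
  expect_equal(unname(net0$net_counts[pos]),
               tab$gcp[match(pos, tab$symbol)])

  tab2 <- random_table(30, seed = 9)
  ms <- c(0, 0.1, 0.315, 0.6, 1, 2)
  nets <- lapply(ms, subtract_background, table = tab2)
  for (net in nets)  # net counts never exceed gross
    expect_true(all(net$net_counts <=
                      net$gross[names(net$net_counts)] + 1e-12))
  for (i in seq_along(ms)[-1]) {
    # increasing m never increases a net count, never shrinks exclusions
    common <- intersect(names(nets[[i]]$net_counts),
                        names(nets[[i - 1]]$net_counts))
    expect_true(all(nets[[i]]$net_counts[common] <=
                      nets[[i - 1]]$net_counts[common] + 1e-12))
    expect_true(all(names(nets[[i - 1]]$excluded) %in%
                      names(nets[[i]]$excluded)))
  }
})

test_that("elimination report summarizes contaminant removal", {
  tab <- spectral_count_table(c("p1", "p2", "p3"), c("Alb", "Tf", "Gap43"),
                              gcp = c(20, 10, 100), laminin = c(0, 0, 0),
                              hss = c(100, 50, 0))
  net <- subtract_background(tab, 0.315)
  rep <- validate_elimination(net, c("Alb", "Tf"))
  expect_equal(rep$proteins_eliminated, 1)
  expect_equal(rep$spectra_eliminated, 1)
  expect_setequal(rep$report$status, "excluded")

  empty <- validate_elimination(net, character())
  expect_equal(nrow(empty$report), 0L)

  # absent controls are reported, not fatal
  rep2 <- validate_elimination(net, c("Alb", "Afp"))
  expect_equal(rep2$report$status[rep2$report$symbol == "Afp"], "absent")
})
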