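toy_regression_study <- function(expr_rows, doses = c(0, 9, 27, 45)) {
  m <- do.call(rbind, expr_rows)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  calls <- matrix("P", nrow(m), ncol(m), dimnames = dimnames(m))
  design <- data.frame(sample_id = colnames(m), time_days = 1,
                       dose_uM = doses)
  expression_study(m, calls, design)
}

test_that("regression reproduces the frozen closed-form OLS example", {
  # doses (0,9,27,45), y (10,20,25,50): slope, t and P computed beforehand
  # from the closed-form OLS / t-tail formulas
  st <- toy_regression_study(list(c(10, 20, 25, 50)))
  res <- fit_dose_regression(st, 1, "raw")
  expect_equal(res$slope, 0.819209, tolerance = 1e-6)
  expect_equal(res$t, 4.894132, tolerance = 1e-6)
  expect_equal(res$p_value, 0.0393043, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_identical(res$direction, "positive")
})

test_that("degenerate fits are flagged, not fatal", {
  st <- toy_regression_study(list(c(5, 5, 5, 5),        # constant
                                  c(10, 19, 37, 55),    # exactly linear
                                  c(50, 40, 30, 35)))
  res <- fit_dose_regression(st, 1, "raw")
  const <- res[res$probe == "g1", ]
  expect_equal(const$slope, 0)
  expect_identical(const$direction, "flat")
  expect_equal(const$p_value, 1)
  perfect <- res[res$probe == "g2", ]
  expect_true(perfect$perfect_fit)
  expect_equal(perfect$p_value, 0)
  expect_identical(perfect$t, Inf)
  expect_false(any(res$perfect_fit[res$probe %in% c("g1", "g3")]))
})

test_that("regression is invariant to sample order and raw-scale rescaling", {
  sim <- simulate_study(sim_config(n_genes = 100, seed = 11))
  st <- sim$study
  res <- fit_dose_regression(st, 1, "raw")
  # reversed sample order
  rev_idx <- rev(seq_len(8))
  st_rev <- expression_study(st$signal[, rev_idx], st$calls[, rev_idx],
                             st$design[rev_idx, ])
  res_rev <- fit_dose_regression(st_rev, 1, "raw")
  expect_equal(res_rev$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(res_rev$slope, res$slope, tolerance = 1e-12)
  # multiplying all expressions by a constant leaves t and P unchanged
  st_scaled <- expression_study(st$signal * 7.5, st$calls, st$design)
  res_sc <- fit_dose_regression(st_scaled, 1, "raw")
  expect_equal(res_sc$t, res$t, tolerance = 1e-9)
  expect_equal(res_sc$p_value, res$p_value, tolerance = 1e-9)
  expect_equal(res_sc$slope, res$slope * 7.5, tolerance = 1e-9)
})

test_that("blocks with too few or degenerate doses are rejected", {
  st <- toy_regression_study(list(c(1, 2, 3, 4)), doses = c(0, 9, 9, 9))
  expect_error(fit_dose_regression(st, 1), "distinct doses")
})

test_that("select_genes applies a strict cutoff and direction filter", {
  res <- data.frame(probe = paste0("g", 1:5),
                    slope = c(1, -1, 2, -2, 0.5),
                    p_value = c(0.005, 0.01, 0.04, 0.20, 0.01000001),
                    direction = c("positive", "negative", "positive",
                                  "negative", "positive"),
                    stringsAsFactors = FALSE)
  sel <- select_genes(res, 0.01)
  expect_identical(sel$ids, "g1")        # P = 0.01 exactly is excluded
  expect_equal(sel$n_universe, 5)
  selp <- select_genes(res, 0.05, "positive")
  expect_identical(sort(selp$ids), c("g1", "g3", "g5"))
  empty <- select_genes(res[0, ], 0.05)
  expect_length(empty$ids, 0)
})

test_that("null simulation type-I error is calibrated at 0.01 and 0.05", {
  hits <- t(vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 500, frac_pos_block1 = 0, frac_neg_block1 = 0,
                      frac_pos_block2 = 0, frac_neg_block2 = 0,
                      module_specs = list(), seed = 2000 + s)
    res <- fit_dose_regression(filter_present(simulate_study(cfg)$study),
                               13, "log2")
    c(mean(res$p_value < 0.01), mean(res$p_value < 0.05))
  }, numeric(2)))
  for (j in 1:2) {
    alpha <- c(0.01, 0.05)[j]
    band <- 3 * sqrt(alpha * (1 - alpha) / 500)
    expect_gte(mean(abs(hits[, j] - alpha) <= band), 0.9)
  }
})

test_that("sensitivity is non-decreasing in effect size", {
  sens <- vapply(c(0.02, 0.05, 0.1), function(sl) {
    mean(vapply(1:5, function(s) {
      sim <- simulate_study(sim_config(n_genes = 500, slope_scale = sl,
                                       module_specs = list(), seed = 300 + s))
      res <- fit_dose_regression(filter_present(sim$study), 1, "log2")
      sel <- select_genes(res, 0.01)
      truth <- sim$truth
      resp <- truth$probe[truth$class_block1 != "null"]
      length(intersect(sel$ids, resp)) / length(resp)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("pvalue_histogram conserves counts and bins correctly", {
  res <- data.frame(p_value = rep(0.005, 10))
  h <- pvalue_histogram(res, 20)
  expect_equal(h$count[1], 10)
  expect_equal(sum(h$count[-1]), 0)
  res2 <- data.frame(p_value = runif(137))
  h2 <- pvalue_histogram(res2, 13)
  expect_equal(sum(h2$count), 137)
  # P = 1 lands in the last bin
  h3 <- pvalue_histogram(data.frame(p_value = c(0, 1)), 10)
  expect_equal(h3$count[c(1, 10)], c(1, 1))
})

test_that("bh_fdr matches the hand step-up calculation", {
  res <- data.frame(probe = c("a", "b", "c"), p_value = c(0.01, 0.02, 0.03))
  expect_equal(unname(bh_fdr(res)), c(0.03, 0.03, 0.03))
  expect_equal(unname(bh_fdr(data.frame(probe = "x", p_value = 0.2))), 0.2)
  expect_equal(unname(bh_fdr(data.frame(probe = c("x", "y"),
                                        p_value = c(1, 1)))), c(1, 1))
  # q values are monotone in P rank
  set.seed(1)
  res2 <- data.frame(probe = paste0("g", 1:50), p_value = runif(50))
  q <- bh_fdr(res2)
  ord <- order(res2$p_value)
  expect_true(all(diff(q[ord]) >= -1e-15))
})
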