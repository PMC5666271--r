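test_that("first eigenvector has unit norm and recovers exact isometry", {
  m <- isometric_matrix(12, 14)
  v <- first_eigenvector(m)
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  expect_equal(unname(v), rep(1 / sqrt(14), 14), tolerance = 1e-10)
  expect_gt(sum(v), 0)
})

test_that("first eigenvector recovers the generating exponent vector", {
  b <- c(2, 1, 1, 1, 1)
  spec <- synthetic_spec(n = 200, slopes = b, noise_sd = 0.01, seed = 31)
  v <- first_eigenvector(generate_series(spec))
  expect_lt(max(abs(v - b / sqrt(sum(b^2)))), 0.02)
})

test_that("degenerate inputs are rejected", {
  expect_error(first_eigenvector(isometric_matrix(2, 3)), "3 complete")
  # orthogonal balanced design: exactly tied leading eigenvalues
  tied <- 10^cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_error(first_eigenvector(tied), "tied leading eigenvalues")
})

test_that("pseudovalues equal a from-scratch leave-one-out recomputation", {
  set.seed(42)
  for (n in c(8, 12)) {
    spec <- synthetic_spec(n = n, slopes = c(1.2, 1, 0.8, 1.1, 0.9),
                           noise_sd = 0.05)
    m <- as.matrix(generate_series(spec)[, 5:9])
    pv <- jackknife_pseudovalues(m)
    expect_lt(max(abs(unclass(pv) - naive_pseudovalues(m))), 1e-10)
  }
})

test_that("noiseless isometric pseudovalues are constant at 1/sqrt(p)", {
  pv <- jackknife_pseudovalues(isometric_matrix(10, 6))
  expect_equal(range(pv), rep(1 / sqrt(6), 2), tolerance = 1e-10)
  expect_equal(max(apply(pv, 2, sd)), 0, tolerance = 1e-10)
})

test_that("trimming removes the m extreme values per column", {
  pv <- structure(cbind(a = c(1, 2, 3, 4, 5), b = c(5, 1, 4, 2, 3)),
                  estimate_full = c(a = 3, b = 3))
  expect_identical(trim_pseudovalues(pv, 0), pv)
  t1 <- trim_pseudovalues(pv, 1)
  expect_equal(sort(t1[, "a"]), c(2, 3, 4))
  expect_equal(sort(t1[, "b"]), c(2, 3, 4))
  expect_error(trim_pseudovalues(pv, 2), "fewer than 3")
  const <- structure(matrix(7, 6, 1, dimnames = list(NULL, "a")),
                     estimate_full = 7)
  expect_equal(unname(trim_pseudovalues(const, 1)[, 1]), rep(7, 4))
})

test_that("trimming cannot raise the column SD on simulated pseudovalues", {
  set.seed(77)
  for (k in 1:10) {
    ser <- generate_series(synthetic_spec(n = 25, noise_sd = 0.05))
    pv <- jackknife_pseudovalues(ser)
    sd_u <- apply(pv, 2, sd)
    sd_t <- apply(trim_pseudovalues(pv, 1), 2, sd)
    expect_true(all(sd_t <= sd_u + 1e-12))
  }
})

test_that("jackknife CI matches the hand-computed t interval", {
  pv <- matrix(c(1, 2, 3, 4, 5), ncol = 1, dimnames = list(NULL, "a"))
  ci <- jackknife_ci(pv, level = 0.95, estimate_full = 2.8)
  expect_equal(ci$jk_mean, 3)
  expect_equal(ci$jk_sd, 1.581139, tolerance = 1e-6)
  expect_equal(ci$bias, 0.2, tolerance = 1e-12)
  # 3 +/- t_{4,.975} * sd / sqrt(5), t = 2.776445
  expect_equal(ci$ci_low, 1.036757, tolerance = 1e-5)
  expect_equal(ci$ci_high, 4.963243, tolerance = 1e-5)
  const <- matrix(0.5, 5, 1, dimnames = list(NULL, "a"))
  ci0 <- jackknife_ci(const, estimate_full = 0.4)
  expect_equal(c(ci0$ci_low, ci0$ci_high), c(0.5, 0.5))
  expect_equal(ci0$bias, 0.1, tolerance = 1e-12)
})

test_that("the 2sd multiplier option widens/narrows intervals as specified", {
  pv <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  ci_t <- jackknife_ci(pv, estimate_full = c(0, 0))
  ci_2 <- jackknife_ci(pv, estimate_full = c(0, 0), multiplier = "2sd")
  expect_equal(ci_2$ci_high - ci_2$ci_low,
               2 * 2 * ci_2$jk_sd / sqrt(10), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ci_t$ci_high, ci_2$ci_high)))
})

test_that("signs classify intervals against the isometric value", {
  co <- tibble::tibble(variable = c("a", "b", "c"),
                       ci_low = c(0.30, 0.20, 0.10),
                       ci_high = c(0.40, 0.30, 0.20))
  got <- classify_signs(co, 1 / sqrt(14))
  expect_equal(got$sign, c("+", "=", "-"))
})

test_that("column means of pseudovalues are the reported jackknife means", {
  ser <- generate_series(synthetic_spec(n = 20, noise_sd = 0.03, seed = 9))
  pv <- jackknife_pseudovalues(ser)
  mv <- multivar_allometry(ser, mode = "untrimmed")
  expect_equal(mv$jk_mean, unname(colMeans(pv)), tolerance = 1e-12)
  expect_equal(mv$bias, mv$jk_mean - mv$estimate, tolerance = 1e-12)
  expect_true(all(mv$ci_low <= mv$jk_mean & mv$jk_mean <= mv$ci_high))
})

test_that("noiseless isometric series select untrimmed mode with all-I signs", {
  mv <- multivar_allometry(as_growth_tbl(isometric_matrix(12, 8)))
  expect_equal(unique(mv$mode), "U")
  expect_equal(unique(mv$sign), "=")
  expect_equal(mv$isometry, rep(1 / sqrt(8), 8))
})

test_that("a gross outlier drives auto mode to the trimmed estimate", {
  pr <- generate_pair("outlier_injection", n = 40, seed = 13)
  mv <- multivar_allometry(pr$data)
  g <- glance(mv)
  dom <- g[g$form == "domestic", ]
  expect_lt(dom$mean_sd_trimmed, dom$mean_sd_untrimmed)
  expect_equal(dom$mode, "T")
})

test_that("isometry value follows the number of variables analyzed", {
  ser <- generate_series(synthetic_spec(n = 15, seed = 3))
  reduced <- ser[, 1:14] # 10 measurement columns
  mv <- multivar_allometry(reduced)
  expect_equal(unique(mv$p), 10)
  expect_equal(unique(mv$isometry), 1 / sqrt(10))
})
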