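test_that("geometric mean size behaves like a degree-1 size proxy", {
  d <- tibble::tibble(specimen = c("a", "b"), taxon = "t", form = "wild",
                      pair = "p", A = c(10, 1), B = c(10, 100),
                      C = c(10, 10))
  gm <- geometric_mean_size(d, c("A", "B"))
  expect_equal(gm$gm, c(10, 10))
  gm3 <- geometric_mean_size(d)
  d2 <- d; d2[c("A", "B", "C")] <- d[c("A", "B", "C")] * 2
  expect_equal(geometric_mean_size(d2)$gm, 2 * gm3$gm)
})

test_that("specimens missing a proxy variable are excluded with a warning", {
  d <- tibble::tibble(specimen = c("a", "b"), taxon = "t", form = "wild",
                      pair = "p", A = c(10, NA), B = c(10, 100))
  expect_warning(gm <- geometric_mean_size(d), "excluded")
  expect_equal(gm$specimen, "a")
})

test_that("normality check flags bimodal sizes but passes normal ones", {
  set.seed(61)
  ok <- vapply(1:100, function(i) {
    size_normality(rnorm(50, 100, 10))$p > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.94)
  bimodal <- c(rnorm(25, 10, 0.05), rnorm(25, 100, 0.05))
  expect_warning(nc <- size_normality(bimodal), "normality")
  expect_lt(nc$p, 0.05)
  expect_gte(size_normality(c(-2, -1, 0, 1, 2))$W, 0.95)
  expect_error(size_normality(rep(3, 10)), "constant")
})

test_that("SMA slope and intercept follow the closed form", {
  x <- log10(seq(2, 40, length.out = 15))
  expect_equal(sma_fit(x, x)$slope, 1)
  expect_equal(sma_fit(x, x)$intercept, 0)
  expect_equal(sma_fit(x, x)$r, 1)
  f2 <- sma_fit(x, 2 * x + 1)
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 1, tolerance = 1e-12)
  set.seed(8)
  xr <- rnorm(100); yr <- 0.6 * xr + rnorm(100, sd = 0.5)
  f <- sma_fit(xr, yr)
  expect_equal(f$slope, sign(cor(xr, yr)) * sd(yr) / sd(xr),
               tolerance = 1e-12)
  expect_equal(f$intercept, mean(yr) - f$slope * mean(xr), tolerance = 1e-12)
  # negative association flips the slope sign
  fneg <- sma_fit(xr, -yr)
  expect_equal(fneg$slope, -f$slope, tolerance = 1e-12)
  expect_error(sma_fit(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("axis-swap duality holds for SMA", {
  set.seed(9)
  x <- rnorm(60); y <- 1.4 * x + rnorm(60, sd = 0.3)
  expect_equal(sma_fit(x, y)$slope, 1 / sma_fit(y, x)$slope,
               tolerance = 1e-12)
})

test_that("the slope test has the stated boundary and power behavior", {
  x <- log10(seq(2, 40, length.out = 20))
  expect_equal(sma_slope_test(x, x, 1)$p, 1)
  set.seed(12)
  x2 <- runif(60); y2 <- 2 * x2 + rnorm(60, sd = 0.01)
  expect_lt(sma_slope_test(x2, y2, 1)$p, 0.0036)
  expect_error(sma_slope_test(x[1:3], x[1:3], 1), "n > 3")
})

test_that("Bonferroni level scales with the number of regressions", {
  ser14 <- generate_series(synthetic_spec(n = 20, noise_sd = 0.02,
                                          seed = 14))
  bv <- suppressWarnings(bivar_allometry(ser14))
  expect_equal(unique(round(bv$alpha_corrected, 4)), 0.0036)
  ser10 <- ser14[, 1:14]
  bv10 <- suppressWarnings(bivar_allometry(ser10))
  expect_equal(unique(bv10$alpha_corrected), 0.005)
})

test_that("scale change moves intercepts but not slopes, p or trends", {
  ser <- generate_series(synthetic_spec(n = 40,
                                        slopes = c(1.3, 1, 0.7, 1, 1, 1),
                                        noise_sd = 0.02, seed = 15))
  scaled <- ser
  vars <- measurement_variables(ser)
  scaled[vars] <- ser[vars] * 7
  a <- suppressWarnings(bivar_allometry(ser))
  b <- suppressWarnings(bivar_allometry(scaled))
  expect_equal(b$slope, a$slope, tolerance = 1e-10)
  expect_equal(b$p_isometry, a$p_isometry, tolerance = 1e-9)
  expect_identical(b$trend, a$trend)
  expect_false(isTRUE(all.equal(b$intercept, a$intercept)))
})

test_that("planted exponents 1.3/1.0/0.7 are classified +/=/- reliably", {
  set.seed(16)
  hits <- vapply(1:200, function(k) {
    ser <- generate_series(synthetic_spec(n = 150,
                                          slopes = c(A = 1.3, B = 1, C = 0.7),
                                          noise_sd = 0.02))
    bv <- suppressWarnings(bivar_allometry(ser))
    identical(bv$trend[match(c("A", "B", "C"), bv$variable)],
              c("+", "=", "-"))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("noiseless isometric series give all-isometric trends", {
  ser <- as_growth_tbl(isometric_matrix(20, 6))
  bv <- suppressWarnings(bivar_allometry(ser))
  expect_equal(unique(bv$trend), "=")
  expect_equal(bv$slope, rep(1, 6), tolerance = 1e-10)
})
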