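test_that("identical samples give null outcomes in all three tests", {
  set.seed(71)
  x <- rnorm(30); y <- 1.2 * x + rnorm(30, sd = 0.2)
  st <- sma_common_slope_test(x, y, x, y)
  expect_equal(st$statistic, 0, tolerance = 1e-8)
  expect_equal(st$p, 1, tolerance = 1e-4)
  it <- sma_elevation_test(x, y, x, y, st$common_slope,
                           st$var_common_slope)
  expect_equal(it$p, 1)
  sh <- sma_shift_test(x, y, x, y, st$common_slope)
  expect_equal(sh$p, 1)
  expect_equal(sh$direction, "none")
})

test_that("clearly different slopes are detected and estimated between", {
  set.seed(72)
  x1 <- runif(80); y1 <- 0.8 * x1 + rnorm(80, sd = 0.02)
  x2 <- runif(80); y2 <- 1.3 * x2 + rnorm(80, sd = 0.02)
  st <- sma_common_slope_test(x1, y1, x2, y2)
  expect_lt(st$p, 0.0036)
  expect_gt(st$common_slope, min(st$slope_wild, st$slope_dom))
  expect_lt(st$common_slope, max(st$slope_wild, st$slope_dom))
})

test_that("elevation offsets are detected with the right direction", {
  set.seed(73)
  hits <- vapply(1:50, function(k) {
    x1 <- runif(80); y1 <- x1 + rnorm(80, sd = 0.05)
    x2 <- runif(80); y2 <- x2 + 0.2 + rnorm(80, sd = 0.05)
    st <- sma_common_slope_test(x1, y1, x2, y2)
    it <- sma_elevation_test(x1, y1, x2, y2, st$common_slope,
                             st$var_common_slope)
    it$p < 0.0036 && it$higher == "domestic"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the elevation test holds its size under equal intercepts", {
  set.seed(74)
  rej <- vapply(1:400, function(k) {
    x1 <- runif(80); y1 <- x1 + rnorm(80, sd = 0.05)
    x2 <- runif(80); y2 <- x2 + rnorm(80, sd = 0.05)
    st <- sma_common_slope_test(x1, y1, x2, y2)
    if (st$p < 0.05) return(NA) # conditioned on the gate, as in use
    sma_elevation_test(x1, y1, x2, y2, st$common_slope,
                       st$var_common_slope)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej, na.rm = TRUE), 0.02)
  expect_lt(mean(rej, na.rm = TRUE), 0.09)
})

test_that("shifts along a shared axis are detected with direction", {
  set.seed(75)
  x1 <- runif(80); y1 <- x1 + rnorm(80, sd = 0.03)
  x2 <- runif(80) + 1; y2 <- x2 + rnorm(80, sd = 0.03)
  st <- sma_common_slope_test(x1, y1, x2, y2)
  sh <- sma_shift_test(x1, y1, x2, y2, st$common_slope, alpha = 0.0036)
  expect_lt(sh$p, 0.0036)
  expect_equal(sh$direction, "domestic_extends")
  # mirror: wild translated upward
  sh2 <- sma_shift_test(x2, y2, x1, y1, st$common_slope, alpha = 0.0036)
  expect_equal(sh2$direction, "wild_extends")
})

test_that("label/process mapping is exactly the two heterochrony triples", {
  pera <- c("acceleration", "hypermorphosis", "pre_displacement")
  paed <- c("deceleration", "hypomorphosis", "post_displacement")
  expect_setequal(names(heterochrony_processes), c(pera, paed, "no_change"))
  expect_true(all(heterochrony_processes[pera] == "peramorphosis"))
  expect_true(all(heterochrony_processes[paed] == "paedomorphosis"))
  expect_equal(unname(heterochrony_processes["no_change"]), "none")
})

test_that("the gated decision tree maps test outcomes to labels", {
  a <- 0.0036
  expect_equal(classify_heterochrony(1e-5, NA, NA, TRUE, NA, "none", a),
               list(label = "acceleration", process = "peramorphosis"))
  expect_equal(classify_heterochrony(1e-5, NA, NA, FALSE, NA, "none", a),
               list(label = "deceleration", process = "paedomorphosis"))
  expect_equal(
    classify_heterochrony(0.5, 1e-5, NA, TRUE, "domestic", "none", a),
    list(label = "pre_displacement", process = "peramorphosis"))
  expect_equal(
    classify_heterochrony(0.5, 1e-5, NA, TRUE, "wild", "none", a),
    list(label = "post_displacement", process = "paedomorphosis"))
  expect_equal(
    classify_heterochrony(0.5, 0.5, 1e-5, TRUE, "tie", "domestic_extends", a),
    list(label = "hypermorphosis", process = "peramorphosis"))
  expect_equal(
    classify_heterochrony(0.5, 0.5, 1e-5, TRUE, "tie", "wild_extends", a),
    list(label = "hypomorphosis", process = "paedomorphosis"))
  expect_equal(classify_heterochrony(0.5, 0.5, 0.5, TRUE, "tie", "none", a),
               list(label = "no_change", process = "none"))
  # configurable intercept polarity flips the displacement labels
  expect_equal(
    classify_heterochrony(0.5, 1e-5, NA, TRUE, "domestic", "none", a,
                          intercept_polarity = "higher_dom_post")$label,
    "post_displacement")
})

test_that("later tests are never reported when an earlier one fires", {
  pr <- generate_pair("acceleration", n = 80, seed = 81)
  cmp <- suppressWarnings(compare_trajectories(pr$data))
  sig <- cmp$slope_p < cmp$alpha_corrected
  expect_true(any(sig))
  expect_true(all(is.na(cmp$intercept_p[sig])))
  expect_true(all(is.na(cmp$shift_p[sig])))
  int_sig <- !is.na(cmp$intercept_p) & cmp$intercept_p < cmp$alpha_corrected
  expect_true(all(is.na(cmp$shift_p[int_sig])))
})

test_that("swapping form labels mirrors every heterochrony label", {
  mirror <- c(acceleration = "deceleration", deceleration = "acceleration",
              pre_displacement = "post_displacement",
              post_displacement = "pre_displacement",
              hypermorphosis = "hypomorphosis",
              hypomorphosis = "hypermorphosis", no_change = "no_change")
  for (preset in c("acceleration", "pre_displacement", "hypermorphosis")) {
    pr <- generate_pair(preset, n = 80, seed = 83)
    swapped <- pr$data
    swapped$form <- ifelse(swapped$form == "wild", "domestic", "wild")
    a <- suppressWarnings(compare_trajectories(pr$data))
    b <- suppressWarnings(compare_trajectories(swapped))
    expect_identical(unname(mirror[a$label]), b$label)
  }
})

test_that("per-pair tallies are consistent with the per-variable labels", {
  pr <- generate_pair("acceleration", n = 80, seed = 85)
  cmp <- suppressWarnings(compare_trajectories(pr$data))
  ps <- pair_summary(cmp)
  expect_equal(ps$n_variables, 6)
  expect_equal(ps$n_heterochronic_events + ps$n_no_change, ps$n_variables)
  expect_equal(ps$n_heterochronic_events,
               sum(cmp$label != "no_change"))
  expect_equal(ps$n_peramorphosis + ps$n_paedomorphosis,
               ps$n_heterochronic_events)
  expect_identical(ps, glance(cmp))
})

test_that("under a null pair, spurious labels stay near the corrected level", {
  set.seed(86)
  frac <- vapply(1:120, function(k) {
    pr <- generate_pair("no_change", n = 60,
                        seed = 9000L + k * 3L)
    cmp <- suppressWarnings(compare_trajectories(pr$data))
    mean(cmp$label != "no_change")
  }, numeric(1))
  # three gated tests at alpha/6 each: expect roughly 3 * 0.0083 = 2.5%
  expect_lt(mean(frac), 0.06)
})
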