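fake_result <- function(form, pair, vars, lo, hi, sign) {
  tibble::tibble(taxon = paste0("t_", pair), form = form, pair = pair,
                 variable = vars, ci_low = lo, ci_high = hi, sign = sign)
}

test_that("interval distance is the gap between disjoint intervals", {
  expect_equal(interval_distance(c(0.1, 0.2), c(0.3, 0.4)),
               list(distance = 0.1, overlap = FALSE))
  expect_equal(interval_distance(c(0.1, 0.3), c(0.2, 0.4)),
               list(distance = 0, overlap = TRUE))
  expect_equal(interval_distance(c(0.1, 0.2), c(0.1, 0.2)),
               list(distance = 0, overlap = TRUE))
})

test_that("interval distance is a pseudo-metric on random intervals", {
  set.seed(5)
  for (k in 1:50) {
    a <- sort(runif(2)); b <- sort(runif(2))
    dab <- interval_distance(a, b)
    dba <- interval_distance(b, a)
    expect_gte(dab$distance, 0)
    expect_equal(dab$distance, dba$distance)
    expect_equal(interval_distance(a, a)$distance, 0)
    if (dab$overlap) expect_equal(dab$distance, 0)
  }
})

test_that("pair divergence sums gaps and flags sign disagreement", {
  vars <- c("CPL", "LN", "HM")
  w <- fake_result("wild", "p1", vars,
                   lo = c(0.10, 0.20, 0.25), hi = c(0.20, 0.30, 0.30),
                   sign = c("-", "=", "=")) # isometry 0.267
  d <- fake_result("domestic", "p1", vars,
                   lo = c(0.30, 0.22, 0.27), hi = c(0.40, 0.32, 0.35),
                   sign = c("+", "=", "+"))
  pd <- pair_divergence(w, d)
  expect_equal(pd$distance, c(0.1, 0, 0))
  expect_equal(attr(pd, "added_change"), 0.1)
  # overlapping intervals can still disagree in sign
  expect_true(pd$sign_disagreement[3])
  expect_true(pd$overlap[3])
  # identity and symmetry
  expect_equal(pair_divergence(w, w)$distance, rep(0, 3))
  expect_equal(pair_divergence(d, w)$distance, pd$distance)
})

test_that("variable-set mismatches restrict to the intersection", {
  w <- fake_result("wild", "p1", c("CPL", "LN"), c(0.1, 0.2), c(0.2, 0.3),
                   c("-", "="))
  d <- fake_result("domestic", "p1", "CPL", 0.4, 0.5, "+")
  expect_warning(pd <- pair_divergence(w, d), "restricting")
  expect_equal(pd$variable, "CPL")
  expect_equal(pd$distance, 0.2)
})

test_that("a single strongly shifted exponent dominates the divergence", {
  b_w <- c(CPL = 1, LN = 1, HM = 1, UPR = 1, LP = 1, BP = 1)
  b_d <- b_w; b_d["CPL"] <- 1.6
  d <- dplyr::bind_rows(
    generate_series(synthetic_spec("wild", n = 60, slopes = b_w,
                                   noise_sd = 0.01), "t", "p1", seed = 51),
    generate_series(synthetic_spec("domestic", n = 60, slopes = b_d,
                                   noise_sd = 0.01), "t", "p1", seed = 52)
  )
  pd <- trajectory_divergence(multivar_allometry(d))
  expect_gt(pd$distance[pd$variable == "CPL"], 0)
  expect_equal(which.max(pd$distance), which(pd$variable == "CPL"))
  expect_false(pd$overlap[pd$variable == "CPL"])
})

test_that("divergence summary marginals are mutually consistent", {
  st <- make_study_fixture(n_pairs = 3, n = 40, seed = 21)
  mv <- multivar_allometry(st$data)
  div <- trajectory_divergence(mv)
  ds <- divergence_summary(div)
  total_cells <- sum(as.matrix(ds$matrix[, -1]), na.rm = TRUE)
  expect_equal(total_cells, sum(ds$pair_added_change$added_change))
  expect_equal(total_cells, sum(ds$variable_added_change$added_change))
  expect_equal(total_cells, ds$total)
  expect_equal(sum(tidy(ds)$distance), ds$total)
})

test_that("planted divergences 0.48/0.24/0 are ranked in order", {
  st <- make_study_fixture(n_pairs = 3, n = 60, seed = 33)
  mv <- multivar_allometry(st$data)
  ds <- divergence_summary(trajectory_divergence(mv))
  ranked <- ds$pair_added_change
  expect_equal(ranked$pair, c("pair01", "pair02", "pair03"))
  expect_lt(ranked$added_change[3], 0.05)
})

test_that("single-pair and all-zero summaries are degenerate correctly", {
  vars <- c("CPL", "LN")
  w <- fake_result("wild", "p1", vars, c(0.1, 0.2), c(0.2, 0.3), c("-", "="))
  pd <- pair_divergence(w, w)
  ds <- divergence_summary(pd)
  expect_equal(nrow(ds$matrix), 1)
  expect_equal(ds$total, 0)
  expect_equal(ds$pair_added_change$added_change, 0)
})
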