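# Shared fixture builders; everything is generated in code at test time.

# Exactly isometric, noiseless measurement matrix: every variable is a fixed
# multiple of a common size factor.
isometric_matrix <- function(n = 12, p = 14, scales = NULL) {
  s <- exp(seq(0, log(3), length.out = n))
  scales <- scales %||% seq(2, by = 3, length.out = p)
  m <- outer(s, scales)
  colnames(m) <- skull_variables[seq_len(p)]
  m
}

# Growth tibble wrapper around a measurement matrix.
as_growth_tbl <- function(m, taxon = "fixture", form = "wild",
                          pair = "pair01") {
  out <- tibble::tibble(
    specimen = sprintf("sp%03d", seq_len(nrow(m))),
    taxon = taxon, form = form, pair = pair
  )
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

# Two-form growth table written to a temporary CSV.
write_fixture_csv <- function(data, path = tempfile(fileext = ".csv")) {
  readr::write_csv(data, path, progress = FALSE)
  path
}

# Independent leave-one-out pseudovalue oracle: recomputes every PCA round
# from scratch, never calling the package's jackknife path.
naive_pseudovalues <- function(m) {
  lx <- log10(m)
  n <- nrow(lx)
  lead_vec <- function(a) {
    e <- eigen(cov(a), symmetric = TRUE)
    e$vectors[, 1]
  }
  full <- lead_vec(lx)
  if (sum(full) < 0) full <- -full
  out <- matrix(NA_real_, n, ncol(lx))
  for (i in seq_len(n)) {
    vi <- lead_vec(lx[-i, , drop = FALSE])
    if (sum(vi * full) < 0) vi <- -vi
    out[i, ] <- n * full - (n - 1) * vi
  }
  out
}

# Bivariate normal sample with population SMA slope 1 (equal variances).
sma_null_group <- function(n, rho = 0.8) {
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  list(x = x, y = y)
}
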