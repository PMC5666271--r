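# Leading eigenvector of the covariance of log10 measurements.
# `raw = TRUE` skips the positive-sum orientation (used internally so
# leave-one-out vectors can be aligned to the full-sample vector instead).
.leading_eigenvector <- function(logm, raw = FALSE) {
  n <- nrow(logm)
  p <- ncol(logm)
  if (n < 3) stop("need at least 3 complete specimens", call. = FALSE)
  if (p < 2) stop("need at least 2 variables", call. = FALSE)
  S <- stats::cov(logm)
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  if (lam[1] <= 0) {
    stop("covariance matrix has no positive leading eigenvalue", call. = FALSE)
  }
  if (p > 1 && (lam[1] - lam[2]) < 1e-10 * lam[1]) {
    stop("degenerate covariance structure: tied leading eigenvalues",
         call. = FALSE)
  }
  v <- e$vectors[, 1]
  if (!raw && sum(v) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' First eigenvector of the log10 covariance matrix
#'
#' The multivariate allometry vector: the unit-scaled eigenvector belonging to
#' the largest eigenvalue of the variance-covariance matrix of
#' log10-transformed measurements. Its elements are the multivariate allometry
#' coefficients; under perfect isometry over p variables every element equals
#' 1/sqrt(p). The vector is oriented so its element sum is positive.
#'
#' @param x A numeric matrix of strictly positive measurements (specimens in
#'   rows, variables in columns) or a growth tibble holding a single series.
#' @param variables Variables to use when `x` is a growth tibble (default all
#'   measurement columns with complete data).
#' @return A named unit-norm numeric vector of length p.
#' @examples
#' m <- outer(exp(seq(0, 1, length.out = 10)), c(2, 5, 9))
#' first_eigenvector(m) # exactly isometric: all elements 1/sqrt(3)
#' @export
first_eigenvector <- function(x, variables = NULL) {
  logm <- .as_log_matrix(x, variables)
  v <- .leading_eigenvector(logm)
  names(v) <- colnames(logm)
  v
}

.as_log_matrix <- function(x, variables = NULL) {
  if (is.data.frame(x)) {
    variables <- variables %||% measurement_variables(x)
    .series_matrix(x, variables, log10_transform = TRUE)
  } else {
    m <- as.matrix(x)
    if (any(!is.finite(m)) || any(m <= 0)) {
      stop("measurement matrix must be complete and strictly positive",
           call. = FALSE)
    }
    log10(m)
  }
}

#' Jackknife pseudovalues of the allometry vector
#'
#' Leave-one-out resampling of [first_eigenvector()]: for each specimen i the
#' first-order Tukey pseudovalue of every coefficient is
#' `n * theta - (n - 1) * theta_(-i)`, where `theta` is the full-sample
#' eigenvector element and `theta_(-i)` its leave-one-out counterpart. Each
#' leave-one-out vector is sign-aligned to the full-sample vector (positive
#' dot product) before the pseudovalue is formed, so arbitrary eigenvector
#' sign flips between rounds cannot corrupt the resampling.
#'
#' @inheritParams first_eigenvector
#' @return An n x p matrix of pseudovalues with attributes `estimate_full`
#'   (the full-sample eigenvector) and `n`.
#' @export
jackknife_pseudovalues <- function(x, variables = NULL) {
  .jackknife_pv(.as_log_matrix(x, variables))
}

.jackknife_pv <- function(logm) {
  n <- nrow(logm)
  if (n < 4) stop("jackknife requires at least 4 specimens", call. = FALSE)
  theta <- .leading_eigenvector(logm)
  pv <- matrix(NA_real_, n, ncol(logm),
               dimnames = list(rownames(logm), colnames(logm)))
  for (i in seq_len(n)) {
    vi <- tryCatch(
      .leading_eigenvector(logm[-i, , drop = FALSE], raw = TRUE),
      error = function(e) {
        stop("eigendecomposition failed when excluding specimen '",
             rownames(logm)[i] %||% i, "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (sum(vi * theta) < 0) vi <- -vi
    pv[i, ] <- n * theta - (n - 1) * vi
  }
  structure(pv, estimate_full = theta, n = n)
}

#' Trim extreme pseudovalues
#'
#' Removes, independently for each coefficient, the `m` largest and `m`
#' smallest pseudovalues. Trimming damps the influence of extreme resampling
#' values on the confidence intervals; after trimming the rows of the matrix
#' no longer correspond to specimens.
#'
#' @param pv Pseudovalue matrix from [jackknife_pseudovalues()].
#' @param m Number of values to drop from each tail per column (default 1).
#' @return An (n - 2m) x p matrix, carrying the same `estimate_full` attribute.
#' @export
trim_pseudovalues <- function(pv, m = 1) {
  stopifnot(m >= 0, m == round(m))
  n <- nrow(pv)
  if (m == 0) return(pv)
  if (n - 2 * m < 3) {
    stop("trimming m = ", m, " would leave fewer than 3 pseudovalues",
         call. = FALSE)
  }
  out <- apply(pv, 2, function(col) {
    ord <- order(col)
    col[ord[(m + 1):(n - m)]]
  })
  structure(out, estimate_full = attr(pv, "estimate_full"), n = n)
}

#' Jackknife confidence intervals for allometry coefficients
#'
#' For each coefficient the column mean of the pseudovalues is the jackknife
#' estimate, their standard deviation gives the standard error, and the
#' interval is `mean +/- q * sd / sqrt(n')` with `n'` the (possibly trimmed)
#' column length. The multiplier `q` is the Student-t quantile by default; a
#' plain `+/- 2 sd/sqrt(n')` interval is available for sensitivity checks.
#' Bias is the signed difference between the jackknife mean and the
#' full-sample estimate.
#'
#' @param pv Pseudovalue matrix ([jackknife_pseudovalues()], possibly
#'   trimmed).
#' @param level Confidence level (default 0.95).
#' @param estimate_full Full-sample eigenvector; defaults to the attribute on
#'   `pv`.
#' @param multiplier `"t"` (Student-t quantile, default) or `"2sd"`.
#' @return A tibble with one row per coefficient: `variable`, `estimate`,
#'   `jk_mean`, `jk_sd`, `bias`, `ci_low`, `ci_high`.
#' @export
jackknife_ci <- function(pv, level = 0.95, estimate_full = NULL,
                         multiplier = c("t", "2sd")) {
  multiplier <- match.arg(multiplier)
  stopifnot(level > 0, level < 1)
  estimate_full <- estimate_full %||% attr(pv, "estimate_full")
  if (is.null(estimate_full)) {
    stop("estimate_full must be supplied when `pv` lacks the attribute",
         call. = FALSE)
  }
  n <- nrow(pv)
  if (n < 3) stop("need at least 3 pseudovalues per coefficient", call. = FALSE)
  mean_ <- colMeans(pv)
  sd_ <- apply(pv, 2, stats::sd)
  q <- switch(multiplier,
    t = stats::qt((1 + level) / 2, df = n - 1),
    `2sd` = 2
  )
  half <- q * sd_ / sqrt(n)
  tibble::tibble(
    variable = colnames(pv) %||% paste0("V", seq_along(mean_)),
    estimate = unname(estimate_full),
    jk_mean = unname(mean_),
    jk_sd = unname(sd_),
    bias = unname(mean_ - estimate_full),
    ci_low = unname(mean_ - half),
    ci_high = unname(mean_ + half)
  )
}

#' Classify coefficients against the isometric value
#'
#' A coefficient is isometric (`=`) when its confidence interval contains the
#' isometric value 1/sqrt(p), positively allometric (`+`) when the whole
#' interval lies above it, and negatively allometric (`-`) below it.
#'
#' @param coefficients Tibble from [jackknife_ci()] (columns `ci_low`,
#'   `ci_high`).
#' @param isometry_value The isometric reference value 1/sqrt(p).
#' @param tol Numerical tolerance guarding the interval comparisons, so that
#'   degenerate (zero-width) intervals produced by noise-free data are not
#'   misclassified by floating-point rounding (default 1e-9).
#' @return The input tibble with a `sign` column added (`+`, `=`, `-`).
#' @export
classify_signs <- function(coefficients, isometry_value, tol = 1e-9) {
  coefficients |>
    dplyr::mutate(sign = dplyr::case_when(
      .data$ci_low > isometry_value + tol ~ "+",
      .data$ci_high < isometry_value - tol ~ "-",
      TRUE ~ "="
    ))
}

# Untrimmed/trimmed candidates and mode choice for one series matrix.
.multivar_one <- function(logm, trim_m, ci_level, mode, ci_multiplier) {
  n <- nrow(logm)
  theta <- .leading_eigenvector(logm)
  pv <- .jackknife_pv(logm)
  cand <- list(U = jackknife_ci(pv, ci_level, multiplier = ci_multiplier))
  can_trim <- trim_m > 0 && n - 2 * trim_m >= 3
  if (can_trim) {
    cand$T <- jackknife_ci(trim_pseudovalues(pv, trim_m), ci_level,
                           estimate_full = theta, multiplier = ci_multiplier)
  }
  sum_sd <- vapply(cand, function(d) mean(d$jk_sd), numeric(1))
  sum_bias <- vapply(cand, function(d) mean(abs(d$bias)), numeric(1))
  # strictly-lower comparisons with a floating-point tie guard; the sd
  # criterion takes precedence, ties fall through to bias, then untrimmed
  lower <- function(a, b) (b - a) > 1e-12 * max(abs(a), abs(b), 1)
  mode_used <- switch(mode,
    untrimmed = "U",
    trimmed = if (can_trim) "T" else "U",
    auto = if (!can_trim) "U"
           else if (lower(sum_sd[["T"]], sum_sd[["U"]])) "T"
           else if (lower(sum_sd[["U"]], sum_sd[["T"]])) "U"
           else if (lower(sum_bias[["T"]], sum_bias[["U"]])) "T"
           else "U"
  )
  list(
    coefficients = cand[[mode_used]], candidates = cand,
    mode_used = mode_used, n = n,
    mean_sd_untrimmed = sum_sd[["U"]],
    mean_sd_trimmed = if (can_trim) sum_sd[["T"]] else NA_real_,
    mean_abs_bias_untrimmed = sum_bias[["U"]],
    mean_abs_bias_trimmed = if (can_trim) sum_bias[["T"]] else NA_real_
  )
}

#' Multivariate allometry with jackknife confidence intervals
#'
#' Runs the full multivariate stage for every (taxon, form, pair) series in a
#' growth table: unit-scaled first eigenvector of the log10 covariance matrix,
#' jackknife pseudovalues, untrimmed and m-trimmed confidence intervals, bias,
#' mode selection, and the allometric sign of every variable relative to the
#' isometric value 1/sqrt(p).
#'
#' In `mode = "auto"` the trimmed result is reported when it attains a lower
#' mean standard deviation across coefficients; when the mean standard
#' deviations tie, a lower mean absolute bias decides, and remaining ties fall
#' back to untrimmed. Each series uses only specimens complete for its
#' analysis variable set, and p (hence the isometric value) is the number of
#' variables actually analyzed for that series.
#'
#' @param data A growth tibble (see [read_growth_table()]).
#' @param variables Variables to analyze (default: all measurement columns
#'   with any data per series).
#' @param trim_m Trimming depth m (default 1).
#' @param ci_level Confidence level (default 0.95).
#' @param mode `"auto"` (default), `"untrimmed"` or `"trimmed"`.
#' @param ci_multiplier `"t"` or `"2sd"`, see [jackknife_ci()].
#' @return A `multivar_allometry` tibble with one row per series x variable:
#'   `taxon`, `form`, `pair`, `variable`, `n`, `p`, `isometry`, `estimate`,
#'   `jk_mean`, `jk_sd`, `bias`, `ci_low`, `ci_high`, `sign`, `mode`. Per-series
#'   summaries (mean sd / mean |bias| for both modes) are attached as the
#'   `"series"` attribute and returned by [glance()].
#' @examples
#' pair <- generate_pair("no_change", n = 30, seed = 1)
#' fit <- multivar_allometry(pair$data)
#' glance(fit)
#' @export
multivar_allometry <- function(data, variables = NULL, trim_m = 1,
                               ci_level = 0.95,
                               mode = c("auto", "untrimmed", "trimmed"),
                               ci_multiplier = c("t", "2sd")) {
  mode <- match.arg(mode)
  ci_multiplier <- match.arg(ci_multiplier)
  .stop_on_errors(data)
  nested <- growth_series_split(data)
  rows <- list()
  series <- list()
  cands <- list()
  for (k in seq_len(nrow(nested))) {
    ser <- nested$data[[k]]
    ser$specimen <- ser$specimen %||% as.character(seq_len(nrow(ser)))
    all_vars <- variables %||% setdiff(names(ser), "specimen")
    use <- all_vars[vapply(all_vars, function(v) {
      v %in% names(ser) && any(!is.na(ser[[v]]))
    }, logical(1))]
    use <- canonical_variable_order(use)
    logm <- .series_matrix(ser, use, log10_transform = TRUE)
    n <- nrow(logm)
    if (n < 5) {
      stop("series ", nested$taxon[k], " (", nested$form[k],
           "): only ", n, " complete specimens", call. = FALSE)
    }
    if (n < 10) {
      warning("series ", nested$taxon[k], " (", nested$form[k], "): n = ", n,
              " < 10; jackknife confidence intervals will be unreliable",
              call. = FALSE)
    }
    p <- ncol(logm)
    iso <- 1 / sqrt(p)
    res <- .multivar_one(logm, trim_m, ci_level, mode, ci_multiplier)
    coef <- classify_signs(res$coefficients, iso)
    rows[[k]] <- dplyr::mutate(coef,
      taxon = nested$taxon[k], form = nested$form[k], pair = nested$pair[k],
      n = res$n, p = p, isometry = iso, mode = res$mode_used,
      .before = 1
    )
    series[[k]] <- tibble::tibble(
      taxon = nested$taxon[k], form = nested$form[k], pair = nested$pair[k],
      n = res$n, p = p, isometry = iso, mode = res$mode_used,
      mean_sd_untrimmed = res$mean_sd_untrimmed,
      mean_sd_trimmed = res$mean_sd_trimmed,
      mean_abs_bias_untrimmed = res$mean_abs_bias_untrimmed,
      mean_abs_bias_trimmed = res$mean_abs_bias_trimmed
    )
    cands[[paste(nested$taxon[k], nested$form[k])]] <- res$candidates
  }
  out <- dplyr::bind_rows(rows)
  out <- out[, c("taxon", "form", "pair", "variable", "n", "p", "isometry",
                 "estimate", "jk_mean", "jk_sd", "bias",
                 "ci_low", "ci_high", "sign", "mode")]
  structure(
    tibble::new_tibble(out, class = "multivar_allometry"),
    series = dplyr::bind_rows(series),
    candidates = cands,
    ci_level = ci_level, trim_m = trim_m
  )
}

#' @export
tidy.multivar_allometry <- function(x, ...) {
  tibble::as_tibble(unclass(x)[!names(unclass(x)) %in%
                                 c("series", "candidates")])
}

#' @rdname multivar_allometry
#' @param x,object A `multivar_allometry` object.
#' @param ... Unused.
#' @export
glance.multivar_allometry <- function(x, ...) {
  attr(x, "series")
}

#' Plot multivariate allometry coefficients
#'
#' Coefficient point estimates with jackknife confidence intervals per
#' variable, one panel per series, with the isometric value 1/sqrt(p) drawn
#' as a dashed reference line.
#'
#' @param object A `multivar_allometry` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multivar_allometry <- function(object, ...) {
  df <- tidy(object)
  df$variable <- factor(df$variable, levels = canonical_variable_order(
    unique(df$variable)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$jk_mean,
                                   colour = .data$sign)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$isometry),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~ taxon + form) +
    ggplot2::scale_colour_manual(
      values = c("+" = "#D55E00", "=" = "grey30", "-" = "#0072B2")) +
    ggplot2::labs(x = NULL, y = "multivariate allometry coefficient",
                  colour = "sign") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
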