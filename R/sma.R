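#' Geometric-mean size proxy
#'
#' Per-specimen geometric mean of a set of measurements, used as the overall
#' size proxy for bivariate allometric regressions. The geometric mean of
#' variables growing as power laws of size is itself isometric with respect
#' to size, which is what qualifies it as the independent variable.
#' Specimens missing any proxy variable are excluded (with a warning).
#'
#' @param data A growth tibble.
#' @param proxy Character vector of proxy variables (default: all measurement
#'   columns).
#' @return A tibble with the id columns and a `gm` column (mm); the proxy set
#'   is attached as the `"proxy"` attribute.
#' @examples
#' df <- tibble::tibble(specimen = "a", taxon = "t", form = "wild",
#'                      pair = "p", A = 1, B = 100)
#' geometric_mean_size(df)$gm # 10
#' @export
geometric_mean_size <- function(data, proxy = NULL) {
  proxy <- proxy %||% measurement_variables(data)
  m <- as.matrix(data[, proxy, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m[!is.na(m)] <= 0)) {
    stop("all proxy measurements must be strictly positive", call. = FALSE)
  }
  keep <- stats::complete.cases(m)
  if (!all(keep)) {
    warning(sum(!keep), " specimen(s) excluded: missing proxy variable(s)",
            call. = FALSE)
  }
  out <- data[keep, intersect(c("specimen", "taxon", "form", "pair"),
                              names(data)), drop = FALSE]
  out$gm <- 10^rowMeans(log10(m[keep, , drop = FALSE]))
  attr(out, "proxy") <- proxy
  out
}

#' Shapiro-Wilk normality check of the size proxy
#'
#' Advisory check that the geometric-mean size variable is compatible with
#' normality before slope tests are interpreted; the analysis proceeds either
#' way, with a warning when p < 0.05.
#'
#' @param sizes Numeric vector of sizes, or a tibble with a `gm` column as
#'   returned by [geometric_mean_size()].
#' @return A one-row tibble with `W`, `p` and `n`.
#' @export
size_normality <- function(sizes) {
  x <- if (is.data.frame(sizes)) sizes$gm else sizes
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("size variable is constant", call. = FALSE)
  sw <- stats::shapiro.test(x)
  if (sw$p.value < 0.05) {
    warning("size proxy departs from normality (Shapiro-Wilk p = ",
            signif(sw$p.value, 3), ")", call. = FALSE)
  }
  tibble::tibble(W = unname(sw$statistic), p = sw$p.value, n = length(x))
}

#' Standardized major axis fit
#'
#' Fits the standardized (reduced) major axis line to a bivariate sample,
#' typically log10 measurement against log10 geometric-mean size. The SMA
#' slope is `sign(r) * sd(y) / sd(x)` and the line passes through the
#' centroid. The slope confidence interval follows the standard construction
#' from the F distribution of the correlation coefficient.
#'
#' @param x,y Numeric vectors (already log-transformed).
#' @param ci_level Confidence level for the slope interval (default 0.95).
#' @return An `sma_fit` list: `n`, `slope`, `intercept`, `r`, `ci_low`,
#'   `ci_high`, `ci_level`.
#' @examples
#' x <- log10(seq(2, 20))
#' f <- sma_fit(x, 2 * x + 1)
#' c(f$slope, f$intercept) # 2 and 1
#' @export
sma_fit <- function(x, y, ci_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("SMA fit requires n >= 3", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in x or y", call. = FALSE)
  r <- stats::cor(x, y)
  b <- if (r < 0) -sy / sx else sy / sx
  a <- mean(y) - b * mean(x)
  B <- stats::qf(ci_level, 1, n - 2) * (1 - r^2) / (n - 2)
  lims <- b * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B))
  structure(
    list(n = n, slope = b, intercept = a, r = r,
         ci_low = min(lims), ci_high = max(lims), ci_level = ci_level,
         x_mean = mean(x), y_mean = mean(y)),
    class = "sma_fit"
  )
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit (n = %d): slope %.4f [%.4f, %.4f], intercept %.4f, r %.4f\n",
              x$n, x$slope, x$ci_low, x$ci_high, x$intercept, x$r))
  invisible(x)
}

#' @export
tidy.sma_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept),
                 ci_low = c(x$ci_low, NA_real_),
                 ci_high = c(x$ci_high, NA_real_))
}

#' @export
glance.sma_fit <- function(x, ...) {
  tibble::tibble(n = x$n, r = x$r, r.squared = x$r^2)
}

# Correlation between SMA residual scores (y - b x) and axis scores (y + b x)
# at a hypothesized slope b. Zero-variance scores (data exactly on the line or
# axis) give 0 by convention.
.sma_resid_axis_cor <- function(x, y, b) {
  res <- y - b * x
  fit <- y + b * x
  if (stats::sd(res) < 1e-14 * max(1, stats::sd(y)) || stats::sd(fit) == 0) {
    return(0)
  }
  stats::cor(res, fit)
}

#' Test an SMA slope against a hypothesized value
#'
#' Tests H0: SMA slope = `null_slope` (1.0 for isometry against a
#' geometric-mean size proxy). Under H0 the residual scores `y - b0 x` and
#' axis scores `y + b0 x` are uncorrelated; the test refers
#' `F = r_rf^2 (n - 2) / (1 - r_rf^2)` to F(1, n - 2). Data lying exactly on
#' the hypothesized line give `r_rf = 0` and p = 1.
#'
#' @param x,y Numeric vectors (log scale).
#' @param null_slope Hypothesized slope (default 1).
#' @return A one-row tibble with `statistic` (F), `df1`, `df2`, `p` and
#'   `r_rf`.
#' @export
sma_slope_test <- function(x, y, null_slope = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n <= 3) stop("slope test requires n > 3", call. = FALSE)
  r_rf <- .sma_resid_axis_cor(x, y, null_slope)
  F_ <- r_rf^2 * (n - 2) / (1 - r_rf^2)
  tibble::tibble(statistic = F_, df1 = 1, df2 = n - 2,
                 p = stats::pf(F_, 1, n - 2, lower.tail = FALSE),
                 r_rf = r_rf)
}

#' Bivariate allometry against the geometric-mean size proxy
#'
#' Runs the bivariate stage for every (taxon, form, pair) series: per
#' variable, an SMA regression of log10 measurement on log10 geometric-mean
#' size, an F-test of deviation from isometry (slope 1.0), and a trend
#' classification at the Bonferroni-corrected level
#' `alpha / (number of regressions fitted for the series)` -- 0.05/14 = 0.0036
#' for a complete 14-variable series. Within a pair both forms use the
#' identical proxy variable set (the pair's common variables), so sizes are
#' comparable across forms; the dependent variable is not excluded from its
#' own geometric mean. Normality of the size proxy is checked per series
#' (advisory; see [size_normality()]).
#'
#' @param data A growth tibble.
#' @param alpha Family-wise significance level before correction (default
#'   0.05).
#' @param proxy Optional fixed proxy variable set; default is the per-pair
#'   common variable set.
#' @param ci_level Confidence level for slope intervals.
#' @return A `bivar_allometry` tibble, one row per series x variable:
#'   `taxon`, `form`, `pair`, `variable`, `n`, `slope`, `intercept`, `r`,
#'   `ci_low`, `ci_high`, `p_isometry`, `alpha_corrected`, `trend`
#'   (`+`/`=`/`-`). Per-series normality checks are attached as the
#'   `"normality"` attribute and returned by [glance()].
#' @export
bivar_allometry <- function(data, alpha = 0.05, proxy = NULL,
                            ci_level = 0.95) {
  .stop_on_errors(data)
  rows <- list()
  norms <- list()
  for (pp in split(data, data$pair)) {
    pvars <- proxy %||% (
      if (all(c("wild", "domestic") %in% pp$form)) {
        common_variables(pp, min_n = 3)
      } else {
        # single-form input: use that form's variables with data
        vv <- measurement_variables(pp)
        canonical_variable_order(
          vv[vapply(vv, function(v) sum(!is.na(pp[[v]])) >= 3, logical(1))])
      })
    for (ser in split(pp, paste(pp$taxon, pp$form, sep = "\r"))) {
      sz <- suppressWarnings(geometric_mean_size(ser, pvars))
      gm_by_spec <- stats::setNames(sz$gm, sz$specimen)
      vars <- pvars[vapply(pvars, function(v) any(!is.na(ser[[v]])),
                           logical(1))]
      n_tests <- length(vars)
      a_corr <- alpha / n_tests
      nrm <- tryCatch(suppressWarnings(size_normality(sz)),
                      error = function(e) tibble::tibble(
                        W = NA_real_, p = NA_real_, n = nrow(sz)))
      norms[[length(norms) + 1]] <- dplyr::mutate(
        nrm, taxon = ser$taxon[1], form = ser$form[1], pair = ser$pair[1],
        .before = 1)
      if (!is.na(nrm$p) && nrm$p < 0.05) {
        warning("series ", ser$taxon[1], " (", ser$form[1],
                "): size proxy departs from normality (Shapiro-Wilk p = ",
                signif(nrm$p, 3), ")", call. = FALSE)
      }
      for (v in vars) {
        keep <- !is.na(ser[[v]]) & ser$specimen %in% names(gm_by_spec)
        yv <- log10(ser[[v]][keep])
        xv <- log10(unname(gm_by_spec[ser$specimen[keep]]))
        fit <- sma_fit(xv, yv, ci_level)
        iso <- sma_slope_test(xv, yv, null_slope = 1)
        trend <- if (iso$p >= a_corr) "="
                 else if (fit$slope > 1) "+" else "-"
        rows[[length(rows) + 1]] <- tibble::tibble(
          taxon = ser$taxon[1], form = ser$form[1], pair = ser$pair[1],
          variable = v, n = fit$n, slope = fit$slope,
          intercept = fit$intercept, r = fit$r,
          ci_low = fit$ci_low, ci_high = fit$ci_high,
          p_isometry = iso$p, alpha_corrected = a_corr, trend = trend
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(
    tibble::new_tibble(out, class = "bivar_allometry"),
    normality = dplyr::bind_rows(norms),
    alpha = alpha
  )
}

#' @export
tidy.bivar_allometry <- function(x, ...) {
  tibble::as_tibble(unclass(x)[!names(unclass(x)) %in% "normality"])
}

#' @rdname bivar_allometry
#' @param x,object A `bivar_allometry` object.
#' @param ... Unused.
#' @export
glance.bivar_allometry <- function(x, ...) {
  attr(x, "normality")
}

#' Plot bivariate allometric slopes
#'
#' SMA slopes with confidence intervals per variable and series, with the
#' isometric slope 1 as a dashed reference line.
#'
#' @param object A `bivar_allometry` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bivar_allometry <- function(object, ...) {
  df <- tidy(object)
  df$variable <- factor(df$variable, levels = canonical_variable_order(
    unique(df$variable)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$slope,
                                   colour = .data$trend)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~ taxon + form) +
    ggplot2::scale_colour_manual(
      values = c("+" = "#D55E00", "=" = "grey30", "-" = "#0072B2")) +
    ggplot2::labs(x = NULL, y = "SMA slope vs log10 geometric mean",
                  colour = "trend") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
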