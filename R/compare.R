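# Minus twice the log likelihood ratio profile for a common SMA slope b over
# a list of groups (each a list with x, y, n): under a common slope the
# residual scores (y - b x) and axis scores (y + b x) are uncorrelated within
# each group, so the statistic accumulates -n_i * log(1 - r_i(b)^2).
.common_slope_profile <- function(groups, b) {
  sum(vapply(groups, function(g) {
    r <- .sma_resid_axis_cor(g$x, g$y, b)
    -g$n * log(max(1 - r^2, 1e-300))
  }, numeric(1)))
}

#' Likelihood-ratio test of a common SMA slope
#'
#' Tests H0: the two groups share one SMA slope. The common slope is
#' estimated by minimizing the likelihood-ratio profile (bracketed search
#' between, and slightly beyond, the two group slopes); the minimized
#' statistic is referred to a chi-squared distribution with 1 degree of
#' freedom. The sampling variance of the common slope (from the curvature of
#' the profile at its minimum) is returned for use by the elevation test.
#'
#' @param x_wild,y_wild,x_dom,y_dom Numeric vectors (log scale) for the two
#'   groups (conventionally wild and domestic).
#' @param tol Convergence tolerance of the slope search (default 1e-10).
#' @return A one-row tibble: `statistic` (LR), `df`, `p`, `common_slope`,
#'   `var_common_slope`, `slope_wild`, `slope_dom`.
#' @export
sma_common_slope_test <- function(x_wild, y_wild, x_dom, y_dom, tol = 1e-10) {
  g <- list(list(x = x_wild, y = y_wild, n = length(x_wild)),
            list(x = x_dom, y = y_dom, n = length(x_dom)))
  if (any(vapply(g, function(gg) gg$n < 3, logical(1)))) {
    stop("common-slope test requires n >= 3 in both groups", call. = FALSE)
  }
  b1 <- sma_fit(x_wild, y_wild)$slope
  b2 <- sma_fit(x_dom, y_dom)$slope
  span <- max(abs(b2 - b1), 0.25 * max(abs(b1), abs(b2)), 0.01)
  lo <- min(b1, b2) - 0.5 * span
  hi <- max(b1, b2) + 0.5 * span
  opt <- stats::optimize(function(b) .common_slope_profile(g, b),
                         lower = lo, upper = hi, tol = tol)
  # widen the bracket if the optimum sits on an edge
  tries <- 0
  while ((opt$minimum - lo < 2 * tol || hi - opt$minimum < 2 * tol) &&
         tries < 20) {
    lo <- lo - span; hi <- hi + span; tries <- tries + 1
    opt <- stats::optimize(function(b) .common_slope_profile(g, b),
                           lower = lo, upper = hi, tol = tol)
  }
  if (tries >= 20) {
    stop("common-slope search failed to bracket a minimum (slopes ",
         signif(b1, 4), " and ", signif(b2, 4), ")", call. = FALSE)
  }
  bc <- opt$minimum
  lr <- max(opt$objective, 0)
  h <- max(1e-5, abs(bc) * 1e-4)
  curv <- (.common_slope_profile(g, bc + h) - 2 * opt$objective +
             .common_slope_profile(g, bc - h)) / h^2
  varb <- if (is.finite(curv) && curv > 0) 2 / curv else NA_real_
  tibble::tibble(
    statistic = lr, df = 1,
    p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    common_slope = bc, var_common_slope = varb,
    slope_wild = b1, slope_dom = b2
  )
}

#' Wald test of common elevation (intercept) given a common slope
#'
#' Given an accepted common SMA slope, compares the elevations
#' `a_i = mean(y_i) - b * mean(x_i)` of the two groups with a Wald statistic
#' referred to chi-squared with 1 df. The variance of the elevation
#' difference accounts for residual variation in both groups and for the
#' uncertainty of the shared slope estimate.
#'
#' @inheritParams sma_common_slope_test
#' @param common_slope Common slope estimate (from
#'   [sma_common_slope_test()]).
#' @param var_common_slope Its sampling variance; 0 treats the slope as
#'   known.
#' @return A one-row tibble: `statistic`, `df`, `p`, `intercept_wild`,
#'   `intercept_dom`, `higher` (`"domestic"`, `"wild"` or `"tie"`).
#' @export
sma_elevation_test <- function(x_wild, y_wild, x_dom, y_dom, common_slope,
                               var_common_slope = 0) {
  if (is.na(var_common_slope)) var_common_slope <- 0
  a_w <- mean(y_wild) - common_slope * mean(x_wild)
  a_d <- mean(y_dom) - common_slope * mean(x_dom)
  vres <- function(x, y) stats::var(y - common_slope * x) / length(x)
  v <- vres(x_wild, y_wild) + vres(x_dom, y_dom) +
    (mean(x_wild) - mean(x_dom))^2 * var_common_slope
  stat <- if (v > 0) (a_w - a_d)^2 / v else 0
  tibble::tibble(
    statistic = stat, df = 1,
    p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    intercept_wild = a_w, intercept_dom = a_d,
    higher = if (a_d > a_w) "domestic" else if (a_d < a_w) "wild" else "tie"
  )
}

#' Wald test of a shift along the common axis
#'
#' Given a shared slope and elevation, tests whether one group is displaced
#' along the common fitted axis -- an extension or truncation of the growth
#' trajectory. The axis scores `y + b x` of the two groups are compared with
#' a Wald test of equal means (chi-squared, 1 df); the direction reports
#' which form extends further along the axis when the test is significant at
#' `alpha`.
#'
#' @inheritParams sma_elevation_test
#' @param alpha Significance level used to set the reported direction
#'   (default 0.05).
#' @return A one-row tibble: `statistic`, `df`, `p`, `axis_mean_wild`,
#'   `axis_mean_dom`, `direction` (`"domestic_extends"`, `"wild_extends"` or
#'   `"none"`).
#' @export
sma_shift_test <- function(x_wild, y_wild, x_dom, y_dom, common_slope,
                           alpha = 0.05) {
  f_w <- y_wild + common_slope * x_wild
  f_d <- y_dom + common_slope * x_dom
  v <- stats::var(f_w) / length(f_w) + stats::var(f_d) / length(f_d)
  stat <- if (v > 0) (mean(f_d) - mean(f_w))^2 / v else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  direction <- if (p >= alpha) "none"
               else if (mean(f_d) > mean(f_w)) "domestic_extends"
               else "wild_extends"
  tibble::tibble(
    statistic = stat, df = 1, p = p,
    axis_mean_wild = mean(f_w), axis_mean_dom = mean(f_d),
    direction = direction
  )
}

#' Heterochrony labels and their developmental processes
#'
#' The six heterochrony outcomes plus `no_change`, and the mapping onto
#' peramorphosis (extended development: acceleration, hypermorphosis,
#' pre-displacement) versus paedomorphosis (truncated development:
#' deceleration, hypomorphosis, post-displacement).
#'
#' @format A named character vector mapping label to process.
#' @export
heterochrony_processes <- c(
  acceleration = "peramorphosis",
  hypermorphosis = "peramorphosis",
  pre_displacement = "peramorphosis",
  deceleration = "paedomorphosis",
  hypomorphosis = "paedomorphosis",
  post_displacement = "paedomorphosis",
  no_change = "none"
)

#' Classify a trajectory comparison into the heterochrony vocabulary
#'
#' Gated decision tree over the three comparison tests, treating the wild
#' form as the ancestral condition: (1) if the slopes differ, a larger
#' domestic slope is acceleration and a smaller one deceleration; (2) else if
#' the elevations differ, a higher domestic intercept maps to
#' pre-displacement and a lower one to post-displacement (the polarity is a
#' convention and can be flipped); (3) else if a shift along the common axis
#' is significant, an extension of the domestic trajectory is hypermorphosis
#' and a truncation hypomorphosis; (4) otherwise no change. Later tests are
#' only consulted when every earlier test is non-significant at `alpha`.
#'
#' @param slope_p,intercept_p,shift_p P-values of the gated tests (later ones
#'   may be `NA` when not reached).
#' @param slope_dom_gt_wild Logical: domestic SMA slope exceeds the wild one.
#' @param intercept_higher `"domestic"`, `"wild"` or `"tie"`.
#' @param shift_direction `"domestic_extends"`, `"wild_extends"` or
#'   `"none"`.
#' @param alpha Significance level applied to each test (typically the
#'   Bonferroni-corrected level).
#' @param intercept_polarity `"higher_dom_pre"` (default) or
#'   `"higher_dom_post"`: which displacement a higher domestic intercept maps
#'   to.
#' @return A list with `label` and `process`.
#' @export
classify_heterochrony <- function(slope_p, intercept_p, shift_p,
                                  slope_dom_gt_wild, intercept_higher,
                                  shift_direction, alpha,
                                  intercept_polarity = c("higher_dom_pre",
                                                         "higher_dom_post")) {
  intercept_polarity <- match.arg(intercept_polarity)
  label <-
    if (!is.na(slope_p) && slope_p < alpha) {
      if (slope_dom_gt_wild) "acceleration" else "deceleration"
    } else if (!is.na(intercept_p) && intercept_p < alpha) {
      hi_dom <- identical(intercept_higher, "domestic")
      if (intercept_polarity == "higher_dom_pre") {
        if (hi_dom) "pre_displacement" else "post_displacement"
      } else {
        if (hi_dom) "post_displacement" else "pre_displacement"
      }
    } else if (!is.na(shift_p) && shift_p < alpha &&
               shift_direction != "none") {
      if (shift_direction == "domestic_extends") "hypermorphosis"
      else "hypomorphosis"
    } else {
      "no_change"
    }
  list(label = label, process = unname(heterochrony_processes[label]))
}

#' Compare wild and domestic growth trajectories variable by variable
#'
#' For every pair in the table and every common variable, compares the wild
#' and domestic bivariate trajectories (log10 measurement vs log10
#' geometric-mean size, both forms sharing the pair's proxy variable set)
#' through the gated sequence common-slope test, elevation (intercept) test,
#' shift test, each at the Bonferroni-corrected level
#' `alpha / (number of variables compared)`. Outcomes are classified with
#' [classify_heterochrony()]. Tests later in the chain are reported as `NA`
#' when an earlier test was significant.
#'
#' @param data A growth tibble with wild and domestic rows per pair.
#' @param alpha Family-wise significance level before correction (default
#'   0.05).
#' @param proxy Optional fixed proxy variable set.
#' @param intercept_polarity See [classify_heterochrony()].
#' @return A `trajectory_comparison` tibble, one row per pair x variable:
#'   slopes, the three test statistics/p-values, the shift direction,
#'   `label` and `process`. Per-pair tallies are available via [glance()] /
#'   [pair_summary()].
#' @examples
#' pair <- generate_pair("acceleration", n = 60, seed = 2)
#' cmp <- compare_trajectories(pair$data)
#' cmp[, c("variable", "label", "process")]
#' @export
compare_trajectories <- function(data, alpha = 0.05, proxy = NULL,
                                 intercept_polarity = c("higher_dom_pre",
                                                        "higher_dom_post")) {
  intercept_polarity <- match.arg(intercept_polarity)
  .stop_on_errors(data)
  rows <- list()
  for (pp in split(data, data$pair)) {
    if (!all(c("wild", "domestic") %in% pp$form)) {
      stop("pair ", pp$pair[1], " lacks a wild or a domestic series",
           call. = FALSE)
    }
    vars <- proxy %||% common_variables(pp, min_n = 3)
    a_corr <- alpha / length(vars)
    grp <- function(form, v) {
      ser <- pp[pp$form == form, , drop = FALSE]
      sz <- suppressWarnings(geometric_mean_size(ser, vars))
      keep <- ser$specimen %in% sz$specimen & !is.na(ser[[v]])
      gm <- stats::setNames(sz$gm, sz$specimen)
      list(x = log10(unname(gm[ser$specimen[keep]])),
           y = log10(ser[[v]][keep]))
    }
    for (v in vars) {
      w <- grp("wild", v)
      d <- grp("domestic", v)
      st <- sma_common_slope_test(w$x, w$y, d$x, d$y)
      it <- sh <- NULL
      if (st$p >= a_corr) {
        it <- sma_elevation_test(w$x, w$y, d$x, d$y, st$common_slope,
                                 st$var_common_slope)
        if (it$p >= a_corr) {
          sh <- sma_shift_test(w$x, w$y, d$x, d$y, st$common_slope,
                               alpha = a_corr)
        }
      }
      cls <- classify_heterochrony(
        slope_p = st$p,
        intercept_p = if (is.null(it)) NA_real_ else it$p,
        shift_p = if (is.null(sh)) NA_real_ else sh$p,
        slope_dom_gt_wild = st$slope_dom > st$slope_wild,
        intercept_higher = if (is.null(it)) NA_character_ else it$higher,
        shift_direction = if (is.null(sh)) "none" else sh$direction,
        alpha = a_corr, intercept_polarity = intercept_polarity
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        pair = pp$pair[1], variable = v,
        alpha_corrected = a_corr,
        slope_wild = st$slope_wild, slope_dom = st$slope_dom,
        common_slope = st$common_slope,
        slope_stat = st$statistic, slope_p = st$p,
        intercept_wild = if (is.null(it)) NA_real_ else it$intercept_wild,
        intercept_dom = if (is.null(it)) NA_real_ else it$intercept_dom,
        intercept_stat = if (is.null(it)) NA_real_ else it$statistic,
        intercept_p = if (is.null(it)) NA_real_ else it$p,
        intercept_higher = if (is.null(it)) NA_character_ else it$higher,
        shift_stat = if (is.null(sh)) NA_real_ else sh$statistic,
        shift_p = if (is.null(sh)) NA_real_ else sh$p,
        shift_direction = if (is.null(sh)) NA_character_ else sh$direction,
        label = cls$label, process = cls$process
      )
    }
  }
  structure(
    tibble::new_tibble(dplyr::bind_rows(rows),
                       class = "trajectory_comparison"),
    alpha = alpha, intercept_polarity = intercept_polarity
  )
}

#' Per-pair tallies of trajectory comparisons
#'
#' Summarizes a [compare_trajectories()] result into the counts conventionally
#' reported per pair: variables with different slopes split by which form is
#' steeper, different intercepts split by the higher form, significant shifts
#' split by direction, heterochronic events counted per variable
#' (`label != "no_change"`) and per significant test, and per-label tallies.
#'
#' @param comparison A `trajectory_comparison` tibble.
#' @return A tibble with one row per pair.
#' @export
pair_summary <- function(comparison) {
  df <- tibble::as_tibble(comparison)
  df |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      n_variables = dplyr::n(),
      n_diff_slope_dom_gt_wild = sum(
        .data$slope_p < .data$alpha_corrected & .data$slope_dom > .data$slope_wild),
      n_diff_slope_wild_gt_dom = sum(
        .data$slope_p < .data$alpha_corrected & .data$slope_dom < .data$slope_wild),
      n_diff_intercept_dom_higher = sum(
        !is.na(.data$intercept_p) & .data$intercept_p < .data$alpha_corrected &
          .data$intercept_higher == "domestic"),
      n_diff_intercept_wild_higher = sum(
        !is.na(.data$intercept_p) & .data$intercept_p < .data$alpha_corrected &
          .data$intercept_higher == "wild"),
      n_shift_domestic = sum(!is.na(.data$shift_direction) &
                               .data$shift_direction == "domestic_extends"),
      n_shift_wild = sum(!is.na(.data$shift_direction) &
                           .data$shift_direction == "wild_extends"),
      n_no_change = sum(.data$label == "no_change"),
      n_heterochronic_events = sum(.data$label != "no_change"),
      n_significant_tests = sum(.data$slope_p < .data$alpha_corrected) +
        sum(!is.na(.data$intercept_p) &
              .data$intercept_p < .data$alpha_corrected) +
        sum(!is.na(.data$shift_p) & .data$shift_p < .data$alpha_corrected),
      n_peramorphosis = sum(.data$process == "peramorphosis"),
      n_paedomorphosis = sum(.data$process == "paedomorphosis"),
      .groups = "drop"
    )
}

#' @export
glance.trajectory_comparison <- function(x, ...) {
  pair_summary(x)
}

#' @export
tidy.trajectory_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot heterochrony outcomes per pair
#'
#' A tile map of the per-variable heterochrony label for every pair.
#'
#' @param object A `trajectory_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$variable <- factor(df$variable, levels = canonical_variable_order(
    unique(df$variable)))
  df$label <- factor(df$label, levels = names(heterochrony_processes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$pair,
                                   fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_brewer(palette = "RdBu", drop = FALSE,
                               na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "heterochrony") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
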