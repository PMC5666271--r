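#' Distance between two confidence intervals
#'
#' The gap between two intervals: zero when they intersect, otherwise the
#' distance between the nearer pair of endpoints. This is the per-variable
#' ingredient of the "added change" divergence metric.
#'
#' @param ci_a,ci_b Numeric length-2 vectors `c(low, high)`.
#' @return A list with `distance` (non-negative) and `overlap` (logical).
#' @examples
#' interval_distance(c(0.1, 0.2), c(0.3, 0.4)) # gap of 0.1
#' @export
interval_distance <- function(ci_a, ci_b) {
  stopifnot(length(ci_a) == 2, length(ci_b) == 2,
            ci_a[1] <= ci_a[2], ci_b[1] <= ci_b[2])
  d <- max(0, ci_b[1] - ci_a[2], ci_a[1] - ci_b[2])
  list(distance = d, overlap = d == 0)
}

.divergence_rows <- function(wild, dom, pair_id) {
  vars <- intersect(wild$variable, dom$variable)
  if (length(vars) < length(union(wild$variable, dom$variable))) {
    warning("pair ", pair_id, ": variable sets differ; restricting to the ",
            length(vars), " common variables", call. = FALSE)
  }
  if (length(vars) == 0) stop("no common variables in pair", call. = FALSE)
  vars <- canonical_variable_order(vars)
  w <- wild[match(vars, wild$variable), ]
  d <- dom[match(vars, dom$variable), ]
  dist <- pmax(0, d$ci_low - w$ci_high, w$ci_low - d$ci_high)
  tibble::tibble(
    pair = pair_id,
    variable = vars,
    wild_sign = w$sign,
    domestic_sign = d$sign,
    distance = dist,
    overlap = dist == 0,
    sign_disagreement = w$sign != d$sign
  )
}

#' Divergence between one wild and one domestic multivariate result
#'
#' Compares the confidence intervals of the multivariate allometry
#' coefficients of the two forms variable by variable: the interval gap
#' ([interval_distance()]), whether the intervals overlap, and whether the
#' two forms were assigned different allometric signs (which can happen even
#' with overlapping intervals when only one interval contains the isometric
#' value). The sum of the gaps over the common variable set is the pair's
#' "added change". The comparison is symmetric in its two arguments.
#'
#' @param wild,domestic `multivar_allometry` tibbles each holding a single
#'   series (or the rows of one form).
#' @return A `pair_divergence` tibble with one row per common variable and an
#'   `added_change` attribute.
#' @export
pair_divergence <- function(wild, domestic) {
  stopifnot(is.data.frame(wild), is.data.frame(domestic))
  pair_id <- unique(c(wild$pair, domestic$pair))
  if (length(pair_id) != 1) {
    stop("wild and domestic results must share one pair id", call. = FALSE)
  }
  out <- .divergence_rows(wild, domestic, pair_id)
  structure(
    tibble::new_tibble(out, class = "pair_divergence"),
    added_change = sum(out$distance)
  )
}

#' Divergence for every wild-domestic pair in a multivariate result
#'
#' Applies [pair_divergence()] to each pair present in a
#' [multivar_allometry()] result.
#'
#' @param multivar A `multivar_allometry` tibble containing wild and domestic
#'   rows for one or more pairs.
#' @return A `pair_divergence` tibble over all pairs.
#' @export
trajectory_divergence <- function(multivar) {
  df <- tibble::as_tibble(unclass(multivar)[c("taxon", "form", "pair",
                                              "variable", "ci_low", "ci_high",
                                              "sign")])
  out <- lapply(split(df, df$pair), function(pp) {
    w <- pp[pp$form == "wild", ]
    d <- pp[pp$form == "domestic", ]
    if (nrow(w) == 0 || nrow(d) == 0) {
      stop("pair ", pp$pair[1], " lacks a wild or a domestic series",
           call. = FALSE)
    }
    .divergence_rows(w, d, pp$pair[1])
  })
  out <- dplyr::bind_rows(out)
  tibble::new_tibble(out, class = "pair_divergence")
}

#' Summarize divergences across pairs
#'
#' Tabulates per-variable interval gaps as a pairs-by-variables matrix and
#' accumulates them into "added change" marginals: the row sums are the
#' per-pair added change (used to rank pairs by how far the domestic
#' trajectory has moved from the wild one) and the column sums the per-variable
#' added change across all pairs. Variables missing for a pair contribute to
#' neither marginal.
#'
#' @param divergence A `pair_divergence` tibble (one or more pairs).
#' @return A `divergence_summary` list with elements `matrix` (wide tibble,
#'   one row per pair, `NA` for missing variables), `pair_added_change`
#'   (ranked tibble), `variable_added_change` (tibble in canonical variable
#'   order), and `total`.
#' @export
divergence_summary <- function(divergence) {
  stopifnot(nrow(divergence) >= 1)
  long <- tibble::as_tibble(divergence)
  wide <- tidyr::pivot_wider(long[, c("pair", "variable", "distance")],
                             names_from = "variable",
                             values_from = "distance")
  vars <- canonical_variable_order(unique(long$variable))
  wide <- wide[, c("pair", vars)]
  pair_tot <- long |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(added_change = sum(.data$distance),
                     n_variables = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$added_change)) |>
    dplyr::mutate(rank = dplyr::row_number())
  var_tot <- long |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(added_change = sum(.data$distance),
                     n_pairs = dplyr::n(), .groups = "drop")
  var_tot <- var_tot[match(vars, var_tot$variable), ]
  structure(
    list(matrix = wide, pair_added_change = pair_tot,
         variable_added_change = var_tot,
         total = sum(long$distance)),
    class = "divergence_summary"
  )
}

#' @export
tidy.divergence_summary <- function(x, ...) {
  tidyr::pivot_longer(x$matrix, -"pair", names_to = "variable",
                      values_to = "distance", values_drop_na = TRUE)
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("Trajectory divergence (added change) across",
      nrow(x$matrix), "pair(s)\n\n")
  print(x$matrix, n = Inf)
  cat("\nPer-pair added change:\n")
  print(x$pair_added_change, n = Inf)
  invisible(x)
}

#' Plot per-pair added change
#'
#' @param object A `divergence_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.divergence_summary <- function(object, ...) {
  df <- object$pair_added_change
  df$pair <- factor(df$pair, levels = rev(df$pair))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$added_change, y = .data$pair)) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::labs(x = "added change", y = NULL) +
    ggplot2::theme_minimal()
}
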