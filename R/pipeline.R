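#' Pipeline configuration
#'
#' Bundles the tunable parameters of [run_pipeline()]. Defaults: family-wise
#' alpha 0.05 (Bonferroni-corrected per series by the number of regressions),
#' 95% jackknife confidence intervals, trimming depth m = 1 with automatic
#' untrimmed/trimmed mode selection, and 3-decimal display rounding for
#' coefficients (p-values are displayed at 4 decimals).
#'
#' @param alpha Family-wise significance level.
#' @param ci_level Jackknife confidence level.
#' @param trim_mode `"auto"`, `"untrimmed"` or `"trimmed"`.
#' @param trim_m Trimming depth m.
#' @param ci_multiplier `"t"` or `"2sd"` (see [jackknife_ci()]).
#' @param intercept_polarity See [classify_heterochrony()].
#' @param rounding Display rounding for coefficients and added change.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, ci_level = 0.95,
                            trim_mode = "auto", trim_m = 1,
                            ci_multiplier = "t",
                            intercept_polarity = "higher_dom_pre",
                            rounding = 3) {
  structure(
    list(alpha = alpha, ci_level = ci_level, trim_mode = trim_mode,
         trim_m = trim_m, ci_multiplier = ci_multiplier,
         intercept_polarity = intercept_polarity, rounding = rounding),
    class = "pipeline_config"
  )
}

#' Render the per-form allometric sign table
#'
#' One row per series: the positional sign string over the requested variable
#' set (`?` marks variables not analyzed for that series), the
#' untrimmed/trimmed mode flag (`U`/`T`), and compact totals such as
#' `"6P,1I,7N"`. The sign string round-trips through [parse_sign_string()].
#'
#' @param multivar A [multivar_allometry()] result.
#' @param variables Variable order for the string columns (default the
#'   canonical 14 codes restricted/extended to those present).
#' @return A tibble with columns `taxon`, `form`, `pair`, `mode`, `signs`,
#'   `totals`.
#' @export
render_sign_table <- function(multivar, variables = NULL) {
  df <- tibble::as_tibble(multivar)
  variables <- variables %||% {
    present <- unique(df$variable)
    if (all(present %in% skull_variables)) skull_variables
    else canonical_variable_order(present)
  }
  df |>
    dplyr::group_by(.data$taxon, .data$form, .data$pair) |>
    dplyr::group_modify(function(g, key) {
      signs <- stats::setNames(rep("?", length(variables)), variables)
      hit <- intersect(variables, g$variable)
      signs[hit] <- g$sign[match(hit, g$variable)]
      pat <- sign_pattern(signs, variables)
      tibble::tibble(
        mode = g$mode[1],
        signs = render_sign_string(pat),
        totals = format_sign_totals(summarize_signs(pat))
      )
    }) |>
    dplyr::ungroup()
}

#' Run the full trajectory-comparison pipeline
#'
#' Orchestrates every stage over a growth table (or a CSV path): validation,
#' multivariate allometry with jackknife confidence intervals for every
#' series, the per-form sign table, wild-vs-domestic interval divergence with
#' added-change marginals, bivariate SMA allometry against the geometric-mean
#' size proxy, and the gated per-variable trajectory comparisons with
#' heterochrony labels and per-pair tallies. Validation errors abort the run.
#'
#' @param data A growth tibble or a path to a CSV file.
#' @param config A [pipeline_config()].
#' @param sep Field separator when `data` is a path.
#' @return An `ontotraj_pipeline` list: `validation`, `multivar`,
#'   `sign_table`, `divergence`, `divergence_summary`, `bivar`,
#'   `comparisons`, `pair_summaries`, `config`.
#' @examples
#' study <- make_study_fixture(n_pairs = 2, n = 30, seed = 1)
#' res <- run_pipeline(study$data)
#' res$divergence_summary$pair_added_change
#' @export
run_pipeline <- function(data, config = pipeline_config(), sep = ",") {
  if (is.character(data)) data <- read_growth_table(data, sep = sep)
  report <- growth_findings(data)
  .stop_on_errors(data)
  multivar <- multivar_allometry(
    data, trim_m = config$trim_m, ci_level = config$ci_level,
    mode = switch(config$trim_mode, U = "untrimmed", T = "trimmed",
                  config$trim_mode),
    ci_multiplier = config$ci_multiplier
  )
  div <- trajectory_divergence(multivar)
  bivar <- bivar_allometry(data, alpha = config$alpha,
                           ci_level = config$ci_level)
  cmp <- compare_trajectories(data, alpha = config$alpha,
                              intercept_polarity = config$intercept_polarity)
  structure(
    list(
      validation = report,
      multivar = multivar,
      sign_table = render_sign_table(multivar),
      divergence = div,
      divergence_summary = divergence_summary(div),
      bivar = bivar,
      comparisons = cmp,
      pair_summaries = pair_summary(cmp),
      config = config
    ),
    class = "ontotraj_pipeline"
  )
}

#' @export
print.ontotraj_pipeline <- function(x, ...) {
  r <- x$config$rounding
  cat("ontotraj pipeline result\n")
  cat("  series analyzed:", nrow(glance(x$multivar)), "\n")
  cat("  pairs compared: ", nrow(x$divergence_summary$matrix), "\n\n")
  cat("Sign table:\n")
  print(x$sign_table, n = Inf)
  cat("\nAdded change per pair (", r, " d.p.):\n", sep = "")
  tot <- x$divergence_summary$pair_added_change
  tot$added_change <- round(tot$added_change, r)
  print(tot, n = Inf)
  cat("\nHeterochrony tallies:\n")
  print(x$pair_summaries, n = Inf)
  invisible(x)
}

#' Write every pipeline table to a directory
#'
#' Writes the stage outputs as TSV (full precision) plus one JSON bundle of
#' summaries, and the resolved configuration alongside them.
#'
#' @param pipeline An `ontotraj_pipeline` result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "ontotraj_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- function(...) file.path(dir, ...)
  write_results(tidy(pipeline$multivar), out("multivar.tsv"))
  write_results(pipeline$sign_table, out("sign_table.tsv"))
  write_results(tibble::as_tibble(pipeline$divergence), out("divergence.tsv"))
  write_results(pipeline$divergence_summary$matrix,
                out("divergence_matrix.tsv"))
  write_results(tidy(pipeline$bivar), out("bivar.tsv"))
  write_results(tibble::as_tibble(pipeline$comparisons),
                out("comparisons.tsv"))
  write_results(pipeline$pair_summaries, out("pair_summaries.tsv"))
  write_results(
    list(
      config = unclass(pipeline$config),
      pair_added_change = pipeline$divergence_summary$pair_added_change,
      variable_added_change = pipeline$divergence_summary$variable_added_change
    ),
    out("summary.json"), format = "json"
  )
  invisible(dir)
}
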