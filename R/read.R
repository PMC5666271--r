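.id_aliases <- list(
  specimen = c("specimen", "specimen_id", "id"),
  taxon    = c("taxon", "taxon_label", "species"),
  form     = c("form"),
  pair     = c("pair", "pair_id")
)

.match_id_columns <- function(nms) {
  out <- vapply(.id_aliases, function(alias) {
    hit <- which(tolower(nms) %in% alias)
    if (length(hit) > 0) hit[1] else NA_integer_
  }, integer(1))
  if (anyNA(out)) {
    # fall back to positional: first four columns are the id columns
    out[] <- seq_len(4)
  }
  out
}

#' Read a growth-series measurement table
#'
#' Reads a delimited file with one row per specimen: an identifier column,
#' taxon, form (`wild`/`domestic`), pair label, and one numeric column per
#' measurement (mm). Id columns are recognized by name (`specimen`/`id`,
#' `taxon`, `form`, `pair`); if any is missing the first four columns are used
#' positionally. Empty cells and `NA` are treated as missing. Measurement
#' columns are reordered canonically when all codes are known (see
#' [skull_variables]); otherwise file order is kept.
#'
#' Problems (non-numeric cells, non-positive measurements, duplicated
#' specimens, forms outside `wild`/`domestic`, small series) are collected
#' into a validation report attached as the `"validation"` attribute and
#' retrievable with [growth_findings()]; reading never aborts on them.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @return A tibble with columns `specimen`, `taxon`, `form`, `pair` followed
#'   by numeric measurement columns.
#' @seealso [validate_growth_table()], [growth_series_split()]
#' @export
read_growth_table <- function(path, sep = ",") {
  raw <- readr::read_delim(
    path, delim = sep, na = c("", "NA"), trim_ws = TRUE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(raw) < 5) {
    stop("expected at least 5 columns (4 id columns + measurements)", call. = FALSE)
  }
  idx <- .match_id_columns(names(raw))
  meas_idx <- setdiff(seq_along(raw), idx)
  meas_names <- names(raw)[meas_idx]

  findings <- list()
  data <- tibble::tibble(
    specimen = as.character(raw[[idx[["specimen"]]]]),
    taxon    = as.character(raw[[idx[["taxon"]]]]),
    form     = tolower(as.character(raw[[idx[["form"]]]])),
    pair     = as.character(raw[[idx[["pair"]]]])
  )
  for (j in seq_along(meas_idx)) {
    cell <- raw[[meas_idx[j]]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad) > 0) {
      findings[[length(findings) + 1]] <- tibble::tibble(
        severity = "error", specimen = data$specimen[bad],
        variable = meas_names[j],
        message = paste0("non-numeric measurement '", cell[bad], "'")
      )
    }
    data[[meas_names[j]]] <- num
  }
  if (all(meas_names %in% skull_variables)) {
    ord <- canonical_variable_order(meas_names)
    data <- data[, c("specimen", "taxon", "form", "pair", ord)]
  }
  report <- dplyr::bind_rows(
    dplyr::bind_rows(findings),
    validate_growth_table(data)
  )
  attr(data, "validation") <- report
  data
}

#' Measurement column names of a growth table
#'
#' @param data A growth tibble as returned by [read_growth_table()].
#' @return Character vector of measurement column names.
#' @export
measurement_variables <- function(data) {
  setdiff(names(data), c("specimen", "taxon", "form", "pair"))
}

#' Validate a growth table
#'
#' Checks the invariants every analysis stage relies on: measurements must be
#' strictly positive (log-transformable), specimen ids unique within a
#' (taxon, form) series, forms must be `wild` or `domestic`, and series must
#' be large enough for jackknife confidence intervals (n >= 10; a warning
#' finding is emitted for 5 <= n <= 9 and an error finding below 5).
#'
#' @param data A growth tibble.
#' @return A tibble of findings with columns `severity` (`error`/`warning`),
#'   `specimen`, `variable`, `message`; zero rows when the table is clean.
#' @export
validate_growth_table <- function(data) {
  vars <- measurement_variables(data)
  out <- list()
  add <- function(severity, specimen, variable, message) {
    out[[length(out) + 1]] <<- tibble::tibble(
      severity = severity, specimen = specimen,
      variable = variable, message = message
    )
  }
  for (v in vars) {
    bad <- which(!is.na(data[[v]]) & data[[v]] <= 0)
    if (length(bad) > 0) {
      add("error", data$specimen[bad], v, "non-positive measurement")
    }
  }
  badform <- which(!data$form %in% c("wild", "domestic"))
  if (length(badform) > 0) {
    add("error", data$specimen[badform], NA_character_,
        paste0("form must be 'wild' or 'domestic', got '",
               data$form[badform], "'"))
  }
  by_series <- split(data, paste(data$taxon, data$form, sep = "\r"))
  for (ser in by_series) {
    dup <- ser$specimen[duplicated(ser$specimen)]
    if (length(dup) > 0) {
      add("error", unique(dup), NA_character_,
          paste0("duplicate specimen id within series ", ser$taxon[1],
                 " (", ser$form[1], ")"))
    }
    n <- nrow(ser)
    if (n < 5) {
      add("error", NA_character_, NA_character_,
          paste0("series ", ser$taxon[1], " (", ser$form[1], "): n = ", n,
                 " is too small for jackknife confidence intervals"))
    } else if (n < 10) {
      add("warning", NA_character_, NA_character_,
          paste0("series ", ser$taxon[1], " (", ser$form[1], "): n = ", n,
                 " < 10; jackknife confidence intervals will be unreliable"))
    }
  }
  if (length(out) == 0) {
    tibble::tibble(severity = character(), specimen = character(),
                   variable = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Retrieve the validation report attached to a growth table
#'
#' @param data A growth tibble from [read_growth_table()].
#' @return The findings tibble, or an empty findings tibble if none attached.
#' @export
growth_findings <- function(data) {
  attr(data, "validation") %||% validate_growth_table(data)
}

.stop_on_errors <- function(data) {
  rep <- growth_findings(data)
  if (any(rep$severity == "error")) {
    msgs <- utils::head(unique(rep$message[rep$severity == "error"]), 5)
    stop("growth table has validation errors:\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  invisible(data)
}

#' Split a growth table into series
#'
#' @param data A growth tibble.
#' @return A tibble with one row per (taxon, form, pair) and a `data`
#'   list-column holding each series' specimen rows.
#' @export
growth_series_split <- function(data) {
  data |>
    dplyr::group_by(.data$taxon, .data$form, .data$pair) |>
    tidyr::nest() |>
    dplyr::ungroup()
}

#' Variables usable in both forms of a pair
#'
#' Returns the measurement variables with sufficient non-missing data
#' (at least `min_n` values) in both the wild and the domestic series of a
#' pair, in canonical order. Variables absent from one form (e.g. dentary
#' measurements unavailable for some taxa) are dropped.
#'
#' @param data A growth tibble containing (at least) one wild and one
#'   domestic series sharing `pair`.
#' @param pair Pair label to restrict to; default uses all rows.
#' @param min_n Minimum non-missing values per form (default 3).
#' @return Character vector of variable codes.
#' @export
common_variables <- function(data, pair = NULL, min_n = 3) {
  if (!is.null(pair)) data <- data[data$pair == pair, , drop = FALSE]
  vars <- measurement_variables(data)
  keep <- vapply(vars, function(v) {
    all(vapply(c("wild", "domestic"), function(f) {
      sum(!is.na(data[[v]][data$form == f])) >= min_n
    }, logical(1)))
  }, logical(1))
  out <- canonical_variable_order(vars[keep])
  if (length(out) == 0) {
    stop("no variable has sufficient data in both forms", call. = FALSE)
  }
  out
}

# Complete-case log10 matrix for one series over a variable set.
.series_matrix <- function(series, variables, log10_transform = FALSE) {
  m <- as.matrix(series[, variables, drop = FALSE])
  storage.mode(m) <- "double"
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  rownames(m) <- series$specimen[keep]
  if (any(m <= 0)) stop("non-positive measurement in series", call. = FALSE)
  if (log10_transform) log10(m) else m
}

#' Write a result table or bundle to disk
#'
#' Data frames round-trip through TSV (full numeric precision) or JSON;
#' arbitrary result lists are serialized to JSON.
#'
#' @param results A data frame or list.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(results)) {
      stop("TSV output requires a data frame", call. = FALSE)
    }
    readr::write_tsv(results, path, progress = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
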