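#' Canonical skull measurement codes
#'
#' The 14 linear skull and dentary measurements used throughout the package,
#' in their canonical display order: condylo-premaxillary length (CPL), length
#' of the nasals (LN), height of the muzzle (HM), upper post-canine row (UPR),
#' length of palate (LP), breadth of palate (BP), length of the orbit (LO),
#' zygomatic breadth (ZB), breadth of the braincase (BB), height of occipital
#' plate (HO), length of the dentary (LD), height of the dentary (HD), height
#' of the coronoid process (HC), and lower post-canine row (LPR). Allometric
#' sign strings are printed positionally in this order, so keeping it fixed
#' makes them comparable across analyses.
#'
#' @format A character vector of length 14.
#' @export
skull_variables <- c(
  "CPL", "LN", "HM", "UPR", "LP", "BP", "LO",
  "ZB", "BB", "HO", "LD", "HD", "HC", "LPR"
)

#' Order variable codes canonically
#'
#' Sorts a set of variable codes into the canonical [skull_variables] order.
#' Codes outside the canonical set keep their input order and are appended
#' after the canonical ones.
#'
#' @param vars Character vector of variable codes.
#' @return Character vector, reordered.
#' @export
canonical_variable_order <- function(vars) {
  known <- skull_variables[skull_variables %in% vars]
  c(known, setdiff(vars, skull_variables))
}

# Display minus sign (U+2212); ASCII hyphen-minus accepted on input.
.minus <- "−"

.normalize_signs <- function(x) {
  x[x == .minus] <- "-"
  x
}

#' Parse an allometric sign string
#'
#' A sign string encodes the per-variable allometric classification of one
#' growth series, one character per variable: `+` (positive allometry),
#' `=` (isometry), `-` (negative allometry; the Unicode minus is also
#' accepted) and `?` (variable not measured).
#'
#' @param text A single string over the alphabet `+ = - ?`.
#' @param variables Optional character vector naming each position; must match
#'   the string length.
#' @return A `sign_pattern` object: a character vector of signs (normalized to
#'   ASCII `-`), named when `variables` is given.
#' @examples
#' summarize_signs(parse_sign_string("++-+=-----+-++"))
#' @export
parse_sign_string <- function(text, variables = NULL) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  signs <- .normalize_signs(strsplit(text, "", fixed = TRUE)[[1]])
  bad <- setdiff(signs, c("+", "=", "-", "?"))
  if (length(bad) > 0) {
    stop("invalid sign character(s): ", paste(unique(bad), collapse = " "),
         call. = FALSE)
  }
  sign_pattern(signs, variables)
}

#' Construct a sign pattern
#'
#' @param signs Character vector over `+ = - ?` (Unicode minus accepted).
#' @param variables Optional names, same length as `signs`.
#' @return A `sign_pattern` object.
#' @export
sign_pattern <- function(signs, variables = NULL) {
  signs <- .normalize_signs(as.character(signs))
  stopifnot(all(signs %in% c("+", "=", "-", "?")))
  if (!is.null(variables)) {
    stopifnot(length(variables) == length(signs))
    names(signs) <- variables
  }
  structure(signs, class = "sign_pattern")
}

#' Tally a sign pattern
#'
#' Counts positions by allometric category, excluding missing (`?`) positions
#' from the three sign classes.
#'
#' @param pattern A `sign_pattern`, a plain character vector of signs, or a
#'   string (parsed with [parse_sign_string()]).
#' @return A one-row tibble with columns `n_pos`, `n_iso`, `n_neg`,
#'   `n_missing` and `n_total`.
#' @export
summarize_signs <- function(pattern) {
  if (is.character(pattern) && length(pattern) == 1L &&
      !inherits(pattern, "sign_pattern") && nchar(pattern) != 1L) {
    pattern <- parse_sign_string(pattern)
  }
  signs <- .normalize_signs(unclass(pattern))
  tibble::tibble(
    n_pos = sum(signs == "+"),
    n_iso = sum(signs == "="),
    n_neg = sum(signs == "-"),
    n_missing = sum(signs == "?"),
    n_total = length(signs)
  )
}

#' Render a sign pattern as a display string
#'
#' Inverse of [parse_sign_string()]; negative allometry is emitted as the
#' Unicode minus used in display tables.
#'
#' @param pattern A `sign_pattern` or character vector of signs.
#' @param unicode_minus Emit U+2212 for negative signs (default `TRUE`).
#' @return A single string.
#' @export
render_sign_string <- function(pattern, unicode_minus = TRUE) {
  signs <- .normalize_signs(unclass(pattern))
  if (unicode_minus) signs[signs == "-"] <- .minus
  paste(signs, collapse = "")
}

#' Format sign totals in the conventional compact style
#'
#' Produces strings such as `"6P,1I,7N"`; categories with zero count are
#' omitted (e.g. `"8I,2N"`), mirroring how summary tables are usually printed.
#'
#' @param totals A one-row tibble as returned by [summarize_signs()].
#' @return A single string.
#' @export
format_sign_totals <- function(totals) {
  parts <- c(
    if (totals$n_pos > 0) paste0(totals$n_pos, "P"),
    if (totals$n_iso > 0) paste0(totals$n_iso, "I"),
    if (totals$n_neg > 0) paste0(totals$n_neg, "N")
  )
  if (is.null(parts)) "0P,0I,0N" else paste(parts, collapse = ",")
}

#' @export
print.sign_pattern <- function(x, ...) {
  cat("<sign_pattern> ", render_sign_string(x), "\n", sep = "")
  tot <- summarize_signs(x)
  cat("  ", format_sign_totals(tot),
      if (tot$n_missing > 0) paste0(" (", tot$n_missing, " missing)"),
      "\n", sep = "")
  invisible(x)
}
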