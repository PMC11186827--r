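#' Ordinal hazard level
#'
#' The framework scores every indicator (occurrence, persistence,
#' transfer/accumulation, severity) and every combined quantity
#' (presence, priority) on a three-point ordinal scale
#' low < medium < high.  Levels are represented as ordered factors with
#' levels `"L" < "M" < "H"`, so the usual comparison operators and
#' `max()`/`min()` work as expected.
#'
#' @param x character vector; accepted spellings (case-insensitive) are
#'   `"L"`, `"M"`, `"H"`, `"low"`, `"medium"`, `"high"`.
#' @return an ordered factor with levels `L < M < H`.
#' @examples
#' hazard_level("low") < hazard_level("H")
#' max(hazard_level(c("M", "L", "H")))
#' @export
hazard_level <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  stopifnot(is.character(x))
  key <- c(l = "L", low = "L", m = "M", medium = "M", med = "M",
           h = "H", high = "H")
  out <- key[tolower(trimws(x))]
  if (anyNA(out) && !anyNA(x)) {
    bad <- unique(x[is.na(out)])
    stop("invalid hazard level(s): ", paste(sQuote(bad), collapse = ", "),
         " (expected L/M/H or low/medium/high)", call. = FALSE)
  }
  factor(unname(out), levels = c("L", "M", "H"), ordered = TRUE)
}

#' @rdname hazard_level
#' @export
is_hazard_level <- function(x) {
  is.ordered(x) && identical(levels(x), c("L", "M", "H")) && !anyNA(x)
}

#' Shift a level up or down the ordinal scale, clamped at L and H
#'
#' Used by the one-level sensitivity analysis: a perturbed indicator can
#' never leave the scale.
#'
#' @param level a hazard level.
#' @param by integer shift, typically -1 or +1.
#' @return the shifted hazard level.
#' @export
level_shift <- function(level, by) {
  stopifnot(is_hazard_level(level), length(level) == 1L)
  i <- min(max(as.integer(level) + as.integer(by), 1L), 3L)
  hazard_level(c("L", "M", "H")[i])
}

# single-character serialisation used in reports and configs
level_chr <- function(level) as.character(level)
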