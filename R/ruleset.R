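#' Classification rule set
#'
#' All numeric thresholds that turn quantitative evidence into ordinal
#' hazard levels live in one configurable rule set.  The defaults are
#' the thresholds used in the published case studies:
#'
#' * `dt50_bounds` (days): persistence is LOW below `low_upper` (30),
#'   HIGH above `high_lower` (100), MEDIUM in between (bounds
#'   inclusive in MEDIUM).
#' * `koc_bounds` (log10 K_OC): transfer to plants is HIGH below
#'   `high_upper_log` (1.0) — water-soluble, mobile — and LOW at or
#'   above `low_lower_log` (2.0).
#' * `baf_bounds` (dimensionless bio-accumulation factor): LOW at or
#'   below 1 (no net accumulation), HIGH above 5.
#' * `chem_conc_bounds` (ng/g dry matter) and `micro_conc_bounds`
#'   (cfu/g dry matter): occurrence class bounds for concentrations in
#'   raw materials.  These bounds are implementation defaults (round
#'   values reproducing the published case tables), not literature
#'   values, and should be reviewed per application.
#' * `exceedance_threshold` (fraction): occurrence on the
#'   exceedance pathway is HIGH when more than 3% of batches exceed
#'   the regulatory limit, LOW otherwise (binary rule).
#' * `hbgv_daily_cutoff` (ug/kg bw/day): chemical severity is HIGH when
#'   the daily-normalised health-based guidance value (ADI, TDI,
#'   BMDL10, TWI/7) is at or below 10.
#' * `daly_bounds` (DALY/case): microbial severity is LOW below 0.01,
#'   HIGH above 0.1, MEDIUM in between (inclusive).
#' * `log_reduction_bounds` (achieved log10 reductions): microbial
#'   persistence is LOW when the waiting time achieves at least
#'   `low_lower` (4) logs and HIGH below `high_upper` (2) logs.
#' * `occurrence_collapse`: how multiple occurrence measurements (one
#'   per raw-material matrix) are collapsed before classification;
#'   `"mean"` (default, the group average used in the case studies) or
#'   `"max"` (worst case).
#'
#' @param ... named overrides of the default fields (see Details).
#' @return an object of class `classification_ruleset` (a named list).
#' @examples
#' default_ruleset()
#' classification_ruleset(exceedance_threshold = 0.05)
#' @export
classification_ruleset <- function(...) {
  rules <- default_ruleset()
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all rule-set overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(rules))
    if (length(unknown)) {
      stop("unknown rule-set key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (key in names(overrides)) {
      value <- overrides[[key]]
      if (key != "occurrence_collapse") {
        value <- as.numeric(value)
        names(value) <- names(rules[[key]])
      }
      rules[[key]] <- value
    }
  }
  validate_ruleset(rules)
}

#' @rdname classification_ruleset
#' @export
default_ruleset <- function() {
  structure(list(
    dt50_bounds          = c(low_upper = 30, high_lower = 100),
    koc_bounds           = c(high_upper_log = 1.0, low_lower_log = 2.0),
    baf_bounds           = c(low_upper = 1.0, high_lower = 5.0),
    chem_conc_bounds     = c(low_upper = 1e4, high_lower = 2e4),
    micro_conc_bounds    = c(low_upper = 1e6, high_lower = 1e7),
    exceedance_threshold = 0.03,
    hbgv_daily_cutoff    = 10,
    daly_bounds          = c(low_upper = 0.01, high_lower = 0.1),
    log_reduction_bounds = c(high_upper = 2, low_lower = 4),
    occurrence_collapse  = "mean"
  ), class = "classification_ruleset")
}

validate_ruleset <- function(rules) {
  stopifnot(is.list(rules))
  pairs <- c("dt50_bounds", "baf_bounds", "chem_conc_bounds",
             "micro_conc_bounds", "daly_bounds")
  for (key in pairs) {
    b <- rules[[key]]
    if (length(b) != 2L || !is.numeric(b) || anyNA(b)) {
      stop("rule-set key ", sQuote(key), " must be two numbers", call. = FALSE)
    }
    if (b[["low_upper"]] > b[["high_lower"]]) {
      stop("rule-set key ", sQuote(key),
           ": low_upper must not exceed high_lower", call. = FALSE)
    }
  }
  kb <- rules$koc_bounds
  if (length(kb) != 2L || anyNA(kb) ||
      kb[["high_upper_log"]] > kb[["low_lower_log"]]) {
    stop("rule-set key 'koc_bounds': high_upper_log must not exceed ",
         "low_lower_log", call. = FALSE)
  }
  lb <- rules$log_reduction_bounds
  if (length(lb) != 2L || anyNA(lb) ||
      lb[["high_upper"]] > lb[["low_lower"]]) {
    stop("rule-set key 'log_reduction_bounds': high_upper must not exceed ",
         "low_lower", call. = FALSE)
  }
  et <- rules$exceedance_threshold
  if (!is.numeric(et) || length(et) != 1L || is.na(et) || et < 0 || et > 1) {
    stop("rule-set key 'exceedance_threshold' must be a fraction in [0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(rules$hbgv_daily_cutoff) || rules$hbgv_daily_cutoff < 0) {
    stop("rule-set key 'hbgv_daily_cutoff' must be non-negative",
         call. = FALSE)
  }
  if (!rules$occurrence_collapse %in% c("mean", "max")) {
    stop("rule-set key 'occurrence_collapse' must be \"mean\" or \"max\"",
         call. = FALSE)
  }
  structure(rules, class = "classification_ruleset")
}

#' Read / write a rule-set configuration file
#'
#' The on-disk format is a flat `key: value` text file whose keys are
#' exactly the `classification_ruleset` field names; two-number fields
#' are written as `key: a, b`.  Missing keys fall back to the package
#' defaults; unknown keys are rejected.  Lines starting with `#` and
#' blank lines are ignored.
#'
#' @param path path of the configuration file.
#' @return `load_ruleset()` returns a validated
#'   `classification_ruleset`; `save_ruleset()` returns `path`
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".cfg")
#' save_ruleset(classification_ruleset(exceedance_threshold = 0.05), f)
#' load_ruleset(f)$exceedance_threshold
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) stop("rule-set file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (line in lines) {
    if (!grepl(":", line, fixed = TRUE)) {
      stop("malformed rule-set line (expected 'key: value'): ",
           sQuote(line), call. = FALSE)
    }
    key <- trimws(sub(":.*$", "", line))
    raw <- trimws(sub("^[^:]*:", "", line))
    raw <- gsub("[][]", "", raw)
    if (key == "occurrence_collapse") {
      overrides[[key]] <- raw
    } else {
      value <- suppressWarnings(as.numeric(strsplit(raw, "[,[:space:]]+")[[1]]))
      if (anyNA(value)) {
        stop("malformed numeric value for rule-set key ", sQuote(key),
             ": ", sQuote(raw), call. = FALSE)
      }
      overrides[[key]] <- value
    }
  }
  do.call(classification_ruleset, overrides)
}

#' @rdname load_ruleset
#' @param rules a `classification_ruleset`.
#' @export
save_ruleset <- function(rules, path) {
  rules <- validate_ruleset(rules)
  fmt <- function(key) {
    v <- rules[[key]]
    if (is.character(v)) v else paste(format(v, scientific = FALSE,
                                             trim = TRUE), collapse = ", ")
  }
  writeLines(paste0(names(rules), ": ", vapply(names(rules), fmt, "")), path)
  invisible(path)
}

#' @export
print.classification_ruleset <- function(x, ...) {
  cat("<classification_ruleset>\n")
  for (key in names(x)) {
    v <- x[[key]]
    cat(sprintf("  %-20s %s\n", key,
                paste(format(v, scientific = FALSE, trim = TRUE),
                      collapse = ", ")))
  }
  invisible(x)
}
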