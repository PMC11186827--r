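#' Hazard profiles and the hazard registry
#'
#' A hazard profile bundles the evidence needed to prioritise one
#' hazard: one or more occurrence measurements (keyed by the
#' raw-material matrix they were measured in), persistence evidence
#' (environment route) or accumulation evidence (accumulation route),
#' transfer evidence, and severity evidence.  Profiles are normally
#' read from a registry CSV with [load_hazard_registry()].
#'
#' @section Registry CSV schema:
#' Long format, one evidence item per row, columns
#' `hazard_id, hazard_class, route, evidence_kind, compartment, value,
#' units, basis`.  `hazard_class` is `chemical` or `microbial`;
#' `route` is `environment` (occurrence -> persistence -> transfer) or
#' `accumulation` (occurrence -> accumulation in the reared animal).
#' Recognised `evidence_kind` values:
#'
#' * `occurrence_concentration` — concentration in a raw material
#'   (`compartment` = matrix label; `units` must be `ng/g dm` for
#'   chemicals, `cfu/g dm` for microbes)
#' * `occurrence_exceedance` — fraction of batches above the legal
#'   limit (dimensionless, in `[0, 1]`)
#' * `occurrence_level`, `persistence_level`, `transfer_level`,
#'   `accumulation_level`, `severity_level`, `chronic_level` —
#'   directly assigned `L`/`M`/`H`
#' * `dt50` — half-life in days (`compartment` = e.g. `manure:cattle
#'   solid`, `soil:sand`)
#' * `log_reduction` — days per 1-log reduction (microbes);
#'   `waiting_time` — days between application and harvest
#' * `log_koc` — log10 organic carbon-water partition coefficient
#' * `baf` — bio-accumulation factor
#' * `hbgv` — health-based guidance value in ug/kg bw with `basis`
#'   `per_day` or `per_week`
#' * `endpoint_flags` — `|`-separated toxicity endpoints out of
#'   `carcinogenic`, `mutagenic`, `reprotoxic`, `repeated_dose`
#' * `antibiotic_choice_class` — 1, 2 or 3 (2/3 = reserve antibiotic,
#'   high resistance concern)
#' * `daly` — disability-adjusted life years per case (microbes)
#'
#' @param path path of the registry CSV.
#' @return `load_hazard_registry()` returns a `hazard_registry`: a
#'   named list of `hazard_profile` objects in file order.
#' @examples
#' reg <- load_hazard_registry(
#'   system.file("extdata", "case1_registry.csv", package = "hazrank"))
#' names(reg)
#' @export
load_hazard_registry <- function(path) {
  if (!file.exists(path)) {
    stop("registry file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("hazard_id", "hazard_class", "route", "evidence_kind",
                "compartment", "value", "units", "basis")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("registry is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("registry is empty: ", path, call. = FALSE)
    return(structure(list(), class = "hazard_registry"))
  }
  ids <- unique(df$hazard_id)
  profiles <- lapply(ids, function(id) {
    build_profile(df[df$hazard_id == id, , drop = FALSE])
  })
  names(profiles) <- ids
  structure(profiles, class = "hazard_registry")
}

LEVEL_KINDS <- c("occurrence_level", "persistence_level", "transfer_level",
                 "accumulation_level", "severity_level", "chronic_level")

ENDPOINT_FLAGS <- c("carcinogenic", "mutagenic", "reprotoxic",
                    "repeated_dose")

build_profile <- function(rows) {
  id <- rows$hazard_id[[1L]]
  fail <- function(...) {
    stop("hazard ", sQuote(id), ": ", ..., call. = FALSE)
  }
  hazard_class <- unique(rows$hazard_class)
  route <- unique(rows$route)
  if (length(hazard_class) != 1L || !hazard_class %in% c("chemical", "microbial")) {
    fail("hazard_class must be a single value, 'chemical' or 'microbial'")
  }
  if (length(route) != 1L || !route %in% c("environment", "accumulation")) {
    fail("route must be a single value, 'environment' or 'accumulation'")
  }
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) fail("non-numeric value for ", what)
    v
  }
  kind <- rows$evidence_kind

  ## occurrence ------------------------------------------------------------
  occ_rows <- rows[kind %in% c("occurrence_concentration",
                               "occurrence_exceedance",
                               "occurrence_level"), , drop = FALSE]
  if (nrow(occ_rows) == 0L) fail("no occurrence evidence")
  expected_units <- if (hazard_class == "chemical") "ng/g dm" else "cfu/g dm"
  occurrence <- lapply(seq_len(nrow(occ_rows)), function(i) {
    r <- occ_rows[i, ]
    ev <- list(kind = r$evidence_kind, matrix = r$compartment,
               units = r$units)
    if (r$evidence_kind == "occurrence_level") {
      ev$level <- hazard_level(r$value)
    } else {
      ev$value <- num(r$value, r$evidence_kind)
      if (ev$value < 0) fail("negative occurrence value")
      if (r$evidence_kind == "occurrence_exceedance" && ev$value > 1) {
        fail("exceedance fraction must be in [0, 1]")
      }
      if (r$evidence_kind == "occurrence_concentration" &&
          r$units != expected_units) {
        fail("occurrence units ", sQuote(r$units), " do not match ",
             hazard_class, " hazard (expected ", sQuote(expected_units), ")")
      }
    }
    ev
  })

  ## persistence -----------------------------------------------------------
  dt50_rows <- rows[kind == "dt50", , drop = FALSE]
  persistence <- list()
  if (nrow(dt50_rows)) {
    v <- num(dt50_rows$value, "dt50")
    if (any(v <= 0)) fail("DT50 values must be positive")
    persistence$dt50_days_by_compartment <-
      stats::setNames(v, dt50_rows$compartment)
  }
  if (any(kind == "log_reduction")) {
    v <- num(rows$value[kind == "log_reduction"][[1L]], "log_reduction")
    if (v <= 0) fail("log_reduction (days per log) must be positive")
    persistence$log_reduction_days <- v
  }
  if (any(kind == "waiting_time")) {
    v <- num(rows$value[kind == "waiting_time"][[1L]], "waiting_time")
    if (v < 0) fail("waiting_time must be non-negative")
    persistence$waiting_time_days <- v
  }
  if (any(kind == "persistence_level")) {
    persistence$assigned_level <-
      hazard_level(rows$value[kind == "persistence_level"][[1L]])
  }

  ## transfer / accumulation ----------------------------------------------
  transfer <- NULL
  if (any(kind == "log_koc")) {
    transfer <- list(kind = "log_koc",
                     value = num(rows$value[kind == "log_koc"][[1L]],
                                 "log_koc"))
  } else if (any(kind == "transfer_level")) {
    transfer <- list(kind = "assigned_level",
                     level = hazard_level(
                       rows$value[kind == "transfer_level"][[1L]]))
  }
  accumulation <- NULL
  if (any(kind == "baf")) {
    v <- num(rows$value[kind == "baf"][[1L]], "baf")
    if (v < 0) fail("BAF must be non-negative")
    accumulation <- list(kind = "bioaccumulation_factor", value = v)
  } else if (any(kind == "accumulation_level")) {
    accumulation <- list(kind = "assigned_level",
                         level = hazard_level(
                           rows$value[kind == "accumulation_level"][[1L]]))
  }

  ## severity ---------------------------------------------------------------
  severity <- list()
  if (any(kind == "hbgv")) {
    i <- which(kind == "hbgv")[[1L]]
    basis <- rows$basis[[i]]
    if (!basis %in% c("per_day", "per_week")) {
      fail("hbgv basis must be 'per_day' or 'per_week'")
    }
    severity$hbgv_value <- num(rows$value[[i]], "hbgv")
    if (severity$hbgv_value < 0) fail("hbgv must be non-negative")
    severity$hbgv_basis <- basis
  }
  if (any(kind == "endpoint_flags")) {
    flags <- strsplit(rows$value[kind == "endpoint_flags"][[1L]], "|",
                      fixed = TRUE)[[1L]]
    flags <- trimws(flags)
    bad <- setdiff(flags, ENDPOINT_FLAGS)
    if (length(bad)) fail("unknown endpoint flag(s): ",
                          paste(bad, collapse = ", "))
    severity$endpoint_flags <- flags
  }
  if (any(kind == "antibiotic_choice_class")) {
    v <- num(rows$value[kind == "antibiotic_choice_class"][[1L]],
             "antibiotic_choice_class")
    if (!v %in% 1:3) fail("antibiotic_choice_class must be 1, 2 or 3")
    severity$antibiotic_choice_class <- as.integer(v)
  }
  if (any(kind == "chronic_level")) {
    severity$chronic_level <-
      hazard_level(rows$value[kind == "chronic_level"][[1L]])
  }
  if (any(kind == "daly")) {
    v <- num(rows$value[kind == "daly"][[1L]], "daly")
    if (v < 0) fail("DALY/case must be non-negative")
    severity$daly_per_case <- v
  }
  if (any(kind == "severity_level")) {
    severity$assigned_level <-
      hazard_level(rows$value[kind == "severity_level"][[1L]])
  }
  severity$kind <- if (hazard_class == "microbial") {
    "microbial"
  } else if (!is.null(severity$antibiotic_choice_class) ||
             !is.null(severity$chronic_level)) {
    "antibiotic"
  } else {
    "chemical"
  }

  ## route invariants -------------------------------------------------------
  if (route == "environment" && length(persistence) == 0L) {
    fail("environment route requires persistence evidence ",
         "(dt50, log_reduction/waiting_time, or persistence_level)")
  }
  if (route == "accumulation" && is.null(accumulation)) {
    fail("accumulation route requires a BAF or an assigned ",
         "accumulation level")
  }
  if (route == "environment" && is.null(transfer)) {
    fail("environment route requires transfer evidence ",
         "(log_koc or transfer_level)")
  }
  if (severity$kind == "microbial" && is.null(severity$daly_per_case) &&
      is.null(severity$assigned_level)) {
    fail("microbial hazard requires DALY/case severity evidence")
  }
  if (severity$kind == "chemical" && is.null(severity$hbgv_value) &&
      is.null(severity$endpoint_flags) && is.null(severity$assigned_level)) {
    fail("chemical hazard requires an HBGV, endpoint flags, or an ",
         "assigned severity level")
  }

  structure(list(hazard_id = id, hazard_class = hazard_class, route = route,
                 occurrence = occurrence, persistence = persistence,
                 transfer = transfer, accumulation = accumulation,
                 severity = severity),
            class = "hazard_profile")
}

#' @rdname load_hazard_registry
#' @param registry a `hazard_registry` (or list of `hazard_profile`).
#' @export
write_hazard_registry <- function(registry, path) {
  rows <- do.call(rbind, lapply(registry, profile_rows))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

profile_rows <- function(p) {
  row <- function(kind, compartment = "", value, units = "", basis = "") {
    data.frame(hazard_id = p$hazard_id, hazard_class = p$hazard_class,
               route = p$route, evidence_kind = kind,
               compartment = compartment, value = as.character(value),
               units = units, basis = basis, stringsAsFactors = FALSE)
  }
  out <- list()
  for (ev in p$occurrence) {
    out[[length(out) + 1L]] <- if (ev$kind == "occurrence_level") {
      row("occurrence_level", ev$matrix, level_chr(ev$level), ev$units)
    } else {
      row(ev$kind, ev$matrix, format(ev$value, scientific = FALSE,
                                     trim = TRUE), ev$units)
    }
  }
  pe <- p$persistence
  for (cmp in names(pe$dt50_days_by_compartment)) {
    out[[length(out) + 1L]] <-
      row("dt50", cmp, pe$dt50_days_by_compartment[[cmp]], "days")
  }
  if (!is.null(pe$log_reduction_days)) {
    out[[length(out) + 1L]] <- row("log_reduction", "",
                                   pe$log_reduction_days, "days/log")
  }
  if (!is.null(pe$waiting_time_days)) {
    out[[length(out) + 1L]] <- row("waiting_time", "",
                                   pe$waiting_time_days, "days")
  }
  if (!is.null(pe$assigned_level)) {
    out[[length(out) + 1L]] <- row("persistence_level", "",
                                   level_chr(pe$assigned_level))
  }
  if (!is.null(p$transfer)) {
    out[[length(out) + 1L]] <- if (p$transfer$kind == "log_koc") {
      row("log_koc", "", p$transfer$value)
    } else {
      row("transfer_level", "", level_chr(p$transfer$level))
    }
  }
  if (!is.null(p$accumulation)) {
    out[[length(out) + 1L]] <- if (p$accumulation$kind ==
                                   "bioaccumulation_factor") {
      row("baf", "", p$accumulation$value)
    } else {
      row("accumulation_level", "", level_chr(p$accumulation$level))
    }
  }
  sev <- p$severity
  if (!is.null(sev$hbgv_value)) {
    out[[length(out) + 1L]] <- row("hbgv", "", sev$hbgv_value, "ug/kg bw",
                                   sev$hbgv_basis)
  }
  if (!is.null(sev$endpoint_flags)) {
    out[[length(out) + 1L]] <- row("endpoint_flags", "",
                                   paste(sev$endpoint_flags, collapse = "|"))
  }
  if (!is.null(sev$antibiotic_choice_class)) {
    out[[length(out) + 1L]] <- row("antibiotic_choice_class", "",
                                   sev$antibiotic_choice_class)
  }
  if (!is.null(sev$chronic_level)) {
    out[[length(out) + 1L]] <- row("chronic_level", "",
                                   level_chr(sev$chronic_level))
  }
  if (!is.null(sev$daly_per_case)) {
    out[[length(out) + 1L]] <- row("daly", "", sev$daly_per_case,
                                   "DALY/case")
  }
  if (!is.null(sev$assigned_level)) {
    out[[length(out) + 1L]] <- row("severity_level", "",
                                   level_chr(sev$assigned_level))
  }
  do.call(rbind, out)
}

#' @export
print.hazard_profile <- function(x, ...) {
  cat(sprintf("<hazard_profile> %s (%s, %s route)\n", x$hazard_id,
              x$hazard_class, x$route))
  invisible(x)
}

#' @export
print.hazard_registry <- function(x, ...) {
  cat(sprintf("<hazard_registry> %d hazard(s): %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}
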