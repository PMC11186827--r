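#' Classify chemical persistence from a half-life (DT50)
#'
#' Persistence of a chemical in manure or soil is scored from its
#' half-life: LOW below 30 days, HIGH above 100 days, MEDIUM in
#' between (both bounds inclusive in MEDIUM).
#'
#' @param dt50_days half-life in days (> 0).
#' @param rules a [classification_ruleset()].
#' @return a [hazard_level()].
#' @examples
#' classify_dt50(1)    # sulphonamides in solid cattle manure
#' classify_dt50(564)  # (fluoro)quinolones in solid cattle manure
#' @export
classify_dt50 <- function(dt50_days, rules = default_ruleset()) {
  stopifnot(is.numeric(dt50_days), length(dt50_days) == 1L)
  if (is.na(dt50_days) || dt50_days <= 0) {
    stop("DT50 must be a positive number of days", call. = FALSE)
  }
  b <- rules$dt50_bounds
  if (dt50_days < b[["low_upper"]]) return(hazard_level("L"))
  if (dt50_days > b[["high_lower"]]) return(hazard_level("H"))
  hazard_level("M")
}

#' Collapse per-compartment persistence levels into one score
#'
#' A hazard passes through compartments sequentially (manure, then
#' manure-amended soil); survival of the most persistent compartment
#' governs, so the maximum level is taken.
#'
#' @param levels a non-empty hazard-level vector (or list of levels).
#' @return a single [hazard_level()].
#' @export
combine_compartment_persistence <- function(levels) {
  if (is.list(levels)) levels <- hazard_level(vapply(levels, level_chr, ""))
  if (length(levels) == 0L) {
    stop("at least one compartment persistence level is required",
         call. = FALSE)
  }
  stopifnot(is_hazard_level(levels))
  max(levels)
}

#' Classify microbial persistence from field die-off and waiting time
#'
#' The achieved log10 reduction between manure application and harvest
#' is `waiting_time_days / log_reduction_days`.  At least 4 achieved
#' logs scores LOW, below 2 logs scores HIGH, MEDIUM in between
#' (bounds inclusive in MEDIUM); bounds are configurable via
#' `rules$log_reduction_bounds`.
#'
#' @param log_reduction_days days needed for a 1-log reduction (> 0).
#' @param waiting_time_days days between application and harvest (>= 0).
#' @param rules a [classification_ruleset()].
#' @return a [hazard_level()].
#' @examples
#' classify_microbial_persistence(12.6, 60)  # E. coli, 60-day waiting time
#' @export
classify_microbial_persistence <- function(log_reduction_days,
                                           waiting_time_days,
                                           rules = default_ruleset()) {
  stopifnot(is.numeric(log_reduction_days), is.numeric(waiting_time_days))
  if (is.na(log_reduction_days) || log_reduction_days <= 0) {
    stop("log_reduction_days must be positive", call. = FALSE)
  }
  if (is.na(waiting_time_days) || waiting_time_days < 0) {
    stop("waiting_time_days must be non-negative", call. = FALSE)
  }
  logs <- waiting_time_days / log_reduction_days
  b <- rules$log_reduction_bounds
  if (logs >= b[["low_lower"]]) return(hazard_level("L"))
  if (logs < b[["high_upper"]]) return(hazard_level("H"))
  hazard_level("M")
}

#' Classify transfer to plants from the log K_OC
#'
#' Water-soluble compounds (small K_OC) are mobile in the soil pore
#' water and readily taken up by plants: log10 K_OC below 1 scores
#' HIGH transfer, at or above 2 scores LOW, MEDIUM in between.
#'
#' @param log_koc log10 of the organic carbon-water partition
#'   coefficient.
#' @param rules a [classification_ruleset()].
#' @return a [hazard_level()].
#' @examples
#' classify_transfer_log_koc(0.5)  # sulphonamides: readily taken up
#' classify_transfer_log_koc(2.9)  # (fluoro)quinolones: bound to soil
#' @export
classify_transfer_log_koc <- function(log_koc, rules = default_ruleset()) {
  stopifnot(is.numeric(log_koc), length(log_koc) == 1L, !is.na(log_koc))
  b <- rules$koc_bounds
  if (log_koc < b[["high_upper_log"]]) return(hazard_level("H"))
  if (log_koc >= b[["low_lower_log"]]) return(hazard_level("L"))
  hazard_level("M")
}

#' Classify accumulation from a bio-accumulation factor
#'
#' BAF at or below 1 means no net accumulation in the reared animal
#' (LOW); above 5 scores HIGH; MEDIUM in between.
#'
#' @param baf bio-accumulation factor (>= 0), concentration in the
#'   animal divided by concentration in its substrate.
#' @param rules a [classification_ruleset()].
#' @return a [hazard_level()].
#' @examples
#' classify_accumulation_baf(20)   # cadmium in black soldier fly larvae
#' classify_accumulation_baf(2.3)  # lead
#' @export
classify_accumulation_baf <- function(baf, rules = default_ruleset()) {
  stopifnot(is.numeric(baf), length(baf) == 1L)
  if (is.na(baf) || baf < 0) {
    stop("BAF must be non-negative", call. = FALSE)
  }
  b <- rules$baf_bounds
  if (baf <= b[["low_upper"]]) return(hazard_level("L"))
  if (baf > b[["high_lower"]]) return(hazard_level("H"))
  hazard_level("M")
}

#' Classify occurrence from raw-material concentrations
#'
#' Concentrations measured in several raw-material matrices (e.g.
#' cattle, poultry and swine manure) are first collapsed to one value
#' per `rules$occurrence_collapse` — the group mean (default, as in
#' the published case tables) or the maximum (worst case) — and then
#' classified against `chem_conc_bounds` (ng/g dm) or
#' `micro_conc_bounds` (cfu/g dm).
#'
#' @param values numeric vector of concentrations, or a list of
#'   occurrence evidence items as stored in a hazard profile.
#' @param hazard_class `"chemical"` or `"microbial"`.
#' @param rules a [classification_ruleset()].
#' @return a [hazard_level()].
#' @examples
#' classify_occurrence_concentration(c(40805, 30166, 89639), "chemical")
#' classify_occurrence_concentration(c(1.3e8, 2.2e7, 4.7e4), "microbial")
#' @export
classify_occurrence_concentration <- function(values, hazard_class,
                                              rules = default_ruleset()) {
  if (is.list(values)) {
    units <- unique(vapply(values, function(ev) ev$units, ""))
    if (length(units) > 1L) {
      stop("mixed occurrence units: ", paste(units, collapse = ", "),
           call. = FALSE)
    }
    values <- vapply(values, function(ev) ev$value, numeric(1))
  }
  stopifnot(is.numeric(values))
  if (length(values) == 0L || anyNA(values) || any(values < 0)) {
    stop("need at least one non-negative concentration", call. = FALSE)
  }
  hazard_class <- match.arg(hazard_class, c("chemical", "microbial"))
  x <- switch(rules$occurrence_collapse, mean = mean(values),
              max = max(values))
  b <- if (hazard_class == "chemical") rules$chem_conc_bounds else
    rules$micro_conc_bounds
  if (x < b[["low_upper"]]) return(hazard_level("L"))
  if (x >= b[["high_lower"]]) return(hazard_level("H"))
  hazard_level("M")
}

#' Classify occurrence from a limit-exceedance fraction
#'
#' On the exceedance pathway occurrence is binary: HIGH when the
#' fraction of batches above the regulatory limit strictly exceeds the
#' threshold (default 3%), LOW otherwise.  MEDIUM is not used on this
#' pathway.
#'
#' @param frac_exceeding fraction in `[0, 1]`.
#' @param rules a [classification_ruleset()].
#' @return a [hazard_level()].
#' @examples
#' classify_occurrence_exceedance(0.062)  # DON, short-chain scenario
#' classify_occurrence_exceedance(0)      # T-2/HT-2
#' @export
classify_occurrence_exceedance <- function(frac_exceeding,
                                           rules = default_ruleset()) {
  stopifnot(is.numeric(frac_exceeding), length(frac_exceeding) == 1L)
  if (is.na(frac_exceeding) || frac_exceeding < 0 || frac_exceeding > 1) {
    stop("exceedance fraction must be in [0, 1]", call. = FALSE)
  }
  if (frac_exceeding > rules$exceedance_threshold) {
    hazard_level("H")
  } else {
    hazard_level("L")
  }
}

#' Normalise a health-based guidance value to the daily scale
#'
#' Weekly guidance values (TWI) are divided by 7 so all guidance
#' values (ADI, TDI, BMDL10, TWI) can be compared against one daily
#' cutoff.
#'
#' @param value guidance value in ug/kg bw (>= 0).
#' @param basis `"per_day"` or `"per_week"`.
#' @return the value in ug/kg bw/day.
#' @examples
#' normalize_hbgv_to_daily(2.5, "per_week")  # cadmium TWI
#' @export
normalize_hbgv_to_daily <- function(value, basis) {
  stopifnot(is.numeric(value), length(value) == 1L)
  if (is.na(value) || value < 0) {
    stop("guidance value must be non-negative", call. = FALSE)
  }
  basis <- match.arg(basis, c("per_day", "per_week"))
  if (basis == "per_week") value / 7 else value
}

#' Classify chemical severity
#'
#' A chemical scores HIGH severity when it is classified in any of the
#' four toxicity endpoints (carcinogenic, mutagenic, reprotoxic,
#' repeated-dose) or when its daily-normalised health-based guidance
#' value is at or below the cutoff (default 10 ug/kg bw/day); LOW
#' otherwise.  BMDL10 values are treated on the daily scale like
#' ADI/TDI.
#'
#' @param hbgv_value guidance value in ug/kg bw, or `NULL`.
#' @param hbgv_basis `"per_day"` or `"per_week"`.
#' @param endpoint_flags character vector of endpoint flags (may be
#'   empty).
#' @param rules a [classification_ruleset()].
#' @return a [hazard_level()] (LOW or HIGH).
#' @examples
#' classify_severity_chemical(0.4)                    # aflatoxin B1 BMDL10
#' classify_severity_chemical(15)                     # typical pesticide ADI
#' classify_severity_chemical(2.5, "per_week")        # cadmium TWI
#' @export
classify_severity_chemical <- function(hbgv_value = NULL,
                                       hbgv_basis = "per_day",
                                       endpoint_flags = character(),
                                       rules = default_ruleset()) {
  if (length(endpoint_flags)) {
    bad <- setdiff(endpoint_flags, ENDPOINT_FLAGS)
    if (length(bad)) {
      stop("unknown endpoint flag(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    return(hazard_level("H"))
  }
  if (is.null(hbgv_value)) {
    stop("chemical severity needs an HBGV or at least one endpoint flag",
         call. = FALSE)
  }
  daily <- normalize_hbgv_to_daily(hbgv_value, hbgv_basis)
  if (daily <= rules$hbgv_daily_cutoff) hazard_level("H") else hazard_level("L")
}

#' Classify antibiotic severity from chronic toxicity and resistance
#'
#' Antibiotics are scored on two binary components: chronic toxicity
#' to humans and the antimicrobial-resistance concern (second/third
#' choice antibiotics score HIGH).  Both HIGH gives HIGH severity,
#' exactly one HIGH gives MEDIUM, both LOW gives LOW.  MEDIUM inputs
#' are rejected: the combination rule is defined for binary components
#' only.
#'
#' @param chronic chronic-toxicity level (LOW or HIGH).
#' @param resistance resistance-concern level (LOW or HIGH).
#' @return a [hazard_level()].
#' @examples
#' classify_severity_antibiotic(hazard_level("H"), hazard_level("H"))
#' @export
classify_severity_antibiotic <- function(chronic, resistance) {
  chronic <- hazard_level(chronic)
  resistance <- hazard_level(resistance)
  if (chronic == "M" || resistance == "M") {
    stop("antibiotic severity components must be LOW or HIGH ",
         "(the combination rule is binary)", call. = FALSE)
  }
  n_high <- sum(c(chronic, resistance) == "H")
  hazard_level(c("L", "M", "H")[n_high + 1L])
}

#' Classify microbial severity from the disease burden per case
#'
#' DALY/case below 0.01 scores LOW, above 0.1 scores HIGH, MEDIUM in
#' between (bounds inclusive in MEDIUM).
#'
#' @param daly_per_case disability-adjusted life years per case (>= 0).
#' @param rules a [classification_ruleset()].
#' @return a [hazard_level()].
#' @examples
#' classify_severity_microbial(0.039)  # Salmonella spp.
#' classify_severity_microbial(3.173)  # Toxoplasma gondii
#' @export
classify_severity_microbial <- function(daly_per_case,
                                        rules = default_ruleset()) {
  stopifnot(is.numeric(daly_per_case), length(daly_per_case) == 1L)
  if (is.na(daly_per_case) || daly_per_case < 0) {
    stop("DALY/case must be non-negative", call. = FALSE)
  }
  b <- rules$daly_bounds
  if (daly_per_case < b[["low_upper"]]) return(hazard_level("L"))
  if (daly_per_case > b[["high_lower"]]) return(hazard_level("H"))
  hazard_level("M")
}
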