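#' Prioritise a single hazard end-to-end
#'
#' Runs every applicable classifier on a hazard profile, combines the
#' indicator levels through the route-appropriate presence matrix, and
#' applies the priority matrix to (presence, severity).  Every level
#' carries provenance: the rule and input value that produced it.
#'
#' Occurrence evidence is resolved in order of specificity: an
#' exceedance fraction wins over concentrations, which win over
#' directly assigned levels (multiple assigned levels collapse to the
#' maximum).  An assigned persistence or severity level always
#' overrides derived values, which is how expert verdicts that
#' deliberately deviate from the strict numeric rule are encoded in
#' the case fixtures.
#'
#' @param profile a `hazard_profile` (see [load_hazard_registry()]).
#' @param rules a [classification_ruleset()].
#' @param matrices a matrix set (see [default_matrices()]).
#' @param occurrence_matrix optional raw-material matrix label; when
#'   given, only occurrence evidence measured in that matrix is used
#'   (one substrate scenario at a time).
#' @return a `priority_record`: list with `hazard_id`, `route`,
#'   `levels` (occurrence, persistence, transfer_accumulation,
#'   severity), `presence`, `severity`, `priority` and a `provenance`
#'   character vector.
#' @examples
#' reg <- load_hazard_registry(
#'   system.file("extdata", "case1_registry.csv", package = "hazrank"))
#' prioritize_hazard(reg[["(fluoro)quinolones"]])$priority
#' @export
prioritize_hazard <- function(profile, rules = default_ruleset(),
                              matrices = default_matrices(),
                              occurrence_matrix = NULL) {
  stopifnot(inherits(profile, "hazard_profile"))
  id <- profile$hazard_id
  with_ctx <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop("hazard ", sQuote(id), ": ", conditionMessage(e), call. = FALSE)
    })
  }
  prov <- character()

  ## occurrence -------------------------------------------------------------
  occ_ev <- profile$occurrence
  if (!is.null(occurrence_matrix)) {
    occ_ev <- Filter(function(ev) ev$matrix == occurrence_matrix, occ_ev)
    if (length(occ_ev) == 0L) {
      stop("hazard ", sQuote(id), ": no occurrence evidence for matrix ",
           sQuote(occurrence_matrix), call. = FALSE)
    }
  }
  kinds <- vapply(occ_ev, function(ev) ev$kind, "")
  occurrence <- with_ctx(
    if (any(kinds == "occurrence_exceedance")) {
      frac <- max(vapply(occ_ev[kinds == "occurrence_exceedance"],
                         function(ev) ev$value, numeric(1)))
      prov["occurrence"] <- sprintf(
        "exceedance fraction %.4g vs threshold %.4g", frac,
        rules$exceedance_threshold)
      classify_occurrence_exceedance(frac, rules)
    } else if (any(kinds == "occurrence_concentration")) {
      conc <- occ_ev[kinds == "occurrence_concentration"]
      vals <- vapply(conc, function(ev) ev$value, numeric(1))
      prov["occurrence"] <- sprintf(
        "%s of %d concentration(s) = %.4g %s",
        rules$occurrence_collapse, length(vals),
        switch(rules$occurrence_collapse, mean = mean(vals),
               max = max(vals)),
        conc[[1L]]$units)
      classify_occurrence_concentration(conc, profile$hazard_class, rules)
    } else {
      levels <- hazard_level(vapply(occ_ev, function(ev) level_chr(ev$level),
                                    ""))
      prov["occurrence"] <- sprintf("assigned level(s): %s",
                                     paste(levels, collapse = ","))
      max(levels)
    })

  ## severity ---------------------------------------------------------------
  sev <- profile$severity
  severity <- with_ctx(
    if (!is.null(sev$assigned_level)) {
      prov["severity"] <- "assigned level (override)"
      sev$assigned_level
    } else if (sev$kind == "microbial") {
      prov["severity"] <- sprintf("%.4g DALY/case", sev$daly_per_case)
      classify_severity_microbial(sev$daly_per_case, rules)
    } else if (sev$kind == "antibiotic") {
      chronic <- if (!is.null(sev$chronic_level)) sev$chronic_level else
        classify_severity_chemical(sev$hbgv_value,
                                   sev$hbgv_basis %||% "per_day",
                                   sev$endpoint_flags %||% character(),
                                   rules)
      if (is.null(sev$antibiotic_choice_class)) {
        stop("antibiotic severity needs an antibiotic_choice_class")
      }
      resistance <- if (sev$antibiotic_choice_class >= 2L)
        hazard_level("H") else hazard_level("L")
      prov["severity"] <- sprintf(
        "antibiotic rule: chronic %s x resistance %s (choice class %d)",
        chronic, resistance, sev$antibiotic_choice_class)
      classify_severity_antibiotic(chronic, resistance)
    } else {
      prov["severity"] <- if (length(sev$endpoint_flags %||% character())) {
        sprintf("endpoint flag(s): %s",
                paste(sev$endpoint_flags, collapse = ","))
      } else {
        sprintf("HBGV %.4g ug/kg bw %s vs daily cutoff %.4g",
                sev$hbgv_value, sev$hbgv_basis, rules$hbgv_daily_cutoff)
      }
      classify_severity_chemical(sev$hbgv_value %||% NULL,
                                 sev$hbgv_basis %||% "per_day",
                                 sev$endpoint_flags %||% character(),
                                 rules)
    })

  ## route-specific indicators and presence ---------------------------------
  if (profile$route == "environment") {
    pe <- profile$persistence
    persistence <- with_ctx(
      if (!is.null(pe$assigned_level)) {
        prov["persistence"] <- "assigned level (override)"
        pe$assigned_level
      } else {
        levels <- list()
        for (cmp in names(pe$dt50_days_by_compartment)) {
          lev <- classify_dt50(pe$dt50_days_by_compartment[[cmp]], rules)
          levels[[cmp]] <- lev
        }
        if (!is.null(pe$log_reduction_days)) {
          if (is.null(pe$waiting_time_days)) {
            stop("log_reduction evidence needs a waiting_time")
          }
          levels[["field die-off"]] <- classify_microbial_persistence(
            pe$log_reduction_days, pe$waiting_time_days, rules)
        }
        if (length(levels) == 0L) stop("no usable persistence evidence")
        prov["persistence"] <- paste(
          sprintf("%s=%s", names(levels),
                  vapply(levels, level_chr, "")), collapse = ", ")
        combine_compartment_persistence(levels)
      })
    transfer <- with_ctx(
      if (profile$transfer$kind == "log_koc") {
        prov["transfer"] <- sprintf("log K_OC %.4g", profile$transfer$value)
        classify_transfer_log_koc(profile$transfer$value, rules)
      } else {
        prov["transfer"] <- "assigned level"
        profile$transfer$level
      })
    presence <- presence_environment(occurrence, persistence, transfer,
                                     matrices)
    levels <- list(occurrence = occurrence, persistence = persistence,
                   transfer_accumulation = transfer, severity = severity)
  } else {
    accumulation <- with_ctx(
      if (profile$accumulation$kind == "bioaccumulation_factor") {
        prov["accumulation"] <- sprintf("BAF %.4g",
                                         profile$accumulation$value)
        classify_accumulation_baf(profile$accumulation$value, rules)
      } else {
        prov["accumulation"] <- "assigned level"
        profile$accumulation$level
      })
    presence <- presence_accumulation(occurrence, accumulation, matrices)
    levels <- list(occurrence = occurrence, persistence = NULL,
                   transfer_accumulation = accumulation,
                   severity = severity)
  }

  priority <- prioritize(presence, severity, matrices)
  prov["presence"] <- sprintf("%s matrix", profile$route)
  prov["priority"] <- sprintf("priority matrix on (%s, %s)", presence,
                              severity)
  structure(list(hazard_id = id, route = profile$route, levels = levels,
                 presence = presence, severity = severity,
                 priority = priority, provenance = prov),
            class = "priority_record")
}

#' @export
print.priority_record <- function(x, ...) {
  cat(sprintf("<priority_record> %s: presence %s, severity %s -> priority %s\n",
              x$hazard_id, x$presence, x$severity, x$priority))
  invisible(x)
}

#' Prioritise every hazard in a registry
#'
#' @param registry a `hazard_registry`.
#' @inheritParams prioritize_hazard
#' @return a data frame with one row per hazard (registry order):
#'   `hazard_id, route, occurrence, persistence, transfer_accumulation,
#'   severity, presence, priority, provenance`.
#' @export
prioritize_registry <- function(registry, rules = default_ruleset(),
                                matrices = default_matrices(),
                                occurrence_matrix = NULL) {
  records <- lapply(registry, prioritize_hazard, rules = rules,
                    matrices = matrices,
                    occurrence_matrix = occurrence_matrix)
  lv <- function(x) if (is.null(x)) NA_character_ else level_chr(x)
  out <- do.call(rbind, lapply(records, function(r) {
    data.frame(hazard_id = r$hazard_id, route = r$route,
               occurrence = lv(r$levels$occurrence),
               persistence = lv(r$levels$persistence),
               transfer_accumulation = lv(r$levels$transfer_accumulation),
               severity = lv(r$severity),
               presence = lv(r$presence),
               priority = lv(r$priority),
               provenance = paste(names(r$provenance), r$provenance,
                                  sep = ": ", collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-level sensitivity of the priority score
#'
#' Uncertainty in the ordinal framework is read off as the change in
#' the final priority when a single underlying indicator shifts by one
#' level (clamped at L and H), all others held fixed.  Severity is
#' perturbed alongside the presence indicators.
#'
#' @inheritParams prioritize_hazard
#' @return a data frame with columns `indicator`, `direction`,
#'   `perturbed_level`, `presence`, `priority`, `baseline_priority`,
#'   `changed`.  Perturbations clamped into the original level (e.g.
#'   `-1` from LOW) are omitted.
#' @export
sensitivity_one_level <- function(profile, rules = default_ruleset(),
                                  matrices = default_matrices(),
                                  occurrence_matrix = NULL) {
  base <- prioritize_hazard(profile, rules, matrices, occurrence_matrix)
  indicators <- names(base$levels)[!vapply(base$levels, is.null, NA)]
  rows <- list()
  for (ind in indicators) {
    for (dir in c(-1L, 1L)) {
      levels <- base$levels
      shifted <- level_shift(levels[[ind]], dir)
      if (shifted == levels[[ind]]) next  # clamped: no effective change
      levels[[ind]] <- shifted
      presence <- if (base$route == "environment") {
        presence_environment(levels$occurrence, levels$persistence,
                             levels$transfer_accumulation, matrices)
      } else {
        presence_accumulation(levels$occurrence,
                              levels$transfer_accumulation, matrices)
      }
      priority <- prioritize(presence, levels$severity, matrices)
      rows[[length(rows) + 1L]] <- data.frame(
        indicator = ind, direction = dir,
        perturbed_level = level_chr(shifted),
        presence = level_chr(presence),
        priority = level_chr(priority),
        baseline_priority = level_chr(base$priority),
        changed = priority != base$priority,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
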