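#' Empirical concentration pool
#'
#' A pool holds one concentration per field (or batch) for one analyte,
#' together with the regulatory limit the scenario summaries are
#' computed against.
#'
#' @param values non-negative concentrations in ug/kg, one per field.
#' @param analyte analyte label (e.g. `"DON"`).
#' @param limit positive limit in ug/kg (EC maximum limit or guidance
#'   level).
#' @param limit_kind `"maximum_limit"` or `"guidance"`.
#' @return a `concentration_pool`.
#' @examples
#' concentration_pool(c(10, 20, 3000), "DON", limit = 1250)
#' @export
concentration_pool <- function(values, analyte, limit,
                               limit_kind = c("maximum_limit", "guidance")) {
  stopifnot(is.numeric(values), is.numeric(limit), length(limit) == 1L)
  if (length(values) == 0L) {
    stop("a concentration pool must be non-empty", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("pool concentrations must be non-negative", call. = FALSE)
  }
  if (is.na(limit) || limit <= 0) {
    stop("the limit must be positive", call. = FALSE)
  }
  structure(list(values = as.numeric(values), analyte = as.character(analyte),
                 limit = as.numeric(limit),
                 limit_kind = match.arg(limit_kind)),
            class = "concentration_pool")
}

#' @export
print.concentration_pool <- function(x, ...) {
  cat(sprintf(
    "<concentration_pool> %s: %d fields, median %.3g, mean %.3g, max %.3g ug/kg (limit %.3g)\n",
    x$analyte, length(x$values), stats::median(x$values), mean(x$values),
    max(x$values), x$limit))
  invisible(x)
}

#' Read / write a pool CSV
#'
#' Single-column CSV of concentrations with a two-line comment-free
#' header: columns `analyte, units, limit, limit_kind, value` (the
#' first four repeat per row; only the first row is consulted).
#'
#' @param path CSV path.
#' @return a `concentration_pool` / `path` invisibly.
#' @export
read_pool_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("analyte", "units", "limit", "limit_kind", "value")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("pool CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  concentration_pool(df$value, df$analyte[[1L]], df$limit[[1L]],
                     df$limit_kind[[1L]])
}

#' @rdname read_pool_csv
#' @param pool a `concentration_pool`.
#' @export
write_pool_csv <- function(pool, path) {
  df <- data.frame(analyte = pool$analyte, units = "ug/kg",
                   limit = pool$limit, limit_kind = pool$limit_kind,
                   value = pool$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

scenario_summary <- function(scenario, batch_values, pool, reps,
                             n_fields_range, seed) {
  structure(list(
    scenario = scenario, analyte = pool$analyte, reps = reps,
    n_fields_range = n_fields_range,
    min = min(batch_values), median = stats::median(batch_values),
    mean = mean(batch_values), max = max(batch_values),
    frac_exceeding = mean(batch_values > pool$limit),
    limit = pool$limit, seed = seed
  ), class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf(
    "<scenario_summary> %s %s: min %.3g, median %.3g, mean %.3g, max %.3g, %.2f%% > %.3g ug/kg (%d reps)\n",
    x$analyte, x$scenario, x$min, x$median, x$mean, x$max,
    100 * x$frac_exceeding, x$limit, x$reps))
  invisible(x)
}

#' Simulate the short-chain (single-field) scenario
#'
#' Each simulated batch of the short supply chain comes from one field:
#' one concentration is drawn (uniformly, with replacement) from the
#' pool per repetition.
#'
#' @param pool a [concentration_pool()].
#' @param reps number of simulated batches (>= 1; the published
#'   analysis uses 100,000).
#' @param seed integer seed; identical inputs give bit-identical
#'   summaries.
#' @return a `scenario_summary` with the batch min / median / mean /
#'   max and the fraction of batches above the pool limit.
#' @export
simulate_short_chain <- function(pool, reps = 1e5, seed) {
  stopifnot(inherits(pool, "concentration_pool"))
  if (!is.numeric(reps) || length(reps) != 1L || is.na(reps) || reps < 1) {
    stop("reps must be a positive integer", call. = FALSE)
  }
  reps <- as.integer(reps)
  batches <- withr::with_seed(seed, {
    pool$values[sample.int(length(pool$values), reps, replace = TRUE)]
  })
  scenario_summary("short_chain", batches, pool, reps, c(1L, 1L), seed)
}

#' Simulate the conventional (mixed-field) scenario
#'
#' Each simulated batch blends several fields: per repetition a batch
#' size `n` is drawn uniformly from `n_min:n_max` (inclusive), then `n`
#' concentrations are drawn with replacement from the pool and
#' averaged.  Mixing dilutes incidental local contamination, so batch
#' extremes shrink towards the pool mean while the mean is unchanged.
#'
#' @inheritParams simulate_short_chain
#' @param n_min,n_max inclusive bounds of the number of fields blended
#'   per batch (published scenario: 5 to 10).
#' @return a `scenario_summary`.
#' @export
simulate_mixed_chain <- function(pool, n_min = 5L, n_max = 10L, reps = 1e5,
                                 seed) {
  stopifnot(inherits(pool, "concentration_pool"))
  if (!is.numeric(reps) || length(reps) != 1L || is.na(reps) || reps < 1) {
    stop("reps must be a positive integer", call. = FALSE)
  }
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (is.na(n_min) || is.na(n_max) || n_min < 1L || n_min > n_max) {
    stop("invalid field range: need 1 <= n_min <= n_max", call. = FALSE)
  }
  reps <- as.integer(reps)
  batches <- withr::with_seed(seed, {
    ns <- if (n_min == n_max) rep.int(n_min, reps) else
      sample.int(n_max - n_min + 1L, reps, replace = TRUE) + n_min - 1L
    draws <- pool$values[sample.int(length(pool$values), sum(ns),
                                    replace = TRUE)]
    group <- rep.int(seq_len(reps), ns)
    as.numeric(rowsum(draws, group)) / ns
  })
  scenario_summary("conventional", batches, pool, reps, c(n_min, n_max),
                   seed)
}

#' Apply a milling processing factor
#'
#' Milling kernels into flour lowers (but does not remove) mycotoxin
#' concentrations; the transfer is summarised by a processing factor in
#' `(0, 1]` applied multiplicatively to all concentrations.  Limits are
#' left unchanged.
#'
#' @param x a `concentration_pool` or `scenario_summary`.
#' @param factor processing factor in `(0, 1]` (white flour: about
#'   0.5-0.8 for DON, 0.1-0.9 for ZEA, 0.2-0.4 for T-2/HT-2).
#' @return an object of the same class with scaled concentrations.
#' @export
apply_processing_factor <- function(x, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L)
  if (is.na(factor) || factor <= 0 || factor > 1) {
    stop("processing factor must be in (0, 1]", call. = FALSE)
  }
  if (inherits(x, "concentration_pool")) {
    x$values <- x$values * factor
  } else if (inherits(x, "scenario_summary")) {
    for (f in c("min", "median", "mean", "max")) x[[f]] <- x[[f]] * factor
  } else {
    stop("expected a concentration_pool or scenario_summary", call. = FALSE)
  }
  x
}

#' Compare the short-chain and conventional scenarios
#'
#' Runs both simulations on the same pool (with seeds derived from
#' `seed` so the scenarios are independent but jointly reproducible),
#' classifies each scenario's exceedance fraction into an occurrence
#' level, and returns the paired summaries.
#'
#' @inheritParams simulate_mixed_chain
#' @param rules a [classification_ruleset()] for the exceedance
#'   occurrence rule.
#' @return a `scenario_comparison`: list with `short_chain` and
#'   `conventional` summaries, their occurrence levels, and a
#'   `report` data frame shaped like the published scenario table
#'   (percentages on the 0-100 scale).
#' @export
compare_scenarios <- function(pool, reps = 1e5, n_min = 5L, n_max = 10L,
                              seed, rules = default_ruleset()) {
  short <- simulate_short_chain(pool, reps, seed = seed)
  conventional <- simulate_mixed_chain(pool, n_min, n_max, reps,
                                       seed = seed + 1L)
  occ <- lapply(list(short = short, conventional = conventional),
                function(s) classify_occurrence_exceedance(s$frac_exceeding,
                                                           rules))
  report <- do.call(rbind, lapply(list(short, conventional), function(s) {
    data.frame(analyte = s$analyte, scenario = s$scenario,
               min = s$min, median = s$median, mean = s$mean, max = s$max,
               pct_exceeding = 100 * s$frac_exceeding,
               occurrence = level_chr(if (s$scenario == "short_chain")
                 occ$short else occ$conventional),
               stringsAsFactors = FALSE)
  }))
  structure(list(short_chain = short, conventional = conventional,
                 occurrence = occ, report = report, seed = seed),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  print(x$report, row.names = FALSE)
  invisible(x)
}
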