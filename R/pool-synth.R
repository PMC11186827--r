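#' Summary targets for a synthetic concentration pool
#'
#' Field-level survey data are often published only as summary
#' statistics.  A target set records the published median, mean,
#' maximum, fraction of fields above the regulatory limit, the
#' left-censoring floor (limit of quantification), and the number of
#' fields, so that a synthetic pool with matching summaries can stand
#' in for the unpublished raw data.
#'
#' @param analyte analyte label.
#' @param median,mean,max target summaries in ug/kg.
#' @param frac_above_limit target fraction of fields above `limit`.
#' @param limit regulatory limit in ug/kg.
#' @param floor censoring floor in ug/kg (values below are reported at
#'   the floor).
#' @param size number of fields (default 293, the size of the wheat
#'   survey the shipped targets summarise).
#' @param limit_kind `"maximum_limit"` or `"guidance"`.
#' @return a `pool_summary_targets`.
#' @examples
#' pool_summary_targets("DON", median = 60, mean = 411, max = 15400,
#'                      frac_above_limit = 0.061, limit = 1250, floor = 25)
#' @export
pool_summary_targets <- function(analyte, median, mean, max,
                                 frac_above_limit, limit, floor,
                                 size = 293L,
                                 limit_kind = c("maximum_limit",
                                                "guidance")) {
  t <- list(analyte = as.character(analyte), median = as.numeric(median),
            mean = as.numeric(mean), max = as.numeric(max),
            frac_above_limit = as.numeric(frac_above_limit),
            limit = as.numeric(limit), floor = as.numeric(floor),
            size = as.integer(size), limit_kind = match.arg(limit_kind))
  check_targets(t)
  structure(t, class = "pool_summary_targets")
}

# soundness: order constraints that any real pool must satisfy
check_targets <- function(t) {
  fail <- function(...) stop("infeasible pool targets (", t$analyte, "): ",
                             ..., call. = FALSE)
  if (anyNA(unlist(t[c("median", "mean", "max", "frac_above_limit",
                       "limit", "floor", "size")]))) {
    fail("missing values")
  }
  if (t$frac_above_limit < 0 || t$frac_above_limit > 1) {
    fail("frac_above_limit must be in [0, 1]")
  }
  if (t$floor < 0 || t$limit <= 0) fail("floor/limit out of range")
  if (t$median < t$floor) fail("median below the censoring floor")
  if (t$median > t$max) fail("median above the maximum")
  if (t$mean > t$max || t$mean < t$floor) {
    fail("mean outside [floor, max]")
  }
  if (t$frac_above_limit > 0 && t$max <= t$limit) {
    fail("frac_above_limit > 0 but max does not exceed the limit")
  }
  if (t$size < 2L) fail("size must be at least 2")
  invisible(t)
}

#' Default synthesis tolerances
#'
#' Relative tolerance 5% on the median and the mean, absolute
#' tolerance 0.5 percentage points on the exceedance fraction, and an
#' exact match on the maximum (imposed by construction).
#'
#' @return a named list of tolerances.
#' @export
default_pool_tolerances <- function() {
  list(median = 0.05, mean = 0.05, frac_above_limit = 0.005, max = 0)
}

# deterministic pool construction for one parameter vector.
# p: censored fraction; mu, sigma: log-normal body parameters.
# jitter: fixed uniforms (length >= size) making the stratified body
# quantiles seed-dependent but smooth in the parameters.
build_pool_values <- function(p, mu, sigma, targets, jitter) {
  n <- targets$size
  n_floor <- max(0L, min(n - 1L, as.integer(round(p * n))))
  n_body <- n - n_floor
  u <- (seq_len(n_body) - jitter[seq_len(n_body)]) / n_body
  body <- stats::qlnorm(u, meanlog = mu, sdlog = sigma)
  values <- c(rep.int(targets$floor, n_floor), body)
  values <- pmin(pmax(values, targets$floor), targets$max)
  values[which.max(values)] <- targets$max  # sample maximum is known exactly
  values
}

#' Synthesise a concentration pool from summary targets
#'
#' The model family is a point mass at the censoring floor (the
#' left-censored fraction of fields) plus a log-normal body, the
#' standard shape for right-skewed, LOQ-censored mycotoxin field data.
#' The three free parameters (censored fraction, log-mean, log-sd) are
#' calibrated by derivative-free search (Nelder-Mead, multi-start) so
#' that the realised pool matches the target median and mean within 5%
#' and the exceedance fraction within 0.5 percentage points; the
#' single largest value is then set to the target maximum exactly, and
#' all values are clipped into `[floor, max]`.
#'
#' @param targets a [pool_summary_targets()].
#' @param seed integer seed (the body quantiles are stratified with
#'   seeded jitter, so distinct seeds give distinct pools with
#'   near-identical summaries).
#' @param tolerances named list as [default_pool_tolerances()].
#' @return a [concentration_pool()] of `targets$size` values.
#' @examples
#' don <- pool_summary_targets("DON", 60, 411, 15400, 0.061, 1250, 25)
#' pool <- synthesize_pool(don, seed = 1)
#' validate_pool(pool, don)
#' @export
synthesize_pool <- function(targets, seed,
                            tolerances = default_pool_tolerances()) {
  stopifnot(inherits(targets, "pool_summary_targets"))
  check_targets(targets)
  jitter <- withr::with_seed(seed, stats::runif(targets$size))

  loss <- function(par) {
    p <- stats::plogis(par[[1L]])
    sigma <- exp(par[[3L]])
    v <- build_pool_values(p, par[[2L]], sigma, targets, jitter)
    rel_med <- if (targets$median > 0) {
      stats::median(v) / targets$median - 1
    } else {
      stats::median(v)
    }
    rel_mean <- mean(v) / targets$mean - 1
    d_frac <- mean(v > targets$limit) - targets$frac_above_limit
    (rel_med / 0.01)^2 + (rel_mean / 0.01)^2 + (d_frac / 0.001)^2
  }

  ## moment-based starting points
  starts <- list()
  p0s <- if (targets$median > targets$floor) c(0.2, 0.4, 0.05) else
    c(0.55, 0.7, 0.85)
  for (p0 in p0s) {
    mu0 <- log(base::max(targets$median, targets$floor * 1.2))
    body_mean <- base::max((targets$mean - p0 * targets$floor) / (1 - p0),
                           targets$floor * 1.1)
    s0 <- sqrt(base::max(0.25, 2 * log(body_mean / exp(mu0))))
    starts[[length(starts) + 1L]] <- c(stats::qlogis(p0), mu0, log(s0))
  }

  best <- NULL
  for (start in starts) {
    fit <- stats::optim(start, loss, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    for (i in 1:3) {  # polish: restart from the incumbent
      fit2 <- stats::optim(fit$par, loss, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-10))
      if (fit2$value >= fit$value - 1e-12) { fit <- fit2; break }
      fit <- fit2
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  values <- build_pool_values(stats::plogis(best$par[[1L]]),
                              best$par[[2L]], exp(best$par[[3L]]),
                              targets, jitter)
  pool <- concentration_pool(values, targets$analyte, targets$limit,
                             targets$limit_kind)
  report <- validate_pool(pool, targets, tolerances)
  if (!all(report$pass)) {
    stop("pool synthesis did not reach the requested tolerances for ",
         targets$analyte, ": ",
         paste(report$statistic[!report$pass], collapse = ", "),
         call. = FALSE)
  }
  pool
}

#' Validate a pool against summary targets
#'
#' @param pool a [concentration_pool()].
#' @param targets a [pool_summary_targets()].
#' @param tolerances named list; `median` and `mean` are relative
#'   tolerances, `frac_above_limit` is absolute, `max` is relative
#'   (0 = exact).  Statistics absent from the list are not checked
#'   (an empty list passes vacuously).
#' @return a data frame with columns `statistic`, `target`,
#'   `realised`, `tolerance`, `pass`.
#' @export
validate_pool <- function(pool, targets,
                          tolerances = default_pool_tolerances()) {
  stopifnot(inherits(pool, "concentration_pool"),
            inherits(targets, "pool_summary_targets"))
  realised <- list(median = stats::median(pool$values),
                   mean = mean(pool$values),
                   max = base::max(pool$values),
                   frac_above_limit = mean(pool$values > targets$limit))
  rows <- lapply(names(tolerances), function(stat) {
    if (!stat %in% names(realised)) {
      stop("unknown statistic in tolerances: ", stat, call. = FALSE)
    }
    tol <- tolerances[[stat]]
    tgt <- targets[[stat]]
    got <- realised[[stat]]
    err <- if (stat == "frac_above_limit") {
      abs(got - tgt)
    } else if (tgt == 0) {
      abs(got)
    } else {
      abs(got / tgt - 1)
    }
    data.frame(statistic = stat, target = tgt, realised = got,
               tolerance = tol, pass = err <= tol + 1e-12,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(statistic = character(), target = numeric(),
                      realised = numeric(), tolerance = numeric(),
                      pass = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read pool-target configuration blocks
#'
#' One `[analyte]` section per pool, with `key: value` lines for the
#' [pool_summary_targets()] fields (`median`, `mean`, `max`,
#' `frac_above_limit`, `limit`, `floor`, optional `size` and
#' `limit_kind`).
#'
#' @param path path of the targets file.
#' @return a named list of `pool_summary_targets`.
#' @export
load_pool_targets <- function(path) {
  if (!file.exists(path)) {
    stop("pool targets file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  blocks <- list()
  for (line in lines) {
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("[][]", "", line)
      blocks[[section]] <- list()
    } else {
      if (is.na(section)) {
        stop("pool target line outside a [section]: ", sQuote(line),
             call. = FALSE)
      }
      key <- trimws(sub(":.*$", "", line))
      val <- trimws(sub("^[^:]*:", "", line))
      blocks[[section]][[key]] <- val
    }
  }
  lapply(stats::setNames(names(blocks), names(blocks)), function(analyte) {
    b <- blocks[[analyte]]
    args <- list(analyte = analyte)
    for (key in c("median", "mean", "max", "frac_above_limit", "limit",
                  "floor", "size")) {
      if (!is.null(b[[key]])) args[[key]] <- as.numeric(b[[key]])
    }
    if (!is.null(b$limit_kind)) args$limit_kind <- b$limit_kind
    do.call(pool_summary_targets, args)
  })
}
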