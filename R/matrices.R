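#' Ordinal combination matrices
#'
#' The framework combines indicator levels through small total decision
#' matrices: a three-way matrix giving the presence of a hazard in the
#' final product from (occurrence, persistence, transfer) on the
#' environment route; a two-way matrix from (occurrence, accumulation)
#' on the accumulation route; and a two-way priority matrix from
#' (presence, severity).  Matrices are data, not code: they can be
#' loaded from a rule file (see [load_combination_matrices()]), and the
#' shipped defaults are the published matrices.  On construction every
#' matrix is checked for totality (each level tuple maps to exactly one
#' output) and monotonicity (the output never decreases when an input
#' level increases).
#'
#' @param rules character vector of rules `"L,M,* -> H"`; `*` is a
#'   wildcard over `L`, `M`, `H`.
#' @param arity number of inputs (2 or 3).
#' @param name label used in error messages.
#' @return a `combination_matrix`.
#' @examples
#' m <- combination_matrix(c("L,* -> L", "M,* -> M", "H,* -> H"), arity = 2)
#' matrix_lookup(m, hazard_level("M"), hazard_level("H"))
#' @export
combination_matrix <- function(rules, arity, name = "matrix") {
  stopifnot(arity %in% c(2L, 3L), is.character(rules), length(rules) > 0L)
  lv <- c("L", "M", "H")
  entries <- character()
  for (rule in rules) {
    parts <- strsplit(rule, "->", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop(name, ": malformed rule ", sQuote(rule),
           " (expected 'levels -> level')", call. = FALSE)
    }
    lhs <- trimws(strsplit(parts[[1L]], ",", fixed = TRUE)[[1L]])
    out <- trimws(parts[[2L]])
    if (length(lhs) != arity) {
      stop(name, ": rule ", sQuote(rule), " has ", length(lhs),
           " inputs, expected ", arity, call. = FALSE)
    }
    slots <- lapply(lhs, function(s) {
      if (s == "*") lv
      else lv[match(toupper(s), lv, nomatch = 0L)] %||%
        stop(name, ": invalid level ", sQuote(s), " in rule ",
             sQuote(rule), call. = FALSE)
    })
    out <- level_chr(hazard_level(out))
    keys <- apply(expand.grid(slots, stringsAsFactors = FALSE), 1L,
                  paste, collapse = ",")
    dup <- intersect(keys, names(entries))
    if (length(dup)) {
      stop(name, ": tuple(s) defined more than once: ",
           paste(dup, collapse = "; "), call. = FALSE)
    }
    entries[keys] <- out
  }
  all_keys <- apply(expand.grid(rep(list(lv), arity),
                                stringsAsFactors = FALSE), 1L,
                    paste, collapse = ",")
  missing <- setdiff(all_keys, names(entries))
  if (length(missing)) {
    stop(name, ": matrix is not total; undefined tuple(s): ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  m <- structure(list(arity = as.integer(arity), entries = entries,
                      name = name),
                 class = "combination_matrix")
  check_monotone(m)
  m
}

`%||%` <- function(x, y) if (length(x) == 0L || is.null(x)) y else x

# every +1 step in any single argument must not decrease the output
check_monotone <- function(m) {
  lv <- c("L", "M", "H")
  grid <- expand.grid(rep(list(lv), m$arity), stringsAsFactors = FALSE)
  rank <- function(x) match(x, lv)
  for (i in seq_len(nrow(grid))) {
    tup <- as.character(grid[i, ])
    out <- rank(m$entries[[paste(tup, collapse = ",")]])
    for (j in seq_len(m$arity)) {
      if (tup[[j]] == "H") next
      up <- tup
      up[[j]] <- lv[[rank(tup[[j]]) + 1L]]
      out_up <- rank(m$entries[[paste(up, collapse = ",")]])
      if (out_up < out) {
        stop(m$name, ": not monotone at (", paste(tup, collapse = ","),
             ") -> (", paste(up, collapse = ","), ")", call. = FALSE)
      }
    }
  }
  invisible(m)
}

#' @rdname combination_matrix
#' @param m a `combination_matrix`.
#' @param ... `arity` hazard levels.
#' @export
matrix_lookup <- function(m, ...) {
  stopifnot(inherits(m, "combination_matrix"))
  args <- lapply(list(...), hazard_level)
  if (length(args) != m$arity) {
    stop(m$name, ": expected ", m$arity, " levels, got ", length(args),
         call. = FALSE)
  }
  key <- paste(vapply(args, level_chr, ""), collapse = ",")
  hazard_level(m$entries[[key]])
}

#' Default combination matrices
#'
#' The published presence and priority matrices.  Environment route
#' (occurrence, persistence, transfer):
#' `(L,L,*)->L; (L,M,L)->L; (L,M,M/H)->M; (L,H,*)->M; (M,L/M,*)->M;
#' (M,H,*)->H; (H,L,*)->M; (H,M,L)->M; (H,M,M/H)->H; (H,H,*)->H`.
#' Accumulation route (occurrence, accumulation):
#' `(L,L)->L; (L,M/H)->M; (M,L/M)->M; (M,H)->H; (H,L/M)->M; (H,H)->H`.
#' Priority (presence, severity):
#' `(L,L/M)->L; (L,H)->M; (M,L)->L; (M,M)->M; (M,H)->H; (H,L)->M;
#' (H,M/H)->H`.
#'
#' @return a named list with elements `presence_environment`,
#'   `presence_accumulation` and `priority`.
#' @export
default_matrices <- function() {
  list(
    presence_environment = combination_matrix(c(
      "L,L,* -> L",
      "L,M,L -> L", "L,M,M -> M", "L,M,H -> M",
      "L,H,* -> M",
      "M,L,* -> M", "M,M,* -> M",
      "M,H,* -> H",
      "H,L,* -> M",
      "H,M,L -> M", "H,M,M -> H", "H,M,H -> H",
      "H,H,* -> H"
    ), arity = 3L, name = "presence_environment"),
    presence_accumulation = combination_matrix(c(
      "L,L -> L", "L,M -> M", "L,H -> M",
      "M,L -> M", "M,M -> M", "M,H -> H",
      "H,L -> M", "H,M -> M", "H,H -> H"
    ), arity = 2L, name = "presence_accumulation"),
    priority = combination_matrix(c(
      "L,L -> L", "L,M -> L", "L,H -> M",
      "M,L -> L", "M,M -> M", "M,H -> H",
      "H,L -> M", "H,M -> H", "H,H -> H"
    ), arity = 2L, name = "priority")
  )
}

#' Read / write combination matrices
#'
#' The rule-file format has one `[section]` per matrix
#' (`presence_environment`, `presence_accumulation`, `priority`) whose
#' lines are rules `L,M,* -> H`.  Wildcards are expanded on load and
#' every matrix is checked for totality, uniqueness and monotonicity.
#'
#' @param path path of the rule file.
#' @return `load_combination_matrices()` returns the named list of
#'   matrices (as [default_matrices()]).
#' @export
load_combination_matrices <- function(path) {
  if (!file.exists(path)) {
    stop("matrix file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  rules <- list()
  for (line in lines) {
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("[][]", "", line)
      rules[[section]] <- character()
    } else {
      if (is.na(section)) {
        stop("matrix rule outside a [section]: ", sQuote(line),
             call. = FALSE)
      }
      rules[[section]] <- c(rules[[section]], line)
    }
  }
  expected <- c("presence_environment", "presence_accumulation", "priority")
  missing <- setdiff(expected, names(rules))
  if (length(missing)) {
    stop("matrix file is missing section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  arity <- c(presence_environment = 3L, presence_accumulation = 2L,
             priority = 2L)
  stats::setNames(lapply(expected, function(s) {
    combination_matrix(rules[[s]], arity = arity[[s]], name = s)
  }), expected)
}

#' @rdname load_combination_matrices
#' @param matrices a named list of `combination_matrix` objects.
#' @export
save_combination_matrices <- function(matrices, path) {
  out <- character()
  for (s in names(matrices)) {
    m <- matrices[[s]]
    out <- c(out, paste0("[", s, "]"),
             paste(names(m$entries), "->", unname(m$entries)), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Presence and priority lookups with the default matrices
#'
#' Thin wrappers over [matrix_lookup()] using [default_matrices()]
#' (or any compatible matrix set).
#'
#' @param occurrence,persistence,transfer,accumulation,presence,severity
#'   hazard levels.
#' @param matrices a matrix set as returned by [default_matrices()] or
#'   [load_combination_matrices()].
#' @return a [hazard_level()].
#' @examples
#' presence_environment("H", "H", "L")   # (fluoro)quinolones
#' presence_accumulation("M", "H")       # cadmium in household waste
#' prioritize("H", "H")
#' @export
presence_environment <- function(occurrence, persistence, transfer,
                                 matrices = default_matrices()) {
  matrix_lookup(matrices$presence_environment, occurrence, persistence,
                transfer)
}

#' @rdname presence_environment
#' @export
presence_accumulation <- function(occurrence, accumulation,
                                  matrices = default_matrices()) {
  matrix_lookup(matrices$presence_accumulation, occurrence, accumulation)
}

#' @rdname presence_environment
#' @export
prioritize <- function(presence, severity, matrices = default_matrices()) {
  matrix_lookup(matrices$priority, presence, severity)
}

#' @export
print.combination_matrix <- function(x, ...) {
  cat(sprintf("<combination_matrix> %s (arity %d)\n", x$name, x$arity))
  for (key in names(x$entries)) {
    cat("  ", key, "->", x$entries[[key]], "\n")
  }
  invisible(x)
}
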