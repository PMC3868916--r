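#' prioritytag: the priority-tag model of attention capture by abrupt onsets
#'
#' The package models visual search through displays that mix abruptly
#' onsetting items with items revealed from placeholders. Search is assumed
#' serial and self-terminating: up to `c` onsets receive a priority tag and
#' are inspected (in random order) before the remaining items (also in random
#' order). The closed-form expected number of comparisons, a stochastic
#' simulator, synthetic experiment generation and capacity selection by
#' regression are the four pillars; see `vignette("priority-tag-model")`.
#'
#' @keywords internal
#' @importFrom rlang .data abort `%||%`
#' @importFrom stats coef fitted lm pf residuals rnorm runif sd var
#' @importFrom utils combn modifyList
"_PACKAGE"

# ---- exact rational helpers (internal) --------------------------------------
# All model expectations are ratios of small integers; keeping them as reduced
# (numerator, denominator) pairs lets the enumeration oracle be compared with
# strict equality rather than a floating tolerance.

frac <- function(num, den) {
  stopifnot(den != 0)
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- .gcd(abs(num), den)
  if (g > 1) {
    num <- num / g
    den <- den / g
  }
  c(num = num, den = den)
}

.gcd <- function(a, b) {
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  max(a, 1)
}

frac_value <- function(f) unname(f["num"] / f["den"])

# ---- condition validation ---------------------------------------------------

#' Validate a search condition
#'
#' A search condition is a display of `n` items of which `x` are abrupt
#' onsets, with the target being either an onset or a no-onset item. A
#' condition is valid when `0 <= x <= n`, an onset target implies at least one
#' onset (`x >= 1`), and a no-onset target implies at least one no-onset item
#' (`x <= n - 1`).
#'
#' @param n Display size (positive integer).
#' @param x Number of onsets (integer in `[0, n]`).
#' @param target_type `"onset"` or `"no_onset"`.
#' @return Invisibly `TRUE`; invalid conditions abort with a diagnostic naming
#'   the violated invariant.
#' @export
validate_condition <- function(n, x, target_type) {
  target_type <- match.arg(target_type, c("onset", "no_onset"))
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    abort("invalid condition: display size `n` must be a positive integer")
  }
  if (length(x) != 1 || is.na(x) || x != round(x)) {
    abort("invalid condition: onset count `x` must be an integer")
  }
  if (x < 0 || x > n) {
    abort(sprintf(
      "invalid condition: onset count must satisfy 0 <= x <= n (got x = %d, n = %d)",
      x, n
    ))
  }
  if (target_type == "onset" && x < 1) {
    abort("invalid condition: an onset target requires x >= 1 (no onset present at x = 0)")
  }
  if (target_type == "no_onset" && x > n - 1) {
    abort("invalid condition: a no-onset target requires x <= n - 1 (no no-onset item at x = n)")
  }
  invisible(TRUE)
}

.check_capacity <- function(c) {
  if (length(c) != 1 || is.na(c) || c < 0 || c != round(c)) {
    abort("invalid capacity: `c` must be a single non-negative integer")
  }
  invisible(TRUE)
}

# exact expected comparisons for one valid (c, n, x, t) cell; capacity is
# clamped to n (capacities beyond the display are prediction-identical to n)
.y_exact <- function(c, n, x, target_type) {
  c <- min(c, n)
  if (target_type == "onset") {
    if (c < x) {
      # two-stage search: tagged subset of onsets first, remainder second
      frac(x * (n + c + 1) - c * n, 2 * x)
    } else {
      frac(x + 1, 2)
    }
  } else {
    if (c < x) frac(n + c + 1, 2) else frac(x + n + 1, 2)
  }
}

#' Expected number of comparisons to find the target
#'
#' Closed-form expectation under the priority-tag model for mixed designs,
#' where the target type is task-irrelevant. With capacity `c`, a uniformly
#' random subset of `min(c, x)` onsets is inspected (in random order) before
#' the remaining items (in random order); search stops at the target. The
#' expectation dispatches on whether the capacity covers the onsets
#' (`c >= x`) and on the target type:
#'
#' * onset target, `c < x`: `(n + c + 1) / 2 - c * n / (2 * x)`
#' * onset target, `c >= x`: `(x + 1) / 2`
#' * no-onset target, `c < x`: `(n + c + 1) / 2`
#' * no-onset target, `c >= x`: `x + (n - x + 1) / 2`
#'
#' Capacities larger than `n` are clamped to `n` (they make identical
#' predictions). Values are computed exactly in integer arithmetic; set
#' `exact = TRUE` to obtain the reduced numerator/denominator pair.
#'
#' @inheritParams validate_condition
#' @param c Priority-set capacity (non-negative integer).
#' @param exact If `TRUE`, return a named numeric `c(num, den)` instead of the
#'   floating-point value. Requires scalar `x`/`target_type`.
#' @return Expected comparisons (numeric, vectorised over `x` and
#'   `target_type`), or an exact fraction when `exact = TRUE`.
#' @examples
#' expected_comparisons(c = 5, n = 8, x = 8, target_type = "onset") # 4.5
#' expected_comparisons(c = 8, n = 8, x = 4, target_type = "no_onset") # 6.5
#' @export
expected_comparisons <- function(c, n, x, target_type, exact = FALSE) {
  .check_capacity(c)
  if (exact) {
    validate_condition(n, x, target_type)
    return(.y_exact(c, n, x, target_type))
  }
  k <- max(length(x), length(target_type))
  x <- rep_len(x, k)
  target_type <- rep_len(target_type, k)
  vapply(seq_len(k), function(i) {
    validate_condition(n, x[i], target_type[i])
    frac_value(.y_exact(c, n, x[i], target_type[i]))
  }, numeric(1))
}

#' Expected comparisons in a blocked design with known relevant set
#'
#' In a blocked design the participant knows in advance which `r` items
#' (the search-relevant set) can contain the target, so up to `c` of the
#' relevant items are tagged regardless of whether they are onsets. The
#' onset-target expectation formulas therefore apply with `x := r` to both
#' target-type blocks: `(r + 1) / 2` when `c >= r`, otherwise
#' `(n + c + 1) / 2 - c * n / (2 * r)`.
#'
#' @inheritParams expected_comparisons
#' @param r Number of search-relevant items (integer in `[1, n]`), vectorised.
#' @return Expected comparisons (numeric), or exact fraction for scalar `r`
#'   when `exact = TRUE`.
#' @examples
#' blocked_expected_comparisons(c = 3, n = 8, r = 3) # 2
#' blocked_expected_comparisons(c = 3, n = 8, r = 8) # 4.5
#' @export
blocked_expected_comparisons <- function(c, n, r, exact = FALSE) {
  .check_capacity(c)
  check_r <- function(ri) {
    if (is.na(ri) || ri != round(ri) || ri < 1 || ri > n) {
      abort(sprintf(
        "invalid condition: relevant-set size must satisfy 1 <= r <= n (got r = %s, n = %d)",
        format(ri), n
      ))
    }
  }
  if (exact) {
    stopifnot(length(r) == 1)
    check_r(r)
    return(.y_exact(c, n, r, "onset"))
  }
  vapply(r, function(ri) {
    check_r(ri)
    frac_value(.y_exact(c, n, ri, "onset"))
  }, numeric(1))
}

#' Tabulate model predictions over a design
#'
#' Builds the prediction table behind the model's signature fan of curves:
#' expected comparisons as a function of the number of onsets, one line per
#' target type, for a given capacity. Invalid cells (onset target with
#' `x = 0`, no-onset target with `x = n`) are omitted rather than filled with
#' `NA`. In blocked mode `x_values` are interpreted as relevant-set sizes and
#' both target-type blocks receive the same prediction.
#'
#' @inheritParams expected_comparisons
#' @param x_values Integer vector of onset counts (mixed) or relevant-set
#'   sizes (blocked).
#' @param mode `"mixed"` or `"blocked"`.
#' @return A tibble with columns `c`, `n`, `x`, `target_type`, `mode`, `y`;
#'   empty for empty `x_values`.
#' @export
prediction_table <- function(c, n, x_values, mode = c("mixed", "blocked")) {
  mode <- match.arg(mode)
  .check_capacity(c)
  rows <- list()
  for (x in x_values) {
    for (t in c("onset", "no_onset")) {
      if (mode == "mixed") {
        ok <- x >= 0 && x <= n && !(t == "onset" && x < 1) &&
          !(t == "no_onset" && x > n - 1)
        if (!ok) next
        y <- frac_value(.y_exact(c, n, x, t))
      } else {
        if (x < 1 || x > n) next
        y <- frac_value(.y_exact(c, n, x, "onset"))
      }
      rows[[length(rows) + 1]] <-
        tibble::tibble(c = c, n = n, x = x, target_type = t, mode = mode, y = y)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      c = integer(), n = integer(), x = integer(),
      target_type = character(), mode = character(), y = numeric()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Partition capacities into prediction-identical groups
#'
#' Two capacities are equivalent with respect to a design when they assign the
#' same expected number of comparisons to every cell of the design. Designs
#' that do not probe intermediate onset counts cannot distinguish high
#' capacities: the classic display-size-8 design with onsets
#' `{0, 1, 2, 4, 6, 8}` cannot tell capacities 6, 7 and 8 apart.
#'
#' @param n Display size.
#' @param design_cells A data frame with columns `x` and `target_type` (and
#'   optionally `mode`, defaulting to the `mode` argument) listing the design
#'   cells.
#' @param capacities Capacities to partition, default `0:n`.
#' @param mode `"mixed"` or `"blocked"`; in blocked mode `x` is the
#'   relevant-set size and `target_type` is ignored for the prediction.
#' @return A list of integer vectors, each a group of prediction-identical
#'   capacities, ordered by smallest member.
#' @export
equivalent_capacities <- function(n, design_cells, capacities = 0:n,
                                  mode = c("mixed", "blocked")) {
  mode <- match.arg(mode)
  if (!nrow(design_cells)) abort("design_cells must be non-empty")
  cells <- dplyr::distinct(
    tibble::as_tibble(design_cells)[, c("x", "target_type")]
  )
  key <- function(c) {
    paste(vapply(seq_len(nrow(cells)), function(i) {
      if (mode == "mixed") {
        validate_condition(n, cells$x[i], cells$target_type[i])
        f <- .y_exact(c, n, cells$x[i], cells$target_type[i])
      } else {
        f <- .y_exact(c, n, cells$x[i], "onset")
      }
      paste(f, collapse = "/")
    }, character(1)), collapse = ";")
  }
  capacities <- sort(unique(as.integer(capacities)))
  keys <- vapply(capacities, key, character(1))
  unname(lapply(split(capacities, factor(keys, levels = unique(keys))), identity))
}

#' Read and write prediction tables
#'
#' Prediction tables round-trip as CSV with the header
#' `c,n,x,target_type,mode,y`, and can be exported as JSON records.
#'
#' @param table A prediction table from [prediction_table()].
#' @param path File path.
#' @return `write_prediction_table()` returns `path` invisibly;
#'   `read_prediction_table()` returns the tibble.
#' @export
write_prediction_table <- function(table, path) {
  readr::write_csv(table[, c("c", "n", "x", "target_type", "mode", "y")], path)
  invisible(path)
}

#' @rdname write_prediction_table
#' @export
read_prediction_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    c = readr::col_integer(), n = readr::col_integer(),
    x = readr::col_integer(), target_type = readr::col_character(),
    mode = readr::col_character(), y = readr::col_double()
  ))
}

#' @rdname write_prediction_table
#' @export
write_prediction_json <- function(table, path) {
  jsonlite::write_json(table, path, dataframe = "rows", digits = NA)
  invisible(path)
}
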