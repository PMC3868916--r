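# Preprocessing, per-capacity OLS fits of the linear comparison model, and
# capacity selection via the per-participant R-squared comparison procedure
# (one-way repeated-measures ANOVA with Greenhouse-Geisser correction and
# unadjusted LSD pairwise comparisons).

#' Preprocess a trial table into cell means
#'
#' Drops practice trials, flags error trials (excluded from RT means but
#' counted in error rates) and RT outliers among correct trials (strictly
#' below `rt_min` or above `rt_max` ms), and computes mean correct RT per
#' participant and design cell. For every cell,
#' `n_used + n_error + n_outlier = n_raw`.
#'
#' @param trials A trial table ([generate_trials()] schema).
#' @param rt_min,rt_max Outlier bounds in ms (defaults 200 and 2000).
#' @return A `cell_means` tibble with columns `participant`, `x`,
#'   `target_type`, `n_raw`, `n_error`, `n_outlier`, `n_used`, `mean_rt`,
#'   `error_rate` (percent). Cells whose every trial was excluded are dropped
#'   from the table and reported in `attr(, "empty_cells")`; the overall
#'   outlier fraction is in `attr(, "outlier_fraction")`.
#' @export
preprocess <- function(trials, rt_min = 200, rt_max = 2000) {
  req <- c("participant", "x", "target_type", "correct", "rt_ms")
  miss <- setdiff(req, names(trials))
  if (length(miss)) {
    abort(paste0("trial table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if ("practice" %in% names(trials)) {
    trials <- dplyr::filter(trials, !.data$practice)
  }
  if (!nrow(trials)) abort("no experimental trials to preprocess")
  trials$.error <- !trials$correct
  trials$.outlier <- trials$correct &
    (trials$rt_ms < rt_min | trials$rt_ms > rt_max)
  trials$.used <- !trials$.error & !trials$.outlier
  cells <- trials |>
    dplyr::group_by(.data$participant, .data$x, .data$target_type) |>
    dplyr::summarise(
      n_raw = dplyr::n(),
      n_error = sum(.data$.error),
      n_outlier = sum(.data$.outlier),
      n_used = sum(.data$.used),
      mean_rt = if (sum(.data$.used) > 0) {
        mean(.data$rt_ms[.data$.used])
      } else {
        NA_real_
      },
      error_rate = 100 * sum(.data$.error) / dplyr::n(),
      .groups = "drop"
    )
  empty <- dplyr::filter(cells, .data$n_used == 0)
  kept <- dplyr::filter(cells, .data$n_used > 0)
  structure(
    kept,
    class = c("cell_means", class(kept)),
    empty_cells = empty,
    outlier_fraction = sum(trials$.outlier) / nrow(trials),
    rt_bounds = c(rt_min, rt_max),
    display_size = if ("n" %in% names(trials)) trials$n[1] else NA_integer_
  )
}

# pooled cell means: grand mean over participants' cell means, unweighted by
# default (each participant counts equally); optionally weighted by trial count
.pool_cells <- function(cells, weighted = FALSE) {
  cells |>
    dplyr::group_by(.data$x, .data$target_type) |>
    dplyr::summarise(
      mean_rt = if (weighted) {
        sum(.data$mean_rt * .data$n_used) / sum(.data$n_used)
      } else {
        mean(.data$mean_rt)
      },
      n_participants = dplyr::n(),
      .groups = "drop"
    )
}

.fit_forms <- c("eq5_mixed", "eq6_blocked")

# design matrix + response for one capacity; returns NULL flag when the
# capacity predicts no variation (constant y under a slope-only form is still
# fittable; constant y under c = 0 is the degenerate flat model)
.build_fit_data <- function(pooled, c, form, n, exclude_r) {
  if (form == "eq5_mixed") {
    y <- expected_comparisons(c, n, pooled$x, pooled$target_type)
    t01 <- as.integer(pooled$target_type == "onset")
    tibble::tibble(
      x = pooled$x, target_type = pooled$target_type,
      y = y, t01 = t01, rt = pooled$mean_rt
    )
  } else {
    tt <- unique(pooled$target_type)
    if (length(tt) != 1) {
      abort("blocked fits are run per target type; filter cells to one target type first")
    }
    r <- if (tt == "onset") pooled$x else n - pooled$x
    keep <- !(r %in% exclude_r)
    pooled <- pooled[keep, ]
    r <- r[keep]
    tibble::tibble(
      x = pooled$x, target_type = pooled$target_type, r = r,
      y = blocked_expected_comparisons(c, n, r), rt = pooled$mean_rt
    )
  }
}

#' Fit the linear comparison model at one capacity
#'
#' Ordinary least squares on cell mean RTs with the model-predicted expected
#' comparisons as regressor. The mixed form is
#' `RT = a * y(c; n, x, t) + b * t + d` with the indicator `t = 1` for onset
#' targets (so a negative `b` is an onset advantage); the blocked form drops
#' the indicator: `RT = a * y(c; n, r) + d`. Capacity 0 predicts no RT
#' variation, so no slope is fit and the result is flagged.
#'
#' @param cells A `cell_means` table from [preprocess()] (or a pooled table
#'   with columns `x`, `target_type`, `mean_rt`).
#' @param c Capacity to evaluate.
#' @param form `"eq5_mixed"` or `"eq6_blocked"`.
#' @param n Display size (default 8).
#' @param weighted Weight the pooled cell means by trial count (default
#'   unweighted, each participant's cell mean counting equally).
#' @param exclude_r Relevant-set sizes to drop from a blocked fit (e.g.
#'   `exclude_r = 1`, where the target location is fully predictable).
#' @return A `fit_result` list: `c`, `form`, coefficients `a`, `b`, `d` with
#'   standard errors, `r2`, `n_cells`, a per-cell `residuals` tibble, and
#'   `flag` (`"predicts no variation"` for the degenerate capacity).
#' @export
fit_capacity <- function(cells, c, form = c("eq5_mixed", "eq6_blocked"),
                         n = 8, weighted = FALSE, exclude_r = integer(0)) {
  form <- match.arg(form)
  pooled <- if ("participant" %in% names(cells)) {
    .pool_cells(cells, weighted)
  } else {
    cells[, intersect(c("x", "target_type", "mean_rt"), names(cells))]
  }
  dat <- .build_fit_data(pooled, c, form, n, exclude_r)
  res <- list(
    c = c, form = form, n = n,
    a = NA_real_, a_se = NA_real_, b = NA_real_, b_se = NA_real_,
    d = NA_real_, d_se = NA_real_, r2 = NA_real_,
    n_cells = nrow(dat), residuals = NULL, flag = NA_character_
  )
  min_cells <- if (form == "eq5_mixed") 3L else 2L
  if (nrow(dat) < min_cells) {
    abort(sprintf(
      "need at least %d cells to fit %s (got %d)", min_cells, form, nrow(dat)
    ))
  }
  if (var(dat$y) < 1e-12) {
    res$flag <- "predicts no variation"
    return(structure(res, class = "fit_result"))
  }
  fml <- if (form == "eq5_mixed") rt ~ y + t01 else rt ~ y
  fit <- lm(fml, data = dat)
  if (fit$rank < length(coef(fit))) {
    abort("rank-deficient design matrix: predictors are collinear for this capacity/design")
  }
  # zero-residual (noiseless) data trips summary.lm's perfect-fit warning;
  # that case is legitimate here
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- sm$coefficients
  res$a <- cf["y", 1]
  res$a_se <- cf["y", 2]
  if (form == "eq5_mixed") {
    res$b <- cf["t01", 1]
    res$b_se <- cf["t01", 2]
  }
  res$d <- cf["(Intercept)", 1]
  res$d_se <- cf["(Intercept)", 2]
  res$r2 <- sm$r.squared
  dat$fitted <- fitted(fit)
  dat$resid <- residuals(fit)
  res$residuals <- dat
  structure(res, class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!is.na(x$flag)) {
    cat(sprintf("<fit_result> c = %d (%s): %s\n", x$c, x$form, x$flag))
    return(invisible(x))
  }
  cat(sprintf(
    "<fit_result> c = %d (%s): a = %.1f (%.1f)%s, d = %.0f (%.1f), R^2 = %.3f\n",
    x$c, x$form, x$a, x$a_se,
    if (!is.na(x$b)) sprintf(", b = %.1f (%.1f)", x$b, x$b_se) else "",
    x$d, x$d_se, x$r2
  ))
  invisible(x)
}

# Greenhouse-Geisser epsilon from the sample covariance of a subjects x levels
# matrix, via an orthonormal contrast basis
.gg_epsilon <- function(mat) {
  k <- ncol(mat)
  C <- qr.Q(qr(stats::contr.helmert(k)))
  M <- t(C) %*% stats::cov(mat) %*% C
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M * M))
  max(min(eps, 1), 1 / (k - 1))
}

# one-way repeated-measures ANOVA on a subjects x levels matrix with GG
# sphericity correction
.rm_anova <- function(mat) {
  nsub <- nrow(mat)
  k <- ncol(mat)
  grand <- mean(mat)
  col_m <- colMeans(mat)
  row_m <- rowMeans(mat)
  ss_treat <- nsub * sum((col_m - grand)^2)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_err <- sum((mat - grand)^2) - ss_treat - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (nsub - 1)
  if (ss_err <= .Machine$double.eps * abs(ss_treat + 1)) {
    return(list(applicable = FALSE, reason = "zero error variance"))
  }
  f <- (ss_treat / df1) / (ss_err / df2)
  eps <- .gg_epsilon(mat)
  list(
    applicable = TRUE, F = f, df1 = df1, df2 = df2,
    gg_epsilon = eps,
    p = pf(f, df1, df2, lower.tail = FALSE),
    p_gg = pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  )
}

# unadjusted pairwise paired t-tests (Fisher's LSD following the ANOVA)
.lsd_pairs <- function(mat) {
  labs <- colnames(mat)
  combs <- combn(ncol(mat), 2)
  rows <- lapply(seq_len(ncol(combs)), function(j) {
    i1 <- combs[1, j]
    i2 <- combs[2, j]
    d <- mat[, i1] - mat[, i2]
    if (sd(d) < 1e-14) {
      return(tibble::tibble(
        level1 = labs[i1], level2 = labs[i2],
        mean_diff = mean(d), t = NA_real_, df = length(d) - 1, p = NA_real_
      ))
    }
    tt <- stats::t.test(mat[, i1], mat[, i2], paired = TRUE)
    tibble::tibble(
      level1 = labs[i1], level2 = labs[i2],
      mean_diff = unname(tt$estimate), t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare priority-tag capacities on one dataset
#'
#' Runs the full selection procedure: a pooled fit per capacity, optional
#' per-participant fits, a one-way repeated-measures ANOVA (with
#' Greenhouse-Geisser correction) on the per-participant R-squared values
#' across the distinguishable capacity levels, unadjusted LSD pairwise
#' comparisons, and capacity selection as the highest pooled R-squared with
#' ties broken toward the smaller capacity. Capacities that make identical
#' predictions on the design (see [equivalent_capacities()]) carry identical
#' fits; the ANOVA and post-hoc stages use one representative per group.
#'
#' @param trials A trial table, or a preprocessed `cell_means` object.
#' @param form `"eq5_mixed"` or `"eq6_blocked"`.
#' @param capacities Capacities to sweep (default `0:n`).
#' @param n Display size.
#' @param participant_fits Compute the per-participant R-squared matrix and
#'   its ANOVA/post-hoc stage (default `TRUE`; disable for speed in large
#'   recovery loops where only the pooled selection is needed).
#' @param weighted,exclude_r Passed to [fit_capacity()].
#' @return A `model_comparison` list: `fits` (per-capacity `fit_result`s),
#'   `fits_table` (tidy coefficient table), `r2_matrix` (participants x
#'   capacities), `anova`, `posthoc`, `equiv_groups`, `selected` and
#'   `tie_group`.
#' @export
compare_capacities <- function(trials, form = c("eq5_mixed", "eq6_blocked"),
                               capacities = NULL, n = 8,
                               participant_fits = TRUE, weighted = FALSE,
                               exclude_r = integer(0)) {
  form <- match.arg(form)
  cells <- if (inherits(trials, "cell_means")) trials else preprocess(trials)
  capacities <- sort(unique(as.integer(capacities %||% 0:n)))
  if (length(capacities) < 2) abort("need at least 2 capacity levels to compare")

  fits <- lapply(capacities, function(cc) {
    fit_capacity(cells, cc, form, n, weighted, exclude_r)
  })
  names(fits) <- capacities
  fits_table <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      c = f$c, a = f$a, a_se = f$a_se, b = f$b, b_se = f$b_se,
      d = f$d, d_se = f$d_se, r2 = f$r2, flag = f$flag
    )
  }))

  # equivalence groups on this design's cells
  dcells <- dplyr::distinct(tibble::as_tibble(cells)[, c("x", "target_type")])
  if (form == "eq6_blocked") {
    tt <- unique(dcells$target_type)
    dcells$x <- if (tt == "onset") dcells$x else n - dcells$x
    dcells <- dcells[!(dcells$x %in% exclude_r), ]
    groups <- equivalent_capacities(n, dcells, capacities, mode = "blocked")
  } else {
    groups <- equivalent_capacities(n, dcells, capacities, mode = "mixed")
  }

  # selection on the pooled fits (non-degenerate capacities only)
  ok <- !is.na(fits_table$r2)
  if (!any(ok)) abort("no capacity produced a valid fit")
  r2 <- fits_table$r2[ok]
  cand <- fits_table$c[ok]
  best <- max(r2)
  tied <- cand[r2 >= best - 1e-12]
  selected <- min(tied)
  tie_group <- groups[[which(vapply(groups, function(g) selected %in% g, logical(1)))]]

  r2_matrix <- NULL
  anova <- NULL
  posthoc <- NULL
  if (participant_fits) {
    parts <- sort(unique(cells$participant))
    fitc <- capacities[vapply(
      capacities,
      function(cc) is.na(fits[[as.character(cc)]]$flag), logical(1)
    )]
    r2_matrix <- matrix(
      NA_real_, length(parts), length(fitc),
      dimnames = list(parts, fitc)
    )
    for (i in seq_along(parts)) {
      pc <- cells[cells$participant == parts[i], ]
      for (j in seq_along(fitc)) {
        r2_matrix[i, j] <-
          fit_capacity(pc, fitc[j], form, n, weighted, exclude_r)$r2
      }
    }
    if (length(parts) >= 2) {
      # one column per distinguishable prediction group
      reps <- vapply(groups, function(g) {
        gg <- g[g %in% fitc]
        if (length(gg)) min(gg) else NA_integer_
      }, integer(1))
      reps <- reps[!is.na(reps)]
      mat <- r2_matrix[, as.character(reps), drop = FALSE]
      if (ncol(mat) >= 2 && any(apply(mat, 1, function(r) diff(range(r)) > 1e-12))) {
        anova <- .rm_anova(mat)
        posthoc <- .lsd_pairs(mat)
      } else {
        anova <- list(
          applicable = FALSE,
          reason = "R^2 constant across capacity levels"
        )
      }
    }
  }

  structure(
    list(
      form = form, n = n, capacities = capacities,
      fits = fits, fits_table = fits_table,
      equiv_groups = groups,
      selected = selected, tie_group = tie_group,
      r2_matrix = r2_matrix, anova = anova, posthoc = posthoc
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model_comparison> %s, capacities %s\n", x$form,
    paste(range(x$capacities), collapse = "-")
  ))
  print(x$fits_table)
  cat(sprintf(
    "selected capacity: %d (prediction-identical group: %s)\n",
    x$selected, paste(x$tie_group, collapse = ", ")
  ))
  if (!is.null(x$anova)) {
    if (isTRUE(x$anova$applicable)) {
      cat(sprintf(
        "R^2 ANOVA: F(%d, %d) = %.2f, GG epsilon = %.3f, p_GG = %.4g\n",
        x$anova$df1, x$anova$df2, x$anova$F, x$anova$gg_epsilon, x$anova$p_gg
      ))
    } else {
      cat(sprintf("R^2 ANOVA inapplicable: %s\n", x$anova$reason))
    }
  }
  invisible(x)
}

#' Classify participants by best-fitting capacity
#'
#' Assigns every participant the capacity with the highest individual
#' R-squared (smallest capacity on ties) and counts how many fall at or below
#' a capacity boundary versus above it.
#'
#' @param comparison A [compare_capacities()] result with participant fits.
#' @param boundary Capacity boundary (default 2, separating small-capacity
#'   from large-capacity searchers).
#' @return A list with `per_participant` (tibble `participant`, `best_c`),
#'   `n_at_or_below`, `n_above`, `boundary`.
#' @export
classify_participants <- function(comparison, boundary = 2) {
  mat <- comparison$r2_matrix
  if (is.null(mat)) {
    abort("comparison lacks per-participant fits; rerun with participant_fits = TRUE")
  }
  caps <- as.integer(colnames(mat))
  best <- apply(mat, 1, function(r) {
    caps[min(which(r >= max(r) - 1e-12))]
  })
  per <- tibble::tibble(
    participant = as.integer(rownames(mat)),
    best_c = as.integer(best)
  )
  list(
    per_participant = per,
    n_at_or_below = sum(per$best_c <= boundary),
    n_above = sum(per$best_c > boundary),
    boundary = boundary
  )
}

#' Write a per-capacity fit table as CSV
#'
#' Header `c,a,a_se,b,b_se,d,d_se,r2`; the `b` columns are empty for blocked
#' fits.
#'
#' @param comparison A [compare_capacities()] result.
#' @param path Output CSV path.
#' @export
write_fits_csv <- function(comparison, path) {
  readr::write_csv(
    comparison$fits_table[, c("c", "a", "a_se", "b", "b_se", "d", "d_se", "r2")],
    path
  )
  invisible(path)
}
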