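make_trials <- function(c_true = 1, sigma = 0, n_participants = 1, seed = 5,
                        experiment = "exp1", ...) {
  p <- generative_params(
    a = 30, b = -70, d = 760, c_true = c_true, sigma = sigma,
    lapse = 0, outlier_rate = 0, a_sd = 0, b_sd = 0, d_sd = 0, ...
  )
  generate_trials(build_design(experiment), p, n_participants, seed)
}

test_that("preprocessing excludes errors and outliers and reconciles counts", {
  tr <- make_trials(sigma = 50, n_participants = 2)
  # plant known exclusions in one cell
  idx <- which(!tr$practice & tr$participant == 1 & tr$x == 4 &
    tr$target_type == "no_onset")
  tr$rt_ms[idx[1]] <- 150 # below the window
  tr$rt_ms[idx[2]] <- 2500 # above the window
  tr$correct[idx[3]] <- FALSE
  cm <- preprocess(tr)
  cell <- cm[cm$participant == 1 & cm$x == 4 & cm$target_type == "no_onset", ]
  expect_equal(cell$n_raw, 20)
  expect_equal(cell$n_outlier, 2)
  expect_equal(cell$n_error, 1)
  expect_equal(cell$n_used, 17)
  expect_equal(cell$n_used + cell$n_error + cell$n_outlier, cell$n_raw)
  # the cell mean uses only the retained trials
  kept <- tr[setdiff(idx, idx[1:3]), ]
  expect_equal(cell$mean_rt, mean(kept$rt_ms))
  expect_equal(cell$error_rate, 100 * 1 / 20)
  # counts reconcile across the whole table
  expect_equal(sum(cm$n_raw), 2 * 400)
  expect_error(preprocess(tr[, 1:3]), "missing column")
})

test_that("planted outlier fractions are reported", {
  p <- generative_params(c_true = 1, lapse = 0, outlier_rate = 0.011)
  tr <- generate_trials(build_design("exp1"), p, 22, seed = 8)
  cm <- preprocess(tr)
  expect_lt(abs(attr(cm, "outlier_fraction") - 0.011), 0.004)
})

test_that("cells with all trials excluded are reported, not zeroed", {
  tr <- make_trials(sigma = 0, n_participants = 1)
  kill <- !tr$practice & tr$x == 8
  tr$correct[kill] <- FALSE
  cm <- preprocess(tr)
  expect_false(any(cm$x == 8))
  empty <- attr(cm, "empty_cells")
  expect_equal(nrow(empty), 1)
  expect_equal(empty$x, 8)
  expect_equal(empty$n_error, 20)
})

test_that("noiseless generation is recovered exactly at the generating capacity", {
  tr <- make_trials(c_true = 1)
  cm <- preprocess(tr)
  f <- fit_capacity(cm, 1, "eq5_mixed")
  expect_equal(f$a, 30, tolerance = 1e-10)
  expect_equal(f$b, -70, tolerance = 1e-10)
  expect_equal(f$d, 760, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-12)
})

test_that("capacity zero is flagged as predicting no variation", {
  tr <- make_trials(c_true = 1)
  f0 <- fit_capacity(preprocess(tr), 0, "eq5_mixed")
  expect_equal(f0$flag, "predicts no variation")
  expect_true(is.na(f0$a) && is.na(f0$r2))
})

test_that("prediction-identical capacities yield identical fits", {
  tr <- make_trials(c_true = 1, sigma = 120, n_participants = 4)
  cm <- preprocess(tr)
  f6 <- fit_capacity(cm, 6, "eq5_mixed")
  f7 <- fit_capacity(cm, 7, "eq5_mixed")
  f8 <- fit_capacity(cm, 8, "eq5_mixed")
  expect_equal(f6[c("a", "b", "d", "r2")], f7[c("a", "b", "d", "r2")])
  expect_equal(f7[c("a", "b", "d", "r2")], f8[c("a", "b", "d", "r2")])
})

test_that("R^2 is invariant to affine rescaling of the RTs", {
  tr <- make_trials(c_true = 2, sigma = 100, n_participants = 4)
  cm <- preprocess(tr)
  f <- fit_capacity(cm, 3, "eq5_mixed")
  cm2 <- cm
  cm2$mean_rt <- 2.5 * cm2$mean_rt + 100
  f2 <- fit_capacity(cm2, 3, "eq5_mixed")
  expect_equal(f2$r2, f$r2, tolerance = 1e-12)
  expect_equal(f2$a, 2.5 * f$a, tolerance = 1e-10)
})

test_that("the goodness-of-fit profile decreases beyond the generating capacity", {
  tr <- make_trials(c_true = 1, sigma = 150, n_participants = 22, seed = 42)
  cmp <- compare_capacities(tr, "eq5_mixed", participant_fits = FALSE)
  r2 <- cmp$fits_table$r2[match(c(1, 3, 5, 8), cmp$fits_table$c)]
  expect_true(all(diff(r2) < 0))
  expect_equal(cmp$selected, 1)
  expect_equal(cmp$tie_group, 1L)
})

test_that("capacity comparison runs the ANOVA and LSD stages on participant R^2", {
  tr <- make_trials(c_true = 1, sigma = 150, n_participants = 8, seed = 14)
  cmp <- compare_capacities(tr, "eq5_mixed")
  expect_equal(dim(cmp$r2_matrix), c(8, 8)) # capacities 1..8 (0 is degenerate)
  # identical columns for the indistinguishable top group
  expect_equal(cmp$r2_matrix[, "6"], cmp$r2_matrix[, "8"])
  expect_true(cmp$anova$applicable)
  expect_true(cmp$anova$gg_epsilon >= 1 / 5 && cmp$anova$gg_epsilon <= 1)
  expect_equal(cmp$anova$df1, 5) # 6 distinguishable levels
  expect_equal(nrow(cmp$posthoc), choose(6, 2))
  expect_true(all(cmp$posthoc$p <= 1, na.rm = TRUE))
})

test_that("constant per-participant R^2 makes the ANOVA inapplicable", {
  # a design probing only x <= 1 cannot distinguish any positive capacity
  cells <- tibble::tibble(
    participant = rep(1:3, each = 3),
    x = rep(c(0, 1, 1), 3),
    target_type = rep(c("no_onset", "no_onset", "onset"), 3),
    n_used = 10,
    mean_rt = rep(c(900, 910, 700), 3) + rep(c(0, 5, -5), each = 3)
  )
  class(cells) <- c("cell_means", class(cells))
  cmp <- compare_capacities(cells, "eq5_mixed")
  expect_false(cmp$anova$applicable)
})

test_that("blocked fits use the relevant-set forms, optionally excluding r = 1", {
  tr <- make_trials(c_true = 3, experiment = "exp3")
  cm <- preprocess(tr)
  on <- cm[cm$target_type == "onset", ]
  class(on) <- class(cm)
  f <- fit_capacity(on, 3, "eq6_blocked", exclude_r = 1)
  expect_equal(f$n_cells, 7)
  expect_equal(f$a, 30, tolerance = 1e-10)
  expect_equal(f$d, 760 - 70, tolerance = 1e-10) # onset offset folds into the intercept
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_true(is.na(f$b))
  no <- cm[cm$target_type == "no_onset", ]
  class(no) <- class(cm)
  fno <- fit_capacity(no, 3, "eq6_blocked", exclude_r = 1)
  expect_equal(fno$a, 30, tolerance = 1e-10)
  expect_equal(fno$d, 760, tolerance = 1e-10)
  # mixing both target types in one blocked fit is rejected
  expect_error(fit_capacity(cm, 3, "eq6_blocked"), "per target type")
})

test_that("blocked comparison at high capacity selects the top group", {
  tr <- make_trials(c_true = 8, sigma = 120, n_participants = 12,
    experiment = "exp3", seed = 77)
  cm <- preprocess(tr)
  on <- cm[cm$target_type == "onset", ]
  class(on) <- class(cm)
  cmp <- compare_capacities(on, "eq6_blocked", participant_fits = FALSE,
    exclude_r = 1)
  expect_true(cmp$selected %in% 7:8)
  expect_true(8 %in% cmp$tie_group)
})

test_that("participants are classified by their best-fitting capacity", {
  # noiseless single participant: exact classification at the true capacity
  tr <- make_trials(c_true = 2, n_participants = 1)
  cmp <- compare_capacities(
    rbind(tr, transform(tr, participant = 2L)), "eq5_mixed"
  )
  cl <- classify_participants(cmp)
  expect_true(all(cl$per_participant$best_c == 2))
  expect_equal(cl$n_at_or_below, 2)
  expect_equal(cl$n_above, 0)
  # a mixture of small- and large-capacity participants splits at the boundary
  p1 <- generative_params(c_true = 1, sigma = 80, a_sd = 0, b_sd = 0, d_sd = 0,
    lapse = 0, outlier_rate = 0)
  p8 <- generative_params(c_true = 8, sigma = 80, a_sd = 0, b_sd = 0, d_sd = 0,
    lapse = 0, outlier_rate = 0)
  d <- build_design("exp1")
  low <- generate_trials(d, p1, 8, seed = 101)
  high <- generate_trials(d, p8, 8, seed = 102)
  high$participant <- high$participant + 8L
  cl2 <- classify_participants(compare_capacities(rbind(low, high), "eq5_mixed"))
  expect_gte(cl2$n_at_or_below, 6)
  expect_gte(cl2$n_above, 6)
})
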