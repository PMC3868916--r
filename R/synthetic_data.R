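# Synthetic trial-level datasets with the statistical structure of the three
# onset-search experiments: their exact cell counts, the inverse-probability
# allocation of target type in mixed designs, RTs generated from the linear
# comparison model, lapse errors and RT outliers.

# per-participant trial counts per (x, target_type) cell; mixed designs keep
# the onset-target proportion at each x equal to x/n by construction
.design_cells <- list(
  exp1 = tibble::tribble(
    ~x, ~target_type, ~n_trials,
    0L, "no_onset", 20L,
    1L, "no_onset", 140L, 1L, "onset", 20L,
    2L, "no_onset", 60L, 2L, "onset", 20L,
    4L, "no_onset", 20L, 4L, "onset", 20L,
    6L, "no_onset", 20L, 6L, "onset", 60L,
    8L, "onset", 20L
  ),
  exp2 = tibble::tribble(
    ~x, ~target_type, ~n_trials,
    0L, "no_onset", 20L,
    1L, "no_onset", 140L, 1L, "onset", 20L,
    2L, "no_onset", 60L, 2L, "onset", 20L,
    3L, "no_onset", 50L, 3L, "onset", 30L,
    4L, "no_onset", 20L, 4L, "onset", 20L,
    5L, "no_onset", 30L, 5L, "onset", 50L,
    6L, "no_onset", 20L, 6L, "onset", 60L,
    8L, "onset", 20L
  )
)

#' Build an experimental design specification
#'
#' Three designs, all with display size 8:
#'
#' * `exp1` — mixed presentation, onsets in `{0, 1, 2, 4, 6, 8}`, 400
#'   experimental trials per participant; at each onset count `x` the target
#'   is an onset on exactly `x/8` of the trials.
#' * `exp2` — as `exp1` plus onset counts 3 and 5, 560 trials.
#' * `exp3` — target type blocked in two counterbalanced sessions; 32 trials
#'   per combination of target type and relevant-set size `r = 1..8`
#'   (512 total). For onset blocks the onset count is `x = r`; for no-onset
#'   blocks `x = 8 - r`.
#'
#' Each design also carries 20 practice trials, flagged and never analysed.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @return A `design_spec`: list with `experiment`, `n`, `cells` (tibble
#'   `x`, `target_type`, `n_trials`, plus `r` for `exp3`), `blocking`,
#'   `n_trials` (experimental trials per participant) and `practice`.
#' @export
build_design <- function(experiment = c("exp1", "exp2", "exp3")) {
  experiment <- match.arg(experiment)
  n <- 8L
  if (experiment == "exp3") {
    cells <- tidyr::expand_grid(
      r = 1:8, target_type = c("onset", "no_onset")
    )
    cells$x <- ifelse(cells$target_type == "onset", cells$r, n - cells$r)
    cells$n_trials <- 32L
    cells <- cells[, c("x", "r", "target_type", "n_trials")]
    blocking <- "blocked"
  } else {
    cells <- .design_cells[[experiment]]
    blocking <- "mixed"
  }
  structure(
    list(
      experiment = experiment, n = n, cells = cells, blocking = blocking,
      n_trials = sum(cells$n_trials), practice = 20L
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "<design_spec> %s: %s, n = %d, %d experimental + %d practice trials/participant\n",
    x$experiment, x$blocking, x$n, x$n_trials, x$practice
  ))
  print(x$cells, n = Inf)
  invisible(x)
}

#' Generative parameters for synthetic reaction times
#'
#' Trial RTs follow the linear comparison model
#' `RT = a * k + b * [target is onset] + d + noise`, where `k` is the number
#' of comparisons simulated at the generating capacity `c_true`. Defaults are
#' on the scale of the classic display-size-8 experiments: a search rate of
#' ~32 ms per comparison, a ~74 ms onset advantage (`b < 0`), an ~760 ms
#' base time, 150 ms trial noise, a 3.7% lapse rate and 1.1% RT outliers.
#' Between-participant spread of the linear coefficients uses truncated
#' normals (`a > 0`, `d > 0`).
#'
#' @param a Population search rate, ms per comparison (> 0).
#' @param b Population onset-advantage offset, ms (negative = advantage).
#' @param d Population base time, ms (> 0).
#' @param c_true Generating priority-set capacity.
#' @param sigma Trial-level RT noise SD, ms.
#' @param lapse Per-trial error probability in `[0, 1)`.
#' @param outlier_rate Fraction of trials replaced by RT outliers.
#' @param outlier_low,outlier_high Uniform ranges (ms) for low/high outliers.
#' @param a_sd,b_sd,d_sd Between-participant SDs of `a`, `b`, `d` (ms).
#' @param noise `"gaussian"` (additive, keeps OLS recovery unbiased) or
#'   `"lognormal"` (multiplicative on the trial mean, for robustness checks).
#' @param timeout_ms RTs above this are censored at it and flagged as errors.
#' @return A `generative_params` list.
#' @export
generative_params <- function(a = 31.6, b = -74.1, d = 764, c_true = 1L,
                              sigma = 150, lapse = 0.037,
                              outlier_rate = 0.011,
                              outlier_low = c(50, 195),
                              outlier_high = c(2050, 5000),
                              a_sd = 8, b_sd = 25, d_sd = 60,
                              noise = c("gaussian", "lognormal"),
                              timeout_ms = 10000) {
  noise <- match.arg(noise)
  if (a <= 0 || d <= 0) abort("generative parameters require a > 0 and d > 0")
  if (sigma < 0) abort("noise SD must be non-negative")
  if (lapse < 0 || lapse >= 1) abort("lapse must lie in [0, 1)")
  structure(
    list(
      a = a, b = b, d = d, c_true = as.integer(c_true), sigma = sigma,
      lapse = lapse, outlier_rate = outlier_rate,
      outlier_low = outlier_low, outlier_high = outlier_high,
      a_sd = a_sd, b_sd = b_sd, d_sd = d_sd, noise = noise,
      timeout_ms = timeout_ms
    ),
    class = "generative_params"
  )
}

# truncated-normal draw by rejection; at plausible SDs the truncation at 0 is
# far in the tail so this terminates immediately
.rtnorm_pos <- function(k, mean, sd) {
  out <- rnorm(k, mean, sd)
  while (any(bad <- out <= 0)) out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

#' Generate a synthetic trial table
#'
#' Simulates `n_participants` participants through a design. Each participant
#' draws individual `(a_i, b_i, d_i)` around the population values; each
#' trial draws its comparison count from the search simulator at `c_true` and
#' maps it to an RT with additive noise. With `sigma = 0` the generator takes
#' the noiseless limit: every trial's RT sits exactly on the model surface
#' (the expected comparison count replaces the sampled one), so fitting at
#' `c_true` recovers the generating coefficients to machine precision. Error (lapse) trials keep their RT
#' but are flagged incorrect; a small fraction of trials is replaced by RT
#' outliers outside the standard 200–2000 ms analysis window. Practice trials
#' are generated (block 0) and flagged. In the blocked design the two
#' target-type sessions alternate order across participants.
#'
#' @param design A [build_design()] specification.
#' @param params A [generative_params()] list.
#' @param n_participants Number of simulated participants (>= 1).
#' @param seed Integer seed; the full table is reproducible given it.
#' @return A tibble with columns `participant`, `block`, `experiment`, `n`,
#'   `x`, `target_type`, `target_pos`, `correct`, `rt_ms`, `practice`.
#' @export
generate_trials <- function(design, params = generative_params(),
                            n_participants, seed) {
  stopifnot(inherits(design, "design_spec"))
  if (n_participants < 1) abort("n_participants must be a positive integer")
  set.seed(seed)
  n <- design$n
  blocked <- design$blocking == "blocked"
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    a_i <- .rtnorm_pos(1, params$a, params$a_sd)
    b_i <- rnorm(1, params$b, params$b_sd)
    d_i <- .rtnorm_pos(1, params$d, params$d_sd)
    cells <- design$cells
    trials <- cells[rep(seq_len(nrow(cells)), cells$n_trials), ]
    trials$n_trials <- NULL
    if (blocked) {
      # counterbalance session order by participant parity
      first <- if (p %% 2 == 1) "onset" else "no_onset"
      s1 <- trials[trials$target_type == first, ]
      s2 <- trials[trials$target_type != first, ]
      s1 <- s1[sample.int(nrow(s1)), ]
      s2 <- s2[sample.int(nrow(s2)), ]
      trials <- rbind(s1, s2)
      trials$block <- rep(1:8, each = 64)[seq_len(nrow(trials))]
    } else {
      trials <- trials[sample.int(nrow(trials)), ]
      trials$block <- rep(seq_len(ceiling(nrow(trials) / 50)), each = 50)[
        seq_len(nrow(trials))
      ]
    }
    trials$practice <- FALSE
    # practice: drawn from the design cells, flagged, block 0
    pr_idx <- sample.int(nrow(trials), design$practice, replace = TRUE)
    practice <- trials[pr_idx, ]
    practice$block <- 0L
    practice$practice <- TRUE
    trials <- rbind(practice, trials)
    # comparison counts per cell, vectorised; in the noiseless limit
    # (sigma = 0) trials sit exactly on the model surface, so the expected
    # count stands in for the sampled one
    trials$comparisons <- NA_real_
    for (key in split(
      seq_len(nrow(trials)),
      paste(trials$x, trials$target_type)
    )) {
      xi <- trials$x[key[1]]
      ti <- trials$target_type[key[1]]
      if (blocked) {
        ri <- trials$r[key[1]]
        trials$comparisons[key] <- if (params$sigma == 0) {
          blocked_expected_comparisons(params$c_true, n, ri)
        } else {
          sample_comparisons(params$c_true, n, ri, "onset", length(key))
        }
      } else {
        trials$comparisons[key] <- if (params$sigma == 0) {
          expected_comparisons(params$c_true, n, xi, ti)
        } else {
          sample_comparisons(params$c_true, n, xi, ti, length(key))
        }
      }
    }
    mu <- a_i * trials$comparisons + b_i * (trials$target_type == "onset") + d_i
    rt <- switch(params$noise,
      gaussian = mu + rnorm(nrow(trials), 0, params$sigma),
      lognormal = mu * exp(rnorm(nrow(trials), 0, params$sigma / params$d))
    )
    # outlier contamination: replace with draws outside the analysis window
    is_out <- runif(nrow(trials)) < params$outlier_rate
    n_out <- sum(is_out)
    if (n_out > 0) {
      low <- runif(n_out) < 0.5
      rt[is_out] <- ifelse(
        low,
        runif(n_out, params$outlier_low[1], params$outlier_low[2]),
        runif(n_out, params$outlier_high[1], params$outlier_high[2])
      )
    }
    rt <- pmax(rt, 1)
    correct <- runif(nrow(trials)) >= params$lapse
    # response timeouts are censored and count as errors
    timed_out <- rt > params$timeout_ms
    rt[timed_out] <- params$timeout_ms
    correct[timed_out] <- FALSE
    # item positions are exchangeable, so the target lands uniformly on the
    # display positions regardless of type
    target_pos <- sample.int(n, nrow(trials), replace = TRUE)
    out[[p]] <- tibble::tibble(
      participant = p,
      block = trials$block,
      experiment = design$experiment,
      n = n,
      x = trials$x,
      target_type = trials$target_type,
      target_pos = target_pos,
      correct = correct,
      rt_ms = rt,
      practice = trials$practice
    )
  }
  dplyr::bind_rows(out)
}

#' Empirical target-position distribution
#'
#' Tabulates where the target appeared across trials; in all designs the
#' target is placed uniformly over the display positions.
#'
#' @param trials A trial table from [generate_trials()] or [read_trials()].
#' @return A tibble with `target_pos`, `count`, `freq`.
#' @export
target_position_distribution <- function(trials) {
  if (!nrow(trials)) abort("trials must be non-empty")
  out <- dplyr::count(trials, .data$target_pos, name = "count")
  out$freq <- out$count / sum(out$count)
  out
}

#' Read and write trial tables
#'
#' Trial tables round-trip as CSV with the header
#' `participant,block,experiment,n,x,target_type,target_pos,correct,rt_ms,practice`.
#' The same schema is accepted for real data.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_integer(), block = readr::col_integer(),
    experiment = readr::col_character(), n = readr::col_integer(),
    x = readr::col_integer(), target_type = readr::col_character(),
    target_pos = readr::col_integer(), correct = readr::col_logical(),
    rt_ms = readr::col_double(), practice = readr::col_logical()
  ))
}

#' Save and replay a generation configuration
#'
#' A written configuration (design id, all generative parameters, participant
#' count, seed) is sufficient to regenerate a dataset bit-for-bit.
#'
#' @param experiment Design id passed to [build_design()].
#' @param params A [generative_params()] list.
#' @param n_participants,seed As in [generate_trials()].
#' @param path JSON file path.
#' @export
write_generation_config <- function(experiment, params, n_participants, seed,
                                    path) {
  cfg <- list(
    experiment = experiment,
    params = unclass(params),
    n_participants = n_participants,
    seed = seed,
    package_version = as.character(utils::packageVersion("prioritytag"))
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generation_config
#' @export
generate_from_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(
    generative_params,
    cfg$params[setdiff(names(cfg$params), character(0))]
  )
  generate_trials(
    build_design(cfg$experiment), params,
    n_participants = cfg$n_participants, seed = cfg$seed
  )
}
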