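# Stochastic and exhaustive oracles for the closed-form model. The simulator
# realises the generative story literally (tag a random subset, permute, scan);
# the enumerator sums over subset choices and scan positions with exact
# combinatorial weights. Neither touches the closed-form equations.

#' Simulate one serial self-terminating search trial
#'
#' Items `1..x` are the onsets, `x+1..n` the no-onset items. The target is
#' drawn uniformly among items of its type; a uniformly random subset of
#' `min(c, x)` onsets is tagged; a random permutation of the tagged set is
#' scanned first, then a random permutation of the remainder; the trial ends
#' when the target is inspected. Uses the current RNG state — seed with
#' [set.seed()] for reproducibility.
#'
#' @inheritParams expected_comparisons
#' @return A list with `comparisons` (1-based inspection position of the
#'   target), `priority_set` (tagged item indices) and `target_in_priority`.
#' @export
simulate_search_trial <- function(c, n, x, target_type) {
  .check_capacity(c)
  validate_condition(n, x, target_type)
  m <- min(c, x, n)
  onsets <- seq_len(x)
  pool <- if (target_type == "onset") onsets else setdiff(seq_len(n), onsets)
  target <- pool[sample.int(length(pool), 1L)]
  priority <- if (m > 0) onsets[sample.int(x, m)] else integer(0)
  rest <- setdiff(seq_len(n), priority)
  order <- c(
    priority[sample.int(length(priority))],
    rest[sample.int(length(rest))]
  )
  list(
    comparisons = match(target, order),
    priority_set = sort(priority),
    target_in_priority = target %in% priority
  )
}

#' @rdname simulate_search_trial
#' @param r Relevant-set size for a blocked trial; the relevant items stand in
#'   for the onsets and the target is always among them.
#' @export
simulate_blocked_trial <- function(c, n, r) {
  simulate_search_trial(c, n, x = r, target_type = "onset")
}

#' Monte-Carlo estimate of expected comparisons
#'
#' Repeatedly runs [simulate_search_trial()] and returns the sample mean and
#' its standard error. Serves as a stochastic cross-check of the closed forms.
#'
#' @inheritParams simulate_search_trial
#' @param trials Number of independent trials (>= 1).
#' @param seed Integer seed; the trial stream is fully reproducible given it.
#' @return A list with `mean`, `se` (`NA` for a single trial), and `trials`.
#' @export
mc_expected_comparisons <- function(c, n, x, target_type, trials = 1e5,
                                    seed = NULL) {
  stopifnot(trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- vapply(
    seq_len(trials),
    function(i) simulate_search_trial(c, n, x, target_type)$comparisons,
    numeric(1)
  )
  list(
    mean = mean(k),
    se = if (trials > 1) sd(k) / sqrt(trials) else NA_real_,
    trials = trials
  )
}

#' Exact expected comparisons by exhaustive enumeration
#'
#' Independent brute-force oracle: sums over every target identity within its
#' type class, every tagged subset of onsets, and every scan position of the
#' target given its subset membership, with uniform weights. Returns the
#' expectation as an exact reduced fraction. Restricted to `n <= 10`.
#'
#' @inheritParams simulate_search_trial
#' @return Named numeric `c(num, den)`, the reduced exact expectation.
#' @export
enumerate_expected_comparisons <- function(c, n, x, target_type) {
  p <- enumerate_comparison_distribution(c, n, x, target_type)
  # E[K] = sum k * P(K = k); common denominator den * n! not needed since the
  # probabilities already share attr "den"
  num <- sum(seq_len(n) * attr(p, "num"))
  frac(num, attr(p, "den"))
}

#' @rdname enumerate_expected_comparisons
#' @return For `enumerate_comparison_distribution()`: a numeric vector of
#'   length `n`, `P(comparisons = k)`, with exact integer numerators in
#'   `attr(, "num")` over the common denominator `attr(, "den")`.
#' @export
enumerate_comparison_distribution <- function(c, n, x, target_type) {
  .check_capacity(c)
  validate_condition(n, x, target_type)
  if (n > 10) {
    abort(sprintf("enumeration supports n <= 10 (got n = %d)", n))
  }
  m <- min(c, x, n)
  onsets <- seq_len(x)
  pool <- if (target_type == "onset") onsets else setdiff(seq_len(n), onsets)
  subsets <- if (m == 0) {
    matrix(integer(0), nrow = 0, ncol = 1)
  } else {
    combn(x, m)
  }
  nsub <- max(ncol(subsets), 1L)
  # common denominator: subsets * target identities * scan slots; scan slots
  # differ between the two stages, so use m * (n - m) (guarding empty stages)
  slot_den <- max(m, 1L) * max(n - m, 1L)
  den <- nsub * length(pool) * slot_den
  num <- numeric(n)
  for (s in seq_len(nsub)) {
    tagged <- if (m > 0) subsets[, s] else integer(0)
    for (target in pool) {
      if (target %in% tagged) {
        # uniform permutation of the tagged set: each of the m first-stage
        # slots is equally likely
        w <- slot_den / m
        num[seq_len(m)] <- num[seq_len(m)] + w
      } else {
        w <- slot_den / (n - m)
        num[m + seq_len(n - m)] <- num[m + seq_len(n - m)] + w
      }
    }
  }
  p <- num / den
  attr(p, "num") <- num
  attr(p, "den") <- den
  p
}

#' Draw comparison counts from the exact trial distribution
#'
#' Vectorised sampler for the per-trial number of comparisons, equivalent in
#' distribution to [simulate_search_trial()] (the tagged subset is uniform, so
#' the target is tagged with probability `min(c, x) / x` and its scan position
#' is uniform within its stage). Used by the synthetic-data generator where
#' trial-identity detail is not needed; tested against the enumeration
#' distribution.
#'
#' @inheritParams simulate_search_trial
#' @param size Number of draws.
#' @return Integer vector of `size` comparison counts in `1..n`.
#' @export
sample_comparisons <- function(c, n, x, target_type, size) {
  .check_capacity(c)
  validate_condition(n, x, target_type)
  if (size == 0) return(integer(0))
  m <- min(c, x, n)
  if (target_type == "onset") {
    tagged <- if (m == 0) rep(FALSE, size) else runif(size) < m / x
  } else {
    tagged <- rep(FALSE, size)
  }
  k <- integer(size)
  n1 <- sum(tagged)
  if (n1 > 0) k[tagged] <- sample.int(m, n1, replace = TRUE)
  if (n1 < size) k[!tagged] <- m + sample.int(n - m, size - n1, replace = TRUE)
  k
}

#' Dump simulated trials to CSV
#'
#' Runs `trials` independent simulated searches of one condition and writes
#' the per-trial outcomes as `trial,c,n,x,target_type,comparisons,target_in_priority`.
#'
#' @inheritParams mc_expected_comparisons
#' @param path Output CSV path.
#' @return The tibble of outcomes, invisibly.
#' @export
write_trial_outcomes <- function(c, n, x, target_type, trials, path,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(trials), function(i) {
    tr <- simulate_search_trial(c, n, x, target_type)
    tibble::tibble(
      trial = i, c = c, n = n, x = x, target_type = target_type,
      comparisons = tr$comparisons, target_in_priority = tr$target_in_priority
    )
  })
  out <- dplyr::bind_rows(out)
  readr::write_csv(out, path)
  invisible(out)
}
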