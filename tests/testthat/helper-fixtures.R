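# Shared fixtures: deterministic generative settings and small designs.

noiseless_params <- function(c_true = 1L, a = 30, b = -70, d = 760) {
  generative_params(
    a = a, b = b, d = d, c_true = c_true, sigma = 0, lapse = 0,
    outlier_rate = 0, a_sd = 0, b_sd = 0, d_sd = 0
  )
}

# every valid (x, target_type) cell for a display of n items
all_valid_cells <- function(n) {
  out <- expand.grid(
    x = 0:n, target_type = c("onset", "no_onset"),
    stringsAsFactors = FALSE
  )
  out[!(out$target_type == "onset" & out$x < 1) &
    !(out$target_type == "no_onset" & out$x > n - 1), ]
}
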