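# Small in-code fixtures shared across test files.

vol_from <- function(values, dim3, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  volume3d(array(values, dim3), spacing = spacing, origin = origin)
}

full_mask <- function(dim3) array(TRUE, dim3)

# random small volume + mask pair for texture property tests
random_texture_case <- function(max_side = 4, n_levels = 4, bin_size = 1) {
  d <- sample(2:max_side, 3, replace = TRUE)
  vals <- sample(seq_len(n_levels), prod(d), replace = TRUE) * bin_size -
    bin_size / 2
  m <- array(runif(prod(d)) < 0.7, d)
  if (sum(m) < 2) m[sample(prod(d), 2)] <- TRUE
  list(vol = vol_from(vals, d), mask = m)
}

# tiny survival cohort generator for evaluation tests
sim_surv <- function(n, beta = 0, x = stats::rnorm(n), cens_rate = 0.1,
                     base_rate = 0.15) {
  t_ev <- stats::rexp(n, base_rate * exp(beta * x))
  t_c <- stats::rexp(n, cens_rate)
  data.frame(time = pmax(pmin(t_ev, t_c), 1e-3),
             event = as.integer(t_ev <= t_c), x = x)
}

light_config <- function(seed = 1L, max_iter = 80L, ...) {
  network_config(h1_units = 8L, h2_units = 4L, n_trees = 60L,
                 min_node = 8L, max_iter = max_iter, seed = seed, ...)
}
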