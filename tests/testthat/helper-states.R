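# Shared fixtures: small configs, random states, random stable configs.

standard_ic <- function(amplitude = 1) {
  binding_state(p = c(amplitude, 0), q = c(amplitude, 0))
}

random_state <- function(config, scale = 1) {
  d <- 2 * config$n + 2 * config$m
  stats::rnorm(d, sd = scale)
}

# random config from the oscillatory (non-growing) regime: 1-2 processes
# per block and relation scales in [-1, 0); larger blocks or |scale| > 1
# put relation-matrix eigenvalues past the damping and the modes grow
random_stable_config <- function() {
  scheme <- sample(c("direct", "difference", "none"), 1)
  if (scheme == "none") {
    binding_config(n = sample(1:2, 1), m = sample(1:2, 1),
                   epsilon = stats::runif(1, -1, -0.1),
                   alpha = stats::runif(1, -1, -0.1),
                   omega = 0, scheme = "none")
  } else {
    binding_config(epsilon = stats::runif(1, -1, -0.1),
                   alpha = stats::runif(1, -1, -0.1),
                   omega = stats::runif(1, 0, 1), scheme = scheme)
  }
}

# Independent closed-form oracle: recover the generator from the right-hand
# side by linearity (columns = rhs of basis vectors), then propagate with
# the matrix exponential. Deliberately does not use system_matrix() or the
# integrator it validates.
closed_form_trajectory_ref <- function(config, initial, times) {
  d <- 2 * config$n + 2 * config$m
  M <- vapply(seq_len(d), function(j) {
    unname(deterministic_rhs(as.numeric(seq_len(d) == j), config))
  }, numeric(d))
  out <- matrix(NA_real_, length(times), d)
  dt <- diff(times)[1]
  P <- as.matrix(Matrix::expm(M * dt))
  s <- as.numeric(initial)
  stopifnot(times[1] == 0)
  out[1, ] <- s
  for (k in seq_along(times)[-1]) {
    s <- drop(P %*% s)
    out[k, ] <- s
  }
  out
}
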