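# Deterministic core: relation matrices, right-hand side, linear-system
# oracle, RK4 integrator.

test_that("distance_matrix reproduces the squared-distance pattern", {
  eps <- -1.3
  expect_equal(distance_matrix(2, eps), matrix(c(0, eps, eps, 0), 2, 2))
  expect_equal(distance_matrix(3, eps),
               matrix(c(0, eps, 4 * eps,
                        eps, 0, eps,
                        4 * eps, eps, 0), 3, 3, byrow = TRUE))
  expect_equal(distance_matrix(1, 5.0), matrix(0, 1, 1))
  expect_error(distance_matrix(0, 1), class = "bindsim_invalid_parameter")
  expect_error(distance_matrix(2.5, 1), class = "bindsim_invalid_parameter")
})

test_that("distance matrices are hollow and symmetric for all sizes", {
  for (size in c(1:5, 10, 25, 50)) {
    A <- distance_matrix(size, 0.7)
    expect_equal(diag(A), rep(0, size))
    expect_identical(A, t(A))
  }
})

test_that("config validation rejects bad parameters", {
  expect_error(binding_config(n = 0), class = "bindsim_invalid_parameter")
  expect_error(binding_config(omega = -0.1), class = "bindsim_invalid_parameter")
  expect_error(binding_config(n = 3, scheme = "direct"),
               class = "bindsim_invalid_parameter")
  expect_silent(binding_config(n = 3, m = 5, scheme = "none"))
})

test_that("coupled 2+2 right-hand side matches direct substitution", {
  cfg <- binding_config(epsilon = -1, alpha = -1, omega = 1, scheme = "direct")
  s <- binding_state(p = c(1, 0), q = c(1, 0))
  expect_equal(unname(deterministic_rhs(s, cfg)),
               c(0, -1, 1, 0, -2, -1, 1, 0))
  # origin is a fixed point
  expect_equal(unname(deterministic_rhs(rep(0, 8), cfg)), rep(0, 8))
  expect_error(deterministic_rhs(rep(0, 7), cfg), class = "bindsim_invalid_state")
})

test_that("blocks decouple at omega = 0", {
  set.seed(11)
  cfg0 <- binding_config(omega = 0, scheme = "direct")
  s <- random_state(cfg0)
  d1 <- deterministic_rhs(s, cfg0)
  # changing the q block must not affect the p block derivative
  s2 <- s
  s2[5:8] <- rnorm(4)
  d2 <- deterministic_rhs(s2, cfg0)
  expect_equal(d1[1:4], d2[1:4])
  # and scheme "none" agrees with omega 0
  expect_equal(unname(d1),
               unname(deterministic_rhs(s, binding_config(scheme = "none"))))
})

test_that("the right-hand side is linear in the state", {
  set.seed(21)
  for (rep in 1:5) {
    cfg <- random_stable_config()
    s1 <- random_state(cfg)
    s2 <- random_state(cfg)
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(deterministic_rhs(a * s1 + b * s2, cfg),
                 a * deterministic_rhs(s1, cfg) + b * deterministic_rhs(s2, cfg))
  }
})

test_that("system matrix reproduces the right-hand side exactly", {
  set.seed(31)
  for (rep in 1:8) {
    cfg <- random_stable_config()
    M <- system_matrix(cfg)$matrix
    s <- random_state(cfg)
    expect_equal(drop(M %*% s), unname(deterministic_rhs(s, cfg)),
                 tolerance = 1e-12)
  }
})

test_that("uncoupled mutual-inhibition block has the known mode structure", {
  # p/x block alone (epsilon = -1): eigenvalues -1 (double) and +/- i;
  # the surviving oscillation has angular frequency 1, period 2*pi
  cfg <- binding_config(n = 2, m = 1, epsilon = -1, omega = 0, scheme = "none")
  M <- system_matrix(cfg)$matrix[1:4, 1:4]
  ev <- sort(eigen(M, only.values = TRUE)$values)
  # the -1 pair is defective, so its numerical eigenvalues split at ~sqrt(eps)
  expect_equal(sort(Re(ev)), c(-1, -1, 0, 0), tolerance = 1e-6)
  expect_equal(sort(abs(Im(ev))), c(0, 0, 1, 1), tolerance = 1e-6)
  modes <- system_matrix(binding_config(omega = 0))
  expect_equal(max(modes$angular_frequencies), 1, tolerance = 1e-8)
  expect_equal(glance(modes)$dominant_period, 2 * pi, tolerance = 1e-6)
})

test_that("mutual inhibition keeps all modes non-growing across omega", {
  for (scheme in c("direct", "difference")) {
    for (w in seq(0, 1, by = 0.25)) {
      modes <- system_matrix(binding_config(omega = w, scheme = scheme))
      expect_lte(max(Re(modes$eigenvalues)), 1e-10)
    }
  }
})

test_that("dominant eigenfrequency strictly increases with binding strength", {
  freqs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(w) {
    max(system_matrix(binding_config(omega = w))$angular_frequencies)
  }, numeric(1))
  expect_true(all(diff(freqs) > 0))
})

test_that("closed-form solution is exact at t = 0 and obeys the semigroup law", {
  cfg <- binding_config(omega = 0.6)
  s0 <- standard_ic()
  expect_equal(closed_form_solution(cfg, s0, 0), binding_state(p = c(1, 0), q = c(1, 0)))
  one_step <- closed_form_solution(cfg, s0, 7.5)
  two_step <- closed_form_solution(cfg, closed_form_solution(cfg, s0, 3), 4.5)
  expect_equal(one_step, two_step, tolerance = 1e-10)
})

test_that("mutually inhibiting pair settles into anti-phase oscillation", {
  # after the symmetric mode (eigenvalue -1, double) decays, p1 = -p2:
  # the relation constraint p_i = eps * p_j with eps = -1
  cfg <- binding_config(omega = 0, scheme = "none")
  s0 <- binding_state(p = c(1, 0), q = c(0, 0))
  tr <- simulate_deterministic(cfg, s0, t_end = 60, dt_out = 0.1)
  late <- tr[tr$time >= 20, ]
  amp <- max(abs(late$p1))
  expect_gt(amp, 0.1)
  expect_lte(max(abs(late$p1 + late$p2)) / amp, 1e-3)
})

test_that("RK4 integration matches the matrix-exponential oracle", {
  set.seed(41)
  for (rep in 1:5) {
    cfg <- random_stable_config()
    s0 <- random_state(cfg)
    tr <- simulate_deterministic(cfg, s0, t_end = 100, dt_out = 1)
    oracle <- closed_form_trajectory_ref(cfg, s0, tr$time)
    expect_lt(max(abs(as.matrix(tr[, -1]) - oracle)), 1e-6)
  }
})

test_that("omega = 0 trajectory of the p block ignores the q block", {
  s_with <- binding_state(p = c(1, 0), q = c(5, -2))
  s_without <- binding_state(p = c(1, 0), q = c(0, 0))
  cfg <- binding_config(omega = 0)
  t1 <- simulate_deterministic(cfg, s_with, t_end = 30, dt_out = 0.5)
  t2 <- simulate_deterministic(cfg, s_without, t_end = 30, dt_out = 0.5)
  expect_equal(t1[c("p1", "p2", "x1", "x2")], t2[c("p1", "p2", "x1", "x2")])
})

test_that("tidy and glance views of the mode decomposition are consistent", {
  modes <- system_matrix(binding_config(omega = 0.5))
  td <- tidy(modes)
  expect_equal(nrow(td), 8)
  # conjugate pairing: imaginary parts sum to zero
  expect_equal(sum(td$imaginary), 0, tolerance = 1e-10)
  g <- glance(modes)
  expect_equal(g$dominant_angular_frequency,
               max(modes$angular_frequencies))
  expect_equal(g$dominant_frequency * 2 * pi, g$dominant_angular_frequency)
})
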