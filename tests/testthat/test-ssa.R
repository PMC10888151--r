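# Stochastic engine: channel decomposition, direct-method primitives,
# full runs and their distributional properties.

test_that("term-wise decomposition yields the expected channel counts", {
  expect_equal(nrow(reaction_channels(binding_config(omega = 0.5))), 20)
  expect_equal(nrow(reaction_channels(binding_config(omega = 0.5,
                                                     scheme = "difference"))), 20)
  # omega = 0 keeps the coupling channels, with zero propensity everywhere
  ch0 <- reaction_channels(binding_config(omega = 0))
  expect_equal(nrow(ch0), 20)
  coefs <- attr(ch0, "coefficients")
  coupling <- grepl("omega", ch0$term)
  expect_equal(sum(coupling), 4)
  expect_true(all(coefs[coupling, ] == 0))
  # uncoupled general systems: (n-1) + 2 channels per process, 1 per auxiliary
  ch <- reaction_channels(binding_config(n = 3, m = 4, scheme = "none"))
  expect_equal(nrow(ch), 3 * 4 + 3 + 4 * 5 + 4)
})

test_that("channel drift reproduces the deterministic right-hand side", {
  set.seed(101)
  for (cfg in list(binding_config(omega = 0.7),
                   binding_config(omega = 0.3, scheme = "difference"),
                   binding_config(n = 3, m = 2, epsilon = -0.5, scheme = "none"))) {
    ch <- reaction_channels(cfg)
    for (rep in 1:100) {
      s <- round(random_state(cfg, scale = 50))
      expect_equal(bindsim:::channel_drift(ch, s),
                   deterministic_rhs(s, cfg), tolerance = 1e-12)
    }
  }
})

test_that("waiting-time draw inverts the exponential law", {
  expect_equal(draw_waiting_time(2, exp(-2)), 1.0)
  expect_equal(draw_waiting_time(5, 1), 0)
  expect_error(draw_waiting_time(0, 0.5), class = "bindsim_absorbing_state")
  expect_error(draw_waiting_time(1, 0), class = "bindsim_invalid_parameter")
  expect_error(draw_waiting_time(1, 1.5), class = "bindsim_invalid_parameter")
})

test_that("waiting times are exponential with the total-propensity rate", {
  set.seed(7)
  a <- 3.7
  tau <- draw_waiting_time(a, runif(1e5))
  ks <- suppressWarnings(stats::ks.test(tau, stats::pexp, rate = a))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(tau), 1 / a, tolerance = 0.02)
})

test_that("channel selection follows the cumulative-fraction rule", {
  expect_equal(select_channel(c(1, 3), 0.2), 1)
  expect_equal(select_channel(c(1, 3), 0.25), 2)   # half-open boundary
  expect_equal(select_channel(c(1, 3), 0), 1)
  expect_equal(select_channel(c(0, 0, 2), 0.99), 3)
  expect_error(select_channel(c(0, 0), 0.5), class = "bindsim_absorbing_state")
  expect_error(select_channel(c(1, -1), 0.5), class = "bindsim_invalid_parameter")
})

test_that("channel selection frequencies are proportional to propensities", {
  set.seed(13)
  picks <- vapply(runif(1e5), function(r) select_channel(c(1, 3), r), numeric(1))
  # 3-sigma binomial band around 0.25
  p_hat <- mean(picks == 1)
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
  expect_gt(stats::chisq.test(table(picks), p = c(0.25, 0.75))$p.value, 0.01)
})

test_that("runs are bit-reproducible given a seed and integer-valued", {
  cfg <- binding_config(omega = 0.4)
  s0 <- binding_state(p = c(50, 0), q = c(50, 0))
  t1 <- gillespie_run(cfg, s0, t_end = 40, samples = 128, seed = 99)
  t2 <- gillespie_run(cfg, s0, t_end = 40, samples = 128, seed = 99)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- gillespie_run(cfg, s0, t_end = 40, samples = 128, seed = 100)
  expect_false(identical(t1$p1, t3$p1))
  vals <- as.matrix(t1[, -1])
  expect_true(all(vals == round(vals)))
  expect_error(gillespie_run(cfg, binding_state(p = c(0.5, 0), q = c(1, 0)),
                             t_end = 1, samples = 4, seed = 1),
               class = "bindsim_invalid_state")
})

test_that("the zero state is absorbing and flagged", {
  cfg <- binding_config(omega = 0.4)
  expect_warning(
    tr <- gillespie_run(cfg, rep(0, 8), t_end = 5, samples = 16, seed = 1),
    class = "bindsim_absorbing_state_warning"
  )
  expect_true(attr(tr, "truncated"))
  expect_true(all(as.matrix(tr[, -1]) == 0))
})

test_that("the event cap raises an explicit error", {
  cfg <- binding_config(omega = 0.4)
  s0 <- binding_state(p = c(1000, 0), q = c(1000, 0))
  expect_error(gillespie_run(cfg, s0, t_end = 930, samples = 64, seed = 1,
                             max_events = 1000),
               class = "bindsim_event_cap")
})

test_that("event-stride recording returns event-timed samples", {
  cfg <- binding_config(omega = 0.4)
  s0 <- binding_state(p = c(100, 0), q = c(100, 0))
  tr <- gillespie_run(cfg, s0, t_end = 100, samples = 256, seed = 5,
                      record = "events", every = 200)
  expect_equal(nrow(tr), 256)
  expect_true(all(diff(tr$time) > 0))
  expect_identical(attr(tr, "sampling"), "events")
  expect_identical(attr(tr, "every"), 200L)
  # spacing fluctuates with the event rate: not a uniform grid
  expect_gt(sd(diff(tr$time)) / mean(diff(tr$time)), 0.01)
  # stride auto-calibration targets the nominal span
  tr2 <- gillespie_run(cfg, s0, t_end = 100, samples = 256, seed = 5,
                       record = "events")
  expect_gt(max(tr2$time), 50)
  expect_lt(max(tr2$time), 200)
})

test_that("the ensemble mean follows the deterministic solution", {
  # mean-field limit: averaging many unit-step runs at amplitude 1000
  # tracks exp(M t) S0 within a few percent of the amplitude
  cfg <- binding_config(omega = 0.5)
  s0 <- binding_state(p = c(1000, 0), q = c(1000, 0))
  n_runs <- 200
  acc <- matrix(0, 64, 8)
  for (i in seq_len(n_runs)) {
    tr <- gillespie_run(cfg, s0, t_end = 20, samples = 64, seed = 5000 + i)
    acc <- acc + as.matrix(tr[, -1])
  }
  oracle <- closed_form_trajectory_ref(cfg, s0, tr$time)
  expect_lt(max(abs(acc / n_runs - oracle)), 0.05 * 1000)
})

test_that("relative fluctuations shrink with amplitude (demographic noise)", {
  cfg <- binding_config(omega = 0.5)
  rel_noise <- function(A) {
    s0 <- binding_state(p = c(A, 0), q = c(A, 0))
    tr <- gillespie_run(cfg, s0, t_end = 50, samples = 256, seed = 17)
    oracle <- closed_form_trajectory_ref(cfg, s0, tr$time)
    sd(tr$p1 - oracle[, 1]) / A
  }
  expect_lt(rel_noise(1000), rel_noise(100))
})
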