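# Exact stochastic version of the model (Gillespie direct method).
#
# The ODE system is decomposed term-wise: every signed additive term of
# every equation becomes one unit-step event channel whose propensity is
# the absolute value of the term and whose step is +/-1 on the target
# component, signed like the term. Summing step * propensity over channels
# recovers the deterministic right-hand side identically (mean-field
# consistency), which is the decisive correctness property of the
# decomposition. States are abstract process amplitudes oscillating around
# zero, so negative values are legal; propensities stay nonnegative through
# the absolute value.

#' Term-wise event channels of the stochastic model
#'
#' Enumerates one unit-step channel per additive term of each equation.
#' Channel `k` has a linear term `c_k . S`, propensity `|c_k . S|`, and step
#' `sign(c_k . S)` on its target component. For the coupled 2+2 system this
#' yields 20 channels (4 per process equation, 1 per auxiliary equation);
#' the 4 coupling channels carry weight `omega` and have zero propensity
#' everywhere when `omega = 0`.
#'
#' @param config A [binding_config()].
#' @return A tibble with one row per channel: `channel`, `target` (state
#'   component name), `target_index`, `term` (human-readable formula), and
#'   a `coefficients` attribute holding the channels-by-state coefficient
#'   matrix used by the simulator.
#' @examples
#' reaction_channels(binding_config(omega = 0.5))
#' @export
reaction_channels <- function(config) {
  n <- config$n; m <- config$m
  d <- 2L * n + 2L * m
  nms <- state_names(n, m)
  ip <- 1:n; ix <- (n + 1):(2 * n)
  iq <- (2 * n + 1):(2 * n + m); iz <- (2 * n + m + 1):d
  rows <- list()
  add <- function(target, coef, label) {
    rows[[length(rows) + 1L]] <<- list(target = target, coef = coef, label = label)
  }
  cvec <- function(pairs) {
    v <- numeric(d)
    for (pr in pairs) v[pr[[1]]] <- v[pr[[1]]] + pr[[2]]
    v
  }
  A <- distance_matrix(n, config$epsilon)
  B <- distance_matrix(m, config$alpha)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-i]) {
      add(ip[i], cvec(list(list(ip[j], A[i, j]))),
          sprintf("%g*%s", A[i, j], nms[ip[j]]))
    }
    add(ip[i], cvec(list(list(ip[i], -1))), sprintf("-%s", nms[ip[i]]))
    add(ip[i], cvec(list(list(ix[i], -1))), sprintf("-%s", nms[ix[i]]))
  }
  for (i in seq_len(m)) {
    for (j in seq_len(m)[-i]) {
      add(iq[i], cvec(list(list(iq[j], B[i, j]))),
          sprintf("%g*%s", B[i, j], nms[iq[j]]))
    }
    add(iq[i], cvec(list(list(iq[i], -1))), sprintf("-%s", nms[iq[i]]))
    add(iq[i], cvec(list(list(iz[i], -1))), sprintf("-%s", nms[iz[i]]))
  }
  if (config$scheme != "none") {
    cm <- coupling_matrices(config$scheme)
    w <- config$omega
    for (i in 1:2) {
      co <- cvec(list(list(iq[1], w * cm$F[i, 1]), list(iq[2], w * cm$F[i, 2])))
      add(ip[i], co, sprintf("omega*f%d(q)", i))
      co <- cvec(list(list(ip[1], w * cm$G[i, 1]), list(ip[2], w * cm$G[i, 2])))
      add(iq[i], co, sprintf("omega*g%d(p)", i))
    }
  }
  for (i in seq_len(n)) add(ix[i], cvec(list(list(ip[i], 1))), nms[ip[i]])
  for (i in seq_len(m)) add(iz[i], cvec(list(list(iq[i], 1))), nms[iq[i]])

  coefs <- do.call(rbind, lapply(rows, `[[`, "coef"))
  colnames(coefs) <- nms
  out <- tibble::tibble(
    channel = seq_along(rows),
    target = nms[vapply(rows, `[[`, integer(1), "target")],
    target_index = vapply(rows, `[[`, integer(1), "target"),
    term = vapply(rows, `[[`, character(1), "label")
  )
  attr(out, "coefficients") <- coefs
  out
}

# Drift of the channel set: sum_k step_k(S) * a_k(S) = sum_k c_k . S,
# accumulated on the targets. Used by the mean-field consistency tests.
channel_drift <- function(channels, state) {
  coefs <- attr(channels, "coefficients")
  terms <- drop(coefs %*% as.numeric(state))
  drift <- numeric(ncol(coefs))
  for (k in seq_along(terms)) {
    tgt <- channels$target_index[k]
    drift[tgt] <- drift[tgt] + terms[k]
  }
  setNames(drift, colnames(coefs))
}

#' Exponential waiting time to the next event
#'
#' Inverse-transform draw of the Gillespie waiting time:
#' `tau = -log(r1) / total_propensity` with `r1` uniform on (0, 1].
#'
#' @param total_propensity Sum of all channel propensities (> 0).
#' @param r1 Uniform random number in (0, 1].
#' @return The waiting time `tau`.
#' @examples
#' draw_waiting_time(2, exp(-2))  # exactly 1
#' @export
draw_waiting_time <- function(total_propensity, r1) {
  if (!is.numeric(total_propensity) || total_propensity <= 0) {
    abort("`total_propensity` must be > 0 (zero total propensity is an absorbing state).",
          class = "bindsim_absorbing_state")
  }
  if (!is.numeric(r1) || any(r1 <= 0) || any(r1 > 1)) {
    abort("`r1` must lie in (0, 1].", class = "bindsim_invalid_parameter")
  }
  -log(r1) / total_propensity
}

#' Select the next event channel
#'
#' Direct-method selection: channel `i` fires if `r2` falls in the half-open
#' interval of cumulative propensity fractions
#' `[cum(i-1)/total, cum(i)/total)`.
#'
#' @param propensities Nonnegative channel propensities, at least one > 0.
#' @param r2 Uniform random number in \\[0, 1).
#' @return The selected channel index.
#' @examples
#' select_channel(c(1, 3), 0.2)   # 1
#' select_channel(c(1, 3), 0.25)  # 2
#' @export
select_channel <- function(propensities, r2) {
  if (any(propensities < 0)) {
    abort("Propensities must be nonnegative.", class = "bindsim_invalid_parameter")
  }
  total <- sum(propensities)
  if (total <= 0) {
    abort("All propensities are zero (absorbing state).",
          class = "bindsim_absorbing_state")
  }
  if (!is.numeric(r2) || r2 < 0 || r2 >= 1) {
    abort("`r2` must lie in [0, 1).", class = "bindsim_invalid_parameter")
  }
  thr <- r2 * total
  cum <- cumsum(propensities)
  which(thr < cum)[1]
}

#' Gillespie stochastic simulation of the bound system
#'
#' Runs the direct method over the term-wise channels of
#' [reaction_channels()]: compute propensities, draw an exponential waiting
#' time, select a channel proportionally to propensity, apply its unit step,
#' and repeat. Runs are bit-reproducible given the same seed (R's
#' Mersenne-Twister generator).
#'
#' Two recording conventions are supported:
#'
#' * `record = "grid"`: the state is recorded on a uniform grid of
#'   `samples` points (`t_j = j * t_end / samples`) with zero-order hold
#'   (each grid time takes the state after the last event at or before it)
#'   and the run stops at `t_end`.
#' * `record = "events"`: the state is recorded after every `every`-th
#'   event, together with the event time, until `samples` records are
#'   taken; the elapsed time then varies from run to run (it is the sum of
#'   `samples * every` exponential waiting times). When `every` is `NULL`
#'   it is calibrated from a short pilot run of length `pilot_t` so that
#'   the recorded span is close to `t_end`. This reproduces the workflow of
#'   stochastic simulators that store every Nth step: sample spacing then
#'   tracks the fluctuating event rate, which matters for downstream
#'   spectral analysis (see the package vignette).
#'
#' If the total propensity reaches zero the state can never change again
#' (absorbing state): the remaining grid is filled with the frozen state
#' (`"grid"`) or the trajectory is cut short (`"events"`), and the result
#' is flagged truncated with a warning. Exceeding `max_events` is an error.
#'
#' @inheritParams closed_form_solution
#' @param initial Initial state; must be integer-valued (unit steps preserve
#'   integrality).
#' @param t_end Run length in arb. u. (default 930); in `"events"` mode the
#'   nominal target span used to calibrate `every`.
#' @param samples Number of output samples (default 4096).
#' @param seed Integer seed.
#' @param record Recording convention, `"grid"` (default) or `"events"`.
#' @param every Record stride in events for `record = "events"`; `NULL`
#'   (default) calibrates it from a pilot run.
#' @param pilot_t Length of the calibration pilot run (default 40 arb. u.).
#' @param max_events Safety cap on the number of events (default 1e8).
#' @return A `binding_trajectory` tibble with attributes `seed`, `n_events`,
#'   `sampling` (`"grid"` or `"events"`), `every`, and `truncated`.
#' @examples
#' cfg <- binding_config(omega = 0.5)
#' s0 <- binding_state(p = c(100, 0), q = c(100, 0))
#' traj <- gillespie_run(cfg, s0, t_end = 50, samples = 256, seed = 1)
#' @export
gillespie_run <- function(config, initial, t_end = 930, samples = 4096,
                          seed = 1L, record = c("grid", "events"),
                          every = NULL, pilot_t = 40, max_events = 1e8) {
  record <- match.arg(record)
  s0 <- check_state(initial, config)
  if (any(s0 != round(s0))) {
    abort("`initial` must be integer-valued for the unit-step stochastic model.",
          class = "bindsim_invalid_state")
  }
  if (!is.numeric(t_end) || t_end <= 0) {
    abort("`t_end` must be > 0.", class = "bindsim_invalid_parameter")
  }
  if (!is.numeric(samples) || samples < 2) {
    abort("`samples` must be >= 2.", class = "bindsim_invalid_parameter")
  }
  channels <- reaction_channels(config)
  coefs <- attr(channels, "coefficients")
  targets0 <- channels$target_index - 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  if (record == "events" && is.null(every)) {
    # pilot run to estimate the mean event rate, then stride so that
    # samples * every events span roughly t_end
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
    pilot <- ssa_core(s0, coefs, targets0, numeric(2), pilot_t,
                      as.numeric(max_events), 0L)
    rate <- pilot$n_events / pilot$t_final
    if (!is.finite(rate) || rate <= 0) {
      abort("Pilot run produced no events; cannot calibrate `every`.",
            class = "bindsim_absorbing_state")
    }
    every <- max(1L, as.integer(round(rate * t_end / samples)))
  }

  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  if (record == "grid") {
    grid <- (seq_len(samples) - 1) * (t_end / samples)
    res <- ssa_core(s0, coefs, targets0, grid, t_end,
                    as.numeric(max_events), 0L)
  } else {
    # generous time cap: the buffer, not the clock, should end the run
    res <- ssa_core(s0, coefs, targets0, numeric(samples), 100 * t_end,
                    as.numeric(max_events), as.integer(every))
  }
  if (res$capped) {
    abort(sprintf("Event cap reached (%g events) at t = %g.",
                  max_events, res$t_final),
          class = "bindsim_event_cap")
  }
  if (res$absorbed) {
    warn(sprintf("Absorbing state (zero total propensity) at t = %g; trajectory truncated.",
                 res$t_final),
         class = "bindsim_absorbing_state_warning")
  }
  keep <- if (record == "grid") seq_len(samples) else seq_len(res$n_recorded)
  tr <- new_trajectory(res$times[keep],
                       res$states[keep, , drop = FALSE], config,
                       source = "ssa", seed = as.integer(seed),
                       n_events = res$n_events, truncated = res$absorbed)
  attr(tr, "sampling") <- record
  attr(tr, "every") <- if (record == "events") as.integer(every) else NA_integer_
  tr
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
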