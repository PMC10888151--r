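# Trajectory container: a tibble with a `time` column and one column per
# state component, carrying the generating config and run metadata as
# attributes so any run can be re-executed from its own record.

new_trajectory <- function(times, states, config, source,
                           seed = NA_integer_, n_events = NA_real_,
                           truncated = FALSE) {
  colnames(states) <- state_names(config$n, config$m)
  out <- tibble::as_tibble(as.data.frame(states))
  out <- tibble::add_column(out, time = as.numeric(times), .before = 1)
  structure(out,
            class = c("binding_trajectory", class(out)),
            config = config, source = source, seed = seed,
            n_events = n_events, truncated = truncated)
}

#' @export
print.binding_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<binding_trajectory> %d samples, t in [%g, %g], source: %s\n",
              nrow(x), min(x$time), max(x$time), attr(x, "source")))
  cat(sprintf("  omega = %g, scheme = %s, epsilon = %g, alpha = %g\n",
              cfg$omega, cfg$scheme, cfg$epsilon, cfg$alpha))
  if (!is.na(attr(x, "seed"))) {
    cat(sprintf("  seed = %d, events = %g%s\n", attr(x, "seed"),
                attr(x, "n_events"),
                if (isTRUE(attr(x, "truncated"))) " (truncated)" else ""))
  }
  NextMethod()
}

# Extract one process column, checking it exists.
trajectory_process <- function(trajectory, process) {
  if (!is.data.frame(trajectory) || !"time" %in% names(trajectory)) {
    abort("`trajectory` must be a data frame with a `time` column.",
          class = "bindsim_invalid_state")
  }
  if (!process %in% names(trajectory)) {
    abort(sprintf("Process `%s` is not a column of the trajectory.", process),
          class = "bindsim_invalid_state")
  }
  trajectory[[process]]
}

#' Write / read a trajectory as CSV with a JSON metadata sidecar
#'
#' The CSV holds `time` plus one column per state component in plain decimal
#' notation; the sidecar `<path>.json` records the model configuration,
#' initial condition, integrator or stochastic-engine settings, and seed, so
#' the run is re-executable from its metadata alone. [read_trajectory()]
#' restores the tibble and its attributes; a written-then-read trajectory
#' compares equal to the original.
#'
#' @param trajectory A `binding_trajectory` (see [simulate_deterministic()],
#'   [gillespie_run()]).
#' @param path Output CSV path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns the restored trajectory.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(tibble::as_tibble(unclass_trajectory(trajectory)), path)
  cfg <- attr(trajectory, "config")
  meta <- list(
    config = cfg[c("n", "m", "epsilon", "alpha", "omega", "scheme")],
    source = attr(trajectory, "source"),
    sampling = attr(trajectory, "sampling"),
    every = attr(trajectory, "every"),
    seed = attr(trajectory, "seed"),
    n_events = attr(trajectory, "n_events"),
    truncated = attr(trajectory, "truncated"),
    initial = as.numeric(unlist(trajectory[1, -1])),
    n_samples = nrow(trajectory),
    t_end = max(trajectory$time)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

unclass_trajectory <- function(trajectory) {
  out <- trajectory
  class(out) <- setdiff(class(out), "binding_trajectory")
  attr(out, "config") <- NULL
  out
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- binding_config(n = meta$config$n, m = meta$config$m,
                        epsilon = meta$config$epsilon, alpha = meta$config$alpha,
                        omega = meta$config$omega, scheme = meta$config$scheme)
  tr <- new_trajectory(dat$time, as.matrix(dat[, -1, drop = FALSE]), cfg,
                 source = meta$source,
                 seed = if (is.null(meta$seed) || is.na(meta$seed)) NA_integer_ else as.integer(meta$seed),
                 n_events = if (is.null(meta$n_events)) NA_real_ else as.numeric(meta$n_events),
                 truncated = isTRUE(meta$truncated))
  if (!is.null(meta$sampling)) {
    attr(tr, "sampling") <- meta$sampling
    attr(tr, "every") <- if (is.null(meta$every) || is.na(meta$every)) {
      NA_integer_
    } else as.integer(meta$every)
  }
  tr
}
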