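# Power spectral density and spectral entropy of process trajectories.
#
# Pipeline: subtract the series mean, FFT, one-sided magnitudes over the
# first half of the spectrum (DC excluded, Nyquist included), then
# PSD_j = |p(f)_j|^2 / (2 * delta_f) with delta_f = 1 / (N * dt). Spectral
# entropy is the Shannon entropy of the PSD normalized by total power,
# scaled by k = 1/log2(number of bins) so that H lies in [0, 1]: H = 0 is a
# single-line (perfectly ordered) spectrum, H = 1 a flat (white) spectrum.
# For the default 4096-point series there are 2048 bins and k = 1/11.

# Low-level PSD of a numeric series sampled at interval dt.
psd_from_series <- function(series, dt) {
  N <- length(series)
  if (N < 4 || N %% 2 != 0) {
    abort("Series length must be an even number >= 4 (default 4096).",
          class = "bindsim_invalid_parameter")
  }
  if (!is.numeric(dt) || dt <= 0) {
    abort("`dt` must be > 0.", class = "bindsim_invalid_parameter")
  }
  delta_f <- 1 / (N * dt)
  amps <- Mod(fft(series - mean(series)))[2:(N / 2 + 1)]
  list(frequency = seq_len(N / 2) * delta_f,
       psd = amps^2 / (2 * delta_f),
       delta_f = delta_f, sampling_frequency = 1 / dt, n_points = N)
}

#' Power spectral density of a process trajectory
#'
#' Computes the one-sided PSD of one process column of a trajectory sampled
#' on a uniform time grid. The series mean is removed (so the DC bin is
#' excluded and the spectrum reflects the oscillation, not the offset); no
#' window function is applied.
#'
#' @param trajectory A `binding_trajectory` (or any data frame with a
#'   uniform `time` column and process columns).
#' @param process Name of the process column to analyse (default `"p1"`).
#' @param n_points Number of leading samples to use (default all; the
#'   standard protocol uses 4096).
#' @param dt Sampling interval. Default `NULL`: taken from the `time`
#'   column, which must then be uniform — except for event-recorded
#'   trajectories (see [gillespie_run()]), whose samples are nominally
#'   uniform at `dt = (time span) / (n - 1)`, the number-of-points-over-
#'   time-interval convention.
#' @return A `binding_spectrum` tibble with columns `frequency` (cycles per
#'   arb. u.), `psd`, and `normalized_psd` (PSD / total power; `NA` if the
#'   total power is zero), plus attributes `delta_f`, `sampling_frequency`,
#'   `n_points`, and `process`.
#' @examples
#' tr <- simulate_deterministic(binding_config(omega = 0.5),
#'                              binding_state(p = c(1, 0), q = c(1, 0)),
#'                              t_end = 100, dt_out = 100 / 512)
#' spectral_density(tr[1:512, ], "p1")
#' @export
spectral_density <- function(trajectory, process = "p1", n_points = NULL,
                             dt = NULL) {
  series <- trajectory_process(trajectory, process)
  times <- trajectory$time
  if (!is.null(n_points)) {
    if (n_points > length(series)) {
      abort(sprintf("Trajectory has %d samples; %d requested.",
                    length(series), n_points),
            class = "bindsim_invalid_parameter")
    }
    series <- series[seq_len(n_points)]
    times <- times[seq_len(n_points)]
  }
  if (is.null(dt)) {
    if (identical(attr(trajectory, "sampling"), "events")) {
      dt <- (max(times) - min(times)) / (length(times) - 1)
    } else {
      dts <- diff(times)
      if (length(dts) < 1 || any(abs(dts - dts[1]) > 1e-8 * max(dts[1], 1))) {
        abort("Trajectory must be sampled on a uniform time grid (or supply `dt`).",
              class = "bindsim_invalid_state")
      }
      dt <- dts[1]
    }
  }
  res <- psd_from_series(series, dt)
  total <- sum(res$psd)
  out <- tibble::tibble(
    frequency = res$frequency,
    psd = res$psd,
    normalized_psd = if (total > 0) res$psd / total else NA_real_
  )
  structure(out,
            class = c("binding_spectrum", class(out)),
            delta_f = res$delta_f, sampling_frequency = res$sampling_frequency,
            n_points = res$n_points, process = process)
}

#' Normalize a power spectral density to unit total power
#'
#' @param spectrum A `binding_spectrum` from [spectral_density()], or a
#'   nonnegative numeric PSD vector.
#' @return The spectrum with `normalized_psd` summing to 1 (a numeric
#'   vector if the input was one).
#' @export
normalize_psd <- function(spectrum) {
  psd <- if (is.data.frame(spectrum)) spectrum$psd else spectrum
  if (any(psd < 0)) {
    abort("PSD values must be nonnegative.", class = "bindsim_invalid_parameter")
  }
  total <- sum(psd)
  if (total <= 0) {
    abort("Total power is zero; the normalized spectrum is undefined (constant series?).",
          class = "bindsim_degenerate_spectrum")
  }
  if (is.data.frame(spectrum)) {
    spectrum$normalized_psd <- psd / total
    spectrum
  } else {
    psd / total
  }
}

#' Spectral entropy of a normalized power spectrum
#'
#' Shannon entropy of the normalized PSD, scaled by
#' `k = 1 / log2(n_bins)` so the result lies in `[0, 1]`
#' (`k = 1/log2(2048) = 1/11` for the default 2048-bin spectrum);
#' `0 * log2(0)` is taken as 0 by continuity.
#'
#' @param x A `binding_spectrum`, or a numeric vector of normalized PSD
#'   values (nonnegative, summing to 1).
#' @return The spectral entropy `H` in `[0, 1]`.
#' @examples
#' spectral_entropy(rep(1 / 2048, 2048))       # 1: flat spectrum
#' spectral_entropy(c(1, rep(0, 2047)))        # 0: single line
#' spectral_entropy(c(0.5, 0.5, rep(0, 2046))) # 1/11
#' @export
spectral_entropy <- function(x) {
  p <- if (is.data.frame(x)) x$normalized_psd else x
  if (is.null(p) || all(is.na(p))) {
    abort("No normalized PSD available (zero total power?).",
          class = "bindsim_degenerate_spectrum")
  }
  if (any(p < 0)) {
    abort("Normalized PSD entries must be nonnegative.",
          class = "bindsim_invalid_distribution")
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort("Normalized PSD must sum to 1.", class = "bindsim_invalid_distribution")
  }
  k <- 1 / log2(length(p))
  nz <- p > 0
  -k * sum(p[nz] * log2(p[nz]))
}

#' One-row spectral summary of a process trajectory
#'
#' Runs the full pipeline — PSD, normalization, spectral entropy, dominant
#' frequency — and returns a glance-style one-row tibble.
#'
#' @inheritParams spectral_density
#' @return A tibble with columns `process`, `entropy`, `dominant_frequency`
#'   (cycles per arb. u.), `dominant_period`, `delta_f`, `k`, `n_bins`.
#' @export
spectral_summary <- function(trajectory, process = "p1", n_points = NULL,
                             dt = NULL) {
  spec <- spectral_density(trajectory, process, n_points, dt)
  spec <- normalize_psd(spec)
  peak <- which.max(spec$normalized_psd)
  tibble::tibble(
    process = process,
    entropy = spectral_entropy(spec),
    dominant_frequency = spec$frequency[peak],
    dominant_period = 1 / spec$frequency[peak],
    delta_f = attr(spec, "delta_f"),
    k = 1 / log2(nrow(spec)),
    n_bins = nrow(spec)
  )
}

#' Write a spectrum as CSV
#'
#' Columns `frequency,psd,normalized_psd`.
#'
#' @param spectrum A `binding_spectrum`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(spectrum)), path)
  invisible(path)
}

#' Synthetic sinusoid-plus-noise series
#'
#' Fixture generator for spectral analysis: a sum of sinusoids on a uniform
#' grid with optional additive Gaussian noise, returned in trajectory-like
#' form (a tibble with `time` and one value column) so it can feed
#' [spectral_density()] directly.
#'
#' @param n_points Number of samples.
#' @param dt Sampling interval.
#' @param frequencies Sinusoid frequencies (cycles per time unit).
#' @param amplitudes Amplitudes, recycled against `frequencies`.
#' @param phases Phases in radians, recycled; default 0 (pure cosines).
#' @param noise_sd Standard deviation of additive white Gaussian noise.
#' @param name Name of the value column (default `"p1"`).
#' @return A tibble with columns `time` and `name`.
#' @examples
#' synth_series(512, 0.1, frequencies = 0.5)
#' @export
synth_series <- function(n_points, dt, frequencies, amplitudes = 1,
                         phases = 0, noise_sd = 0, name = "p1") {
  t <- (seq_len(n_points) - 1) * dt
  amplitudes <- rep_len(amplitudes, length(frequencies))
  phases <- rep_len(phases, length(frequencies))
  y <- rep(0, n_points)
  for (i in seq_along(frequencies)) {
    y <- y + amplitudes[i] * cos(2 * pi * frequencies[i] * t + phases[i])
  }
  if (noise_sd > 0) y <- y + rnorm(n_points, sd = noise_sd)
  out <- tibble::tibble(time = t)
  out[[name]] <- y
  out
}
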